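cohort_41 <- function(seed = 1) {
  generate_cohort(c(8, 10, 14, 9), seed = seed)   # N = 41 in 2 x 2 cells
}

test_that("mixed RM-ANOVA df follow the 2x2-between, 3-within design", {
  a <- rm_anova(cohort_41())
  within <- a[a$effect == "band", ]
  expect_equal(c(within$df1, within$df2), c(2, 74))
  between <- a[a$effect == "likelihood", ]
  expect_equal(c(between$df1, between$df2), c(1, 37))
  expect_setequal(a$effect, c("likelihood", "age", "likelihood:age", "band",
                              "likelihood:band", "age:band",
                              "likelihood:age:band"))
})

test_that("RM-ANOVA F values match hand-computed sums of squares", {
  # balanced 2 x 2 x 3 toy (2 subjects per cell): Type III == classical SS
  set.seed(8)
  toy <- generate_cohort(2, seed = 8)
  Y <- as.matrix(toy[, c("norm_stressed", "norm_syllable", "norm_phonological")])
  n <- nrow(Y); p <- 3
  grp <- as.integer(toy$likelihood_group == "HL")
  age <- as.integer(toy$age_group == "14m")
  subj_mean <- rowMeans(Y)
  grand <- mean(Y)
  # between-subject decomposition on subject means (x p for SS on cells)
  cellmean <- ave(subj_mean, interaction(grp, age))
  gm <- ave(subj_mean, grp); am <- ave(subj_mean, age)
  ss_grp <- p * sum((gm - grand)^2)
  ss_age <- p * sum((am - grand)^2)
  ss_ga <- p * sum((cellmean - gm - am + grand)^2)
  ss_subj <- p * sum((subj_mean - cellmean)^2)
  f_grp <- (ss_grp / 1) / (ss_subj / (n - 4))
  # within decomposition
  bandmean <- colMeans(Y)
  cell_band <- matrix(0, n, p)
  for (k in 1:p) cell_band[, k] <- ave(Y[, k], interaction(grp, age))
  gm_b <- matrix(0, n, p); am_b <- matrix(0, n, p)
  for (k in 1:p) { gm_b[, k] <- ave(Y[, k], grp); am_b[, k] <- ave(Y[, k], age) }
  ss_band <- n * sum((bandmean - grand)^2)
  # band x subject residual: remove subject and cell-by-band structure
  err <- 0
  for (k in 1:p) {
    dev <- (Y[, k] - subj_mean) - (cell_band[, k] - cellmean)
    err <- err + sum(dev^2)
  }
  f_band <- (ss_band / (p - 1)) / (err / ((p - 1) * (n - 4)))
  a <- rm_anova(toy)
  expect_equal(a$F[a$effect == "likelihood"], f_grp, tolerance = 1e-10)
  expect_equal(a$F[a$effect == "band"], f_band, tolerance = 1e-10)
})

test_that("band contrasts are paired t-tests with df = N - 1", {
  bc <- band_contrasts(cohort_41())
  expect_equal(nrow(bc), 3)
  expect_true(all(bc$df == 40))

  same <- cohort_41()
  same$norm_syllable <- same$norm_stressed
  b2 <- band_contrasts(same)
  row <- b2[b2$band_a == "stressed" & b2$band_b == "syllable", ]
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)

  toy <- generate_cohort(c(2, 1, 1, 1), seed = 3)   # N = 5
  x <- toy$norm_stressed; y <- toy$norm_syllable
  d <- x - y
  t_direct <- mean(d) / (sd(d) / sqrt(5))
  b3 <- band_contrasts(toy)
  expect_equal(b3$t[b3$band_a == "stressed" & b3$band_b == "syllable"],
               t_direct, tolerance = 1e-12)
})

cohort_n <- function(n, seed = 1, ...) {
  base <- generate_cohort(ceiling(n / 4), seed = seed, ...)
  base[seq_len(n), ]
}

test_that("step-1 regression has F(3, 30) at n = 34", {
  tab <- cohort_n(34, seed = 4)
  hr <- hierarchical_regression(tab, "receptive", cv = FALSE)
  s1 <- hr$steps[[1]]
  expect_equal(c(s1$df1, s1$df2), c(3, 30))
  expect_length(hr$steps, 3)
})

test_that("ADOS models run in the HL group without likelihood terms", {
  set.seed(10)
  tab <- generate_cohort(c(11, 1, 7, 1), seed = 10,
                         behavior = behavior_model(ados_slope = 0.5))
  # 18 HL subjects; step 1 has 2 non-intercept terms -> F(2, 15)
  hr <- hierarchical_regression(tab, "ados", cv = FALSE)
  s1 <- hr$steps[[1]]
  expect_equal(c(s1$df1, s1$df2), c(2, 15))
  expect_false(any(grepl("grp01", s1$coefficients$term)))
})

test_that("a noiseless linear outcome saturates step 1 and blocks later steps", {
  tab <- cohort_n(40, seed = 5)
  tab$cdi_receptive_pct <- pmin(100, pmax(0, 10 + 30 * tab$norm_stressed))
  hr <- suppressWarnings(   # lm warns about the intentionally perfect fit
    hierarchical_regression(tab, "receptive", cv_rep = 30, seed = 2))
  expect_true(hr$steps[[1]]$retained)
  expect_gt(suppressWarnings(summary(hr$steps[[1]]$fit))$r.squared, 1 - 1e-10)
  expect_false(hr$steps[[2]]$retained)
  expect_false(hr$steps[[3]]$retained)
  expect_equal(hr$steps[[1]]$cv_r2, 1, tolerance = 1e-8)
  expect_lt(hr$steps[[1]]$cv_rmse, 1e-8)
})

test_that("step 3 is compared against step 1 when step 2 is not retained", {
  set.seed(991)
  tab <- cohort_n(40, seed = 12)
  tab$cdi_receptive_pct <- pmin(100, pmax(0,
    30 + 20 * tab$norm_stressed + rnorm(40, 0, 5)))
  hr <- hierarchical_regression(tab, "receptive", cv = FALSE)
  expect_false(hr$steps[[2]]$retained)
  # the step-3 comparison must then have 3 numerator df against step 1
  cmp <- anova(hr$steps[[1]]$fit, hr$steps[[3]]$fit)
  expect_equal(cmp$Df[2], 3)
  expect_equal(hr$steps[[3]]$comparison_p, cmp$`Pr(>F)`[2], tolerance = 1e-12)
})

test_that("df bookkeeping holds over random design sizes", {
  set.seed(33)
  for (r in 1:20) {
    n <- sample(20:60, 1)
    tab <- cohort_n(n, seed = r + 50)
    hr <- hierarchical_regression(tab, "receptive", cv = FALSE)
    k <- 3
    for (s in hr$steps) {
      expect_equal(s$df2, n - (s$df1 + 1))
      expect_true(s$retained == (is.finite(s$comparison_p) && s$comparison_p < 0.05))
    }
    expect_equal(hr$steps[[1]]$df1, 3)
  }
})

test_that("Monte-Carlo CV is deterministic, exact for noiseless data, and null-bounded", {
  tab <- cohort_n(40, seed = 6)
  tab$.y <- 5 + 2 * tab$norm_stressed
  cv1 <- monte_carlo_cv("norm_stressed", tab, n_rep = 50, seed = 3)
  expect_equal(cv1$cv_r2, 1, tolerance = 1e-10)
  expect_lt(cv1$cv_rmse, 1e-8)
  cv2 <- monte_carlo_cv("norm_stressed", tab, n_rep = 50, seed = 3)
  expect_identical(cv1, cv2)

  # pure-noise outcome: mean CV R2 stays small
  set.seed(21)
  r2s <- vapply(1:10, function(s) {
    tab$.y <- rnorm(40)
    monte_carlo_cv("norm_stressed", tab, n_rep = 60, seed = s)$cv_r2
  }, numeric(1))
  expect_lt(mean(r2s), 0.15)

  expect_error(monte_carlo_cv(paste0("x", 1:30), tab[1:10, ], n_rep = 5),
               "parameter count")
})

test_that("leave-one-out CV matches brute-force enumeration and flags degeneracy", {
  set.seed(14)
  tab <- cohort_n(5, seed = 14)
  tab$.y <- tab$cdi_receptive_pct
  got <- loo_cv("norm_stressed", tab)
  pred <- vapply(1:5, function(i) {
    fit <- lm(.y ~ norm_stressed, data = tab[-i, ])
    unname(predict(fit, newdata = tab[i, ]))
  }, numeric(1))
  expect_equal(got$cv_r2, cor(tab$.y, pred)^2, tolerance = 1e-12)
  expect_equal(got$cv_rmse, sqrt(mean((tab$.y - pred)^2)), tolerance = 1e-12)

  tab$.y <- 7
  flat <- loo_cv("norm_stressed", tab)
  expect_equal(flat$cv_r2, 0)
  expect_true(flat$flagged)

  tab2 <- cohort_n(40, seed = 15)
  tab2$.y <- 5 + 2 * tab2$norm_stressed
  expect_equal(loo_cv("norm_stressed", tab2)$cv_r2, 1, tolerance = 1e-10)
})

test_that("group correlations report r with df = n - 2 per subgroup", {
  tab <- cohort_n(34, seed = 16)
  tab$age_group <- rep(c("10m", "14m"), c(11, 23))
  gc <- group_correlations(tab, "receptive", "age_group")
  expect_equal(gc$df[gc$group == "10m"], 9)
  expect_equal(gc$n[gc$group == "10m"], 11)

  perf <- tab
  perf$cdi_receptive_pct <- pmin(100, pmax(0, 50 + 10 * perf$norm_stressed))
  gp <- group_correlations(perf, "receptive", "age_group")
  expect_equal(gp$r, c(1, 1), tolerance = 1e-10)

  toy <- cohort_n(6, seed = 17)
  toy$age_group <- "10m"
  gt <- group_correlations(toy, "receptive", "age_group")
  r_direct <- cor(toy$norm_stressed, toy$cdi_receptive_pct)
  expect_equal(gt$r, r_direct, tolerance = 1e-12)
  expect_equal(gt$df, 4)
})

test_that("single-band control models reuse the step-1 design", {
  tab <- cohort_n(34, seed = 18)
  sb <- single_band_model(tab, "receptive", "syllable")
  expect_equal(c(sb$df1, sb$df2), c(3, 30))
  expect_true(all(grepl("norm_syllable|age01|grp01",
                        setdiff(sb$coefficients$term, "(Intercept)"))))

  tab$cdi_receptive_pct <- pmin(100, pmax(0, 20 + 25 * tab$norm_syllable))
  expect_true(suppressWarnings(   # perfect fit by construction
    single_band_model(tab, "receptive", "syllable"))$retained)
})

test_that("an outcome driven by the stressed band is rarely matched by the syllable band", {
  hits <- 0L
  for (r in 1:60) {
    tab <- generate_cohort(13, seed = 900 + r,
                           behavior = behavior_model(slope_stressed = 20,
                                                     age_interaction = 0,
                                                     group_interaction = 0,
                                                     residual_sd = 20))[1:50, ]
    sb <- single_band_model(tab, "receptive", "syllable")
    hits <- hits + as.integer(sb$comparison_p < 0.05)
  }
  expect_lt(hits / 60, 0.5)   # no specific signal in the majority of replicates
})

test_that("the planted regression structure is recovered across replicate cohorts", {
  bm <- behavior_model(intercept = 25, slope_stressed = 25,
                       age_interaction = -15, group_interaction = -10,
                       residual_sd = 15)
  n_rep <- 100
  retained <- logical(n_rep)
  covered <- logical(n_rep)
  slopes <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    tab <- generate_cohort(10, behavior = bm, seed = 3000 + r)   # n = 40
    hr <- hierarchical_regression(tab, "receptive", cv = FALSE)
    s1 <- hr$steps[[1]]
    retained[r] <- s1$retained
    est <- s1$coefficients
    b <- est[est$term == "norm_stressed", ]
    ci <- confint(s1$fit)["norm_stressed", ]
    covered[r] <- ci[1] <= bm$slope_stressed && bm$slope_stressed <= ci[2]
    slopes[r] <- b$estimate
  }
  expect_gt(mean(retained), 0.9)
  expect_gte(mean(covered), 0.9)
  expect_gt(median(slopes), 0)
  expect_lt(abs(median(slopes) - 25) / 25, 0.1)
})
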