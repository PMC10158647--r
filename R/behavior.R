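#' Read / validate a cohort table
#'
#' @param x data.frame or CSV path with columns `subject_id`,
#'   `likelihood_group` (HL/LL), `age_group` (10m/14m), `norm_stressed`,
#'   `norm_syllable`, `norm_phonological`, and outcome columns
#'   `cdi_receptive_pct`, `cdi_productive_pct` (0-100) and optional
#'   `ados_comparison` (integer 1-10).
#' @return validated data.frame of class `cohort_table`.
#' @export
cohort_table <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  x <- as.data.frame(x)
  need <- c("subject_id", "likelihood_group", "age_group",
            "norm_stressed", "norm_syllable", "norm_phonological")
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("cohort table lacks columns: %s", paste(miss, collapse = ", "))
  if (!all(x$likelihood_group %in% c("HL", "LL")))
    stopf("likelihood_group must be HL or LL")
  if (!all(x$age_group %in% c("10m", "14m"))) stopf("age_group must be 10m or 14m")
  for (col in intersect(c("cdi_receptive_pct", "cdi_productive_pct"), names(x)))
    if (any(x[[col]] < 0 | x[[col]] > 100, na.rm = TRUE))
      stopf("%s must lie in [0, 100]", col)
  if ("ados_comparison" %in% names(x) &&
      any(x$ados_comparison < 1 | x$ados_comparison > 10, na.rm = TRUE))
    stopf("ados_comparison must lie in [1, 10]")
  class(x) <- c("cohort_table", "data.frame")
  x
}

outcome_column <- function(outcome = c("receptive", "productive", "ados")) {
  switch(match.arg(outcome),
         receptive = "cdi_receptive_pct",
         productive = "cdi_productive_pct",
         ados = "ados_comparison")
}

#' Mixed repeated-measures ANOVA on band coherences
#'
#' Within-subject factor: rate band (3 levels); between-subject factors:
#' likelihood group and age group (2 x 2). Type III sums of squares with
#' sum-to-zero contrasts; df follow the mixed-design rules (between effects
#' against the between-subject residual on N - 4 df, within effects against
#' the band x subject residual on 2(N - 4) df).
#'
#' @param table [cohort_table()] with complete band triples (subjects with
#'   missing band values are dropped with a message).
#' @return data.frame with columns `effect`, `df1`, `df2`, `F`, `p`.
#' @export
rm_anova <- function(table) {
  table <- cohort_table(table)
  bands <- c("norm_stressed", "norm_syllable", "norm_phonological")
  ok <- stats::complete.cases(table[, bands])
  if (any(!ok)) {
    message(sprintf("%d subject(s) dropped for missing band values", sum(!ok)))
    table <- table[ok, ]
  }
  cells <- table(table$likelihood_group, table$age_group)
  if (any(cells < 2)) stopf("need >= 2 subjects in every likelihood x age cell")
  Y <- as.matrix(table[, bands])
  colnames(Y) <- c("stressed", "syllable", "phonological")
  d <- data.frame(likelihood = factor(table$likelihood_group),
                  age = factor(table$age_group))
  mod <- stats::lm(Y ~ likelihood * age, data = d,
                   contrasts = list(likelihood = stats::contr.sum,
                                    age = stats::contr.sum))
  idata <- data.frame(band = factor(colnames(Y), levels = colnames(Y)))
  a <- car::Anova(mod, idata = idata, idesign = ~band, type = 3)
  u <- suppressWarnings(summary(a, multivariate = FALSE))$univariate.tests
  u <- u[rownames(u) != "(Intercept)", , drop = FALSE]
  data.frame(effect = rownames(u), df1 = u[, "num Df"], df2 = u[, "den Df"],
             F = u[, "F value"], p = u[, "Pr(>F)"], row.names = NULL)
}

#' Pairwise paired t-tests between the three rate bands
#'
#' @param table [cohort_table()].
#' @return data.frame with one row per band pair: `t`, `df` (= N - 1), `p`,
#'   and the two band means.
#' @export
band_contrasts <- function(table) {
  table <- cohort_table(table)
  bands <- c(stressed = "norm_stressed", syllable = "norm_syllable",
             phonological = "norm_phonological")
  pairs <- utils::combn(names(bands), 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- table[[bands[pairs[1, i]]]]; b <- table[[bands[pairs[2, i]]]]
    if (stats::sd(a - b) == 0) {
      # identical band values: no difference to test
      tt <- list(statistic = 0, parameter = length(a) - 1, p.value = 1)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
    }
    data.frame(band_a = pairs[1, i], band_b = pairs[2, i],
               mean_a = mean(a), mean_b = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, out)
}

# Model matrix columns for one band's step: coherence + its interactions
# with age (10m = 0, 14m = 1) and, unless dropped, likelihood (LL = 0,
# HL = 1). `main_effects = TRUE` switches to the hierarchical coding that
# also enters the group main effects.
step_terms <- function(band, with_likelihood, main_effects = FALSE) {
  base <- paste0("norm_", band)
  terms <- c(base, paste0(base, ":age01"))
  if (with_likelihood) terms <- c(terms, paste0(base, ":grp01"))
  if (main_effects) {
    terms <- c("age01", if (with_likelihood) "grp01", terms)
  }
  terms
}

prep_regression_data <- function(table, outcome) {
  col <- outcome_column(outcome)
  if (!col %in% names(table)) stopf("outcome column %s missing", col)
  if (outcome == "ados") table <- table[table$likelihood_group == "HL", ]
  table <- table[stats::complete.cases(table[, c(col, "norm_stressed",
                                                 "norm_syllable",
                                                 "norm_phonological")]), ]
  table$age01 <- as.integer(table$age_group == "14m")
  table$grp01 <- as.integer(table$likelihood_group == "HL")
  table$.y <- table[[col]]
  table
}

fit_terms <- function(terms, data) {
  f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  stats::lm(f, data = data)
}

step_result <- function(step_index, terms_added, fit, cmp_p, retained,
                        cv = NULL) {
  sm <- summary(fit)
  co <- stats::coef(sm)
  fstat <- sm$fstatistic
  list(step_index = step_index, predictors_added = terms_added,
       coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                 t = co[, 3], p = co[, 4], row.names = NULL),
       F = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
       p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       comparison_p = cmp_p, retained = retained,
       cv_r2 = if (!is.null(cv)) cv$cv_r2 else NA_real_,
       cv_rmse = if (!is.null(cv)) cv$cv_rmse else NA_real_,
       fit = fit)
}

#' Three-step hierarchical regression of an outcome on band coherences
#'
#' Predictors enter in blocks: step 1 the stressed-syllable band (coherence
#' plus its interactions with age group and - for vocabulary outcomes -
#' likelihood group), step 2 adds the phonological band triple, step 3 the
#' syllable band triple. Each candidate model is compared against the last
#' retained model with an incremental F-test; a block is retained iff that
#' p < 0.05 (step 1 is compared against the intercept-only model). The ADOS
#' outcome is fit in the HL group only and its likelihood-interaction terms
#' are dropped. Group codes: LL = 0 / HL = 1, 10m = 0 / 14m = 1; by default
#' only the listed terms enter (no separate group main effects), matching
#' the three-predictor step-1 design; `main_effects = TRUE` switches to
#' hierarchical coding.
#'
#' @param table [cohort_table()].
#' @param outcome `"receptive"`, `"productive"`, or `"ados"`.
#' @param main_effects also enter age/likelihood main effects (default
#'   FALSE).
#' @param cv run Monte-Carlo cross-validation per step (default TRUE).
#' @param cv_rep,cv_holdout,seed cross-validation settings (defaults 200
#'   repetitions, 20% holdout).
#' @return object of class `hier_reg`: list of step results (see
#'   [monte_carlo_cv()] for the CV metrics).
#' @export
hierarchical_regression <- function(table, outcome = c("receptive", "productive", "ados"),
                                    main_effects = FALSE, cv = TRUE,
                                    cv_rep = 200, cv_holdout = 0.2, seed = 1L) {
  outcome <- match.arg(outcome)
  table <- cohort_table(table)
  data <- prep_regression_data(table, outcome)
  with_lik <- outcome != "ados"
  blocks <- list(step_terms("stressed", with_lik, main_effects),
                 step_terms("phonological", with_lik, FALSE),
                 step_terms("syllable", with_lik, FALSE))
  steps <- list()
  retained_terms <- character(0)
  baseline <- fit_terms("1", data)
  for (s in seq_along(blocks)) {
    cand_terms <- unique(c(retained_terms, blocks[[s]]))
    fit <- fit_terms(cand_terms, data)
    if (any(is.na(stats::coef(fit)))) {
      warning(sprintf("step %d is rank deficient; not retained", s))
      steps[[s]] <- step_result(s, blocks[[s]], fit, NA_real_, FALSE)
      next
    }
    base_rss <- sum(stats::residuals(baseline)^2)
    tss <- sum((data$.y - mean(data$.y))^2)
    if (base_rss <= 1e-10 * max(tss, 1)) {
      # the retained model already fits exactly; nothing can improve it
      cmp_p <- NA_real_
    } else {
      cmp <- stats::anova(baseline, fit)
      cmp_p <- cmp$`Pr(>F)`[2]
    }
    retained <- is.finite(cmp_p) && cmp_p < 0.05
    cvres <- if (cv) monte_carlo_cv(cand_terms, data, n_rep = cv_rep,
                                    holdout = cv_holdout,
                                    seed = derive_seed(seed, paste0("cv", s)))
             else NULL
    steps[[s]] <- step_result(s, blocks[[s]], fit, cmp_p, retained, cvres)
    if (retained) {
      retained_terms <- cand_terms
      baseline <- fit
    }
  }
  structure(list(steps = steps, outcome = outcome, n = nrow(data),
                 main_effects = main_effects),
            class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, ...) {
  cat(sprintf("<hier_reg: outcome %s, n = %d>\n", x$outcome, x$n))
  for (s in x$steps) {
    cat(sprintf("  step %d [%s]: F(%g, %g) = %.2f, p = %.4f; comparison p = %.4f%s",
                s$step_index, paste(s$predictors_added, collapse = ", "),
                s$df1, s$df2, s$F, s$p,
                s$comparison_p,
                if (s$retained) " *retained*\n" else "\n"))
    if (!is.na(s$cv_r2))
      cat(sprintf("           CV: R2 = %.3f, RMSE = %.2f\n", s$cv_r2, s$cv_rmse))
  }
  invisible(x)
}

#' Single-band control models
#'
#' The step-1 design with the syllable or phonological band substituted for
#' the stressed band (band coherence plus its interactions with age and
#' likelihood group), used to check specificity of a stressed-band effect.
#'
#' @param table [cohort_table()].
#' @param outcome as in [hierarchical_regression()].
#' @param band `"syllable"` or `"phonological"`.
#' @param ... passed to the CV machinery as in [hierarchical_regression()].
#' @return a single step result (list), with `retained` meaning overall
#'   F-test p < 0.05.
#' @export
single_band_model <- function(table, outcome = c("receptive", "productive", "ados"),
                              band = c("syllable", "phonological"),
                              cv = FALSE, cv_rep = 200, cv_holdout = 0.2,
                              seed = 1L) {
  outcome <- match.arg(outcome)
  band <- match.arg(band)
  table <- cohort_table(table)
  data <- prep_regression_data(table, outcome)
  terms <- step_terms(band, with_likelihood = outcome != "ados")
  fit <- fit_terms(terms, data)
  cmp <- stats::anova(fit_terms("1", data), fit)
  cmp_p <- cmp$`Pr(>F)`[2]
  cvres <- if (cv) monte_carlo_cv(terms, data, n_rep = cv_rep,
                                  holdout = cv_holdout, seed = seed) else NULL
  step_result(1L, terms, fit, cmp_p, is.finite(cmp_p) && cmp_p < 0.05, cvres)
}

#' Monte-Carlo cross-validation of a linear model
#'
#' Repeatedly holds out a random fraction of subjects, fits on the rest, and
#' predicts the holdout. Per repetition, R-squared is the squared Pearson
#' correlation between predicted and observed values and RMSE the root mean
#' squared prediction error; the returned metrics are means over
#' repetitions. Repetitions with a degenerate holdout (zero variance in
#' predictions or observations) are skipped and counted.
#'
#' @param terms character vector of predictor terms (the `.y` outcome and
#'   coded columns must exist in `data`), or a formula.
#' @param data prepared data.frame.
#' @param n_rep repetitions (default 200).
#' @param holdout held-out fraction (default 0.2).
#' @param seed RNG seed.
#' @return list with `cv_r2`, `cv_rmse`, `n_skipped`.
#' @export
monte_carlo_cv <- function(terms, data, n_rep = 200, holdout = 0.2, seed = 1L) {
  f <- if (inherits(terms, "formula")) terms
       else stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  yname <- all.vars(f)[1]
  n <- nrow(data)
  n_test <- max(1L, round(holdout * n))
  n_par <- length(attr(stats::terms(f), "term.labels")) + 1L
  if (n - n_test <= n_par)
    stopf("training folds (%d) would not exceed the parameter count (%d)",
          n - n_test, n_par)
  r2 <- rmse <- numeric(0)
  skipped <- 0L
  with_seed(seed, {
    for (r in seq_len(n_rep)) {
      test <- sample.int(n, n_test)
      fit <- stats::lm(f, data = data[-test, , drop = FALSE])
      pred <- stats::predict(fit, newdata = data[test, , drop = FALSE])
      obs <- data[[yname]][test]
      err <- sqrt(mean((obs - pred)^2))
      if (n_test >= 2 && stats::sd(obs) > 0 && stats::sd(pred) > 0) {
        r2 <- c(r2, stats::cor(obs, pred)^2)
        rmse <- c(rmse, err)
      } else skipped <- skipped + 1L
    }
  })
  list(cv_r2 = if (length(r2)) mean(r2) else NA_real_,
       cv_rmse = if (length(rmse)) mean(rmse) else NA_real_,
       n_skipped = skipped)
}

#' Leave-one-out cross-validation of a linear model
#'
#' Fits `n` models, each leaving one subject out; R-squared is the squared
#' Pearson correlation of the `n` held-out predictions against the
#' observations and RMSE the root mean squared held-out error. A constant
#' outcome (or constant predictions) makes the correlation undefined; R2 is
#' then reported as 0 with `flagged = TRUE`.
#'
#' @inheritParams monte_carlo_cv
#' @return list with `cv_r2`, `cv_rmse`, `flagged`.
#' @export
loo_cv <- function(terms, data) {
  f <- if (inherits(terms, "formula")) terms
       else stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  yname <- all.vars(f)[1]
  n <- nrow(data)
  n_par <- length(attr(stats::terms(f), "term.labels")) + 1L
  if (n < n_par + 2) stopf("n = %d too small for %d parameters", n, n_par)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- stats::lm(f, data = data[-i, , drop = FALSE])
    pred[i] <- stats::predict(fit, newdata = data[i, , drop = FALSE])
  }
  obs <- data[[yname]]
  flagged <- stats::sd(obs) == 0 || stats::sd(pred) == 0
  list(cv_r2 = if (flagged) 0 else stats::cor(obs, pred)^2,
       cv_rmse = sqrt(mean((obs - pred)^2)),
       flagged = flagged)
}

#' Group-wise Pearson correlations between a band coherence and an outcome
#'
#' @param table [cohort_table()].
#' @param outcome as in [hierarchical_regression()].
#' @param split_by `"age_group"` or `"likelihood_group"`.
#' @param band predictor band (default `"stressed"`).
#' @return data.frame with one row per subgroup: `n`, `r`, `df` (= n - 2),
#'   `p`, `flagged` (zero-variance subgroup).
#' @export
group_correlations <- function(table, outcome = c("receptive", "productive", "ados"),
                               split_by = c("age_group", "likelihood_group"),
                               band = "stressed") {
  outcome <- match.arg(outcome)
  split_by <- match.arg(split_by)
  table <- cohort_table(table)
  col <- outcome_column(outcome)
  xcol <- paste0("norm_", band)
  table <- table[stats::complete.cases(table[, c(col, xcol)]), ]
  out <- lapply(split(table, table[[split_by]]), function(g) {
    if (nrow(g) < 3) stopf("subgroup with n = %d < 3", nrow(g))
    if (stats::sd(g[[xcol]]) == 0 || stats::sd(g[[col]]) == 0)
      return(data.frame(group = g[[split_by]][1], n = nrow(g), r = NA_real_,
                        df = nrow(g) - 2, p = NA_real_, flagged = TRUE))
    ct <- stats::cor.test(g[[xcol]], g[[col]])
    data.frame(group = g[[split_by]][1], n = nrow(g),
               r = unname(ct$estimate), df = unname(ct$parameter),
               p = ct$p.value, flagged = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
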