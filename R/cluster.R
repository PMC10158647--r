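# Schematic 2D positions (top view, nose up) for the 28-channel montage,
# from which distance-based adjacency is built. Also shipped as JSON under
# inst/extdata/neighbors_1020.json.
ntrack_channel_positions <- function() {
  pos <- rbind(
    FP1 = c(-0.27,  0.90), FP2 = c( 0.27,  0.90),
    F7  = c(-0.72,  0.55), F3  = c(-0.39,  0.55), Fz  = c(0,  0.55),
    F4  = c( 0.39,  0.55), F8  = c( 0.72,  0.55),
    FC5 = c(-0.59,  0.30), FC1 = c(-0.20,  0.30),
    FC2 = c( 0.20,  0.30), FC6 = c( 0.59,  0.30),
    T7  = c(-0.90,  0.00), C3  = c(-0.45,  0.00), Cz  = c(0,  0.00),
    C4  = c( 0.45,  0.00), T8  = c( 0.90,  0.00),
    CP5 = c(-0.59, -0.30), CP1 = c(-0.20, -0.30),
    CP2 = c( 0.20, -0.30), CP6 = c( 0.59, -0.30),
    P7  = c(-0.72, -0.55), P3  = c(-0.39, -0.55), Pz  = c(0, -0.55),
    P4  = c( 0.39, -0.55), P8  = c( 0.72, -0.55),
    O1  = c(-0.27, -0.90), Oz  = c(0, -0.90), O2  = c( 0.27, -0.90))
  colnames(pos) <- c("x", "y")
  pos
}

#' Channel neighbor graph for the cluster test
#'
#' Distance-based adjacency over schematic 10-20 positions of the 28-channel
#' montage: channels closer than `max_dist` (on the unit-head layout) are
#' neighbors. The default distance yields 3-6 neighbors per channel and a
#' connected graph.
#'
#' @param labels channel labels to include (default the full montage).
#' @param max_dist neighbor distance threshold (default 0.45).
#' @return object of class `neighbor_graph`: logical adjacency matrix
#'   (symmetric, no self-edges) plus the source template name.
#' @export
neighbor_graph <- function(labels = NTRACK_CHANNELS, max_dist = 0.45) {
  pos <- ntrack_channel_positions()
  missing <- setdiff(toupper(labels), toupper(rownames(pos)))
  if (length(missing)) stopf("no template position for: %s",
                             paste(missing, collapse = ", "))
  pos <- pos[match(toupper(labels), toupper(rownames(pos))), , drop = FALSE]
  d <- as.matrix(stats::dist(pos))
  adj <- d > 0 & d < max_dist
  dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, source = "schematic-10-20-distance"),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph (%s): %d channels, %.1f neighbors/channel>\n",
              x$source, nrow(x$adjacency), mean(rowSums(x$adjacency))))
  invisible(x)
}

#' Paired t-statistic map of observed minus surrogate coherence
#'
#' One-sample t on the per-subject observed-surrogate differences at each
#' channel x frequency cell, df = n - 1. Cells with zero variance and a
#' nonzero mean are capped at `t_cap` (flagged via the `"capped"` attribute).
#'
#' @param obs_stack,surr_stack subject x channel x frequency arrays (or lists
#'   of `coherence_spectrum` objects from the same subjects).
#' @param t_cap replacement for infinite t (default 1e6).
#' @return channel x frequency t matrix.
#' @export
paired_tmap <- function(obs_stack, surr_stack, t_cap = 1e6) {
  obs_stack <- as_subject_stack(obs_stack)
  surr_stack <- as_subject_stack(surr_stack)
  if (!all(dim(obs_stack) == dim(surr_stack)))
    stopf("observed and surrogate stacks differ in shape")
  n <- dim(obs_stack)[1]
  if (n < 2) stopf("paired t-map needs n >= 2 subjects")
  tmap_from_diff(obs_stack - surr_stack, t_cap)
}

tmap_from_diff <- function(d, t_cap = 1e6) {
  n <- dim(d)[1]
  dm <- matrix(d, nrow = n)          # cells as columns
  m <- colMeans(dm)
  ctr <- dm - matrix(m, n, ncol(dm), byrow = TRUE)
  s <- sqrt(colSums(ctr^2) / (n - 1))
  tt <- numeric(length(m))
  pos <- s > 0
  tt[pos] <- m[pos] / (s[pos] / sqrt(n))
  deg <- !pos & m != 0
  tt[deg] <- sign(m[deg]) * t_cap
  tt <- matrix(tt, dim(d)[2], dim(d)[3])
  attr(tt, "capped") <- sum(deg)
  attr(tt, "df") <- n - 1
  tt
}

as_subject_stack <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "coherence_spectrum"))) {
    arr <- array(NA_real_, c(length(x), dim(x[[1]]$values)))
    for (i in seq_along(x)) arr[i, , ] <- x[[i]]$values
    return(arr)
  }
  stopf("expected a subject x channel x frequency array or a list of coherence spectra")
}

# Connected components of suprathreshold cells. Connectivity: channel
# adjacency at the same frequency OR adjacent frequency bins on the same
# channel. Returns a list of integer matrices (channel, bin).
find_clusters <- function(mask, adjacency) {
  n_ch <- nrow(mask); n_f <- ncol(mask)
  lab <- matrix(0L, n_ch, n_f)
  nb <- lapply(seq_len(n_ch), function(c) which(adjacency[c, ]))
  comp <- 0L
  out <- list()
  for (c0 in seq_len(n_ch)) for (f0 in seq_len(n_f)) {
    if (!mask[c0, f0] || lab[c0, f0]) next
    comp <- comp + 1L
    stack <- matrix(c(c0, f0), 1, 2)
    lab[c0, f0] <- comp
    cells <- matrix(integer(0), 0, 2)
    while (nrow(stack)) {
      cur <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      cells <- rbind(cells, cur)
      ch <- cur[1]; fb <- cur[2]
      cand <- rbind(
        if (fb > 1)   c(ch, fb - 1L),
        if (fb < n_f) c(ch, fb + 1L),
        if (length(nb[[ch]])) cbind(nb[[ch]], fb))
      if (!is.null(cand)) for (i in seq_len(nrow(cand))) {
        cc <- cand[i, 1]; ff <- cand[i, 2]
        if (mask[cc, ff] && !lab[cc, ff]) {
          lab[cc, ff] <- comp
          stack <- rbind(stack, c(cc, ff))
        }
      }
    }
    colnames(cells) <- c("channel", "bin")
    out[[comp]] <- cells
  }
  out
}

max_cluster_mass <- function(tmat, thr, adjacency, sided = 1) {
  mass_of <- function(tm) {
    cl <- find_clusters(tm > thr, adjacency)
    if (!length(cl)) return(0)
    max(vapply(cl, function(cells) sum(tm[cells]), numeric(1)))
  }
  if (sided == 1) mass_of(tmat) else max(mass_of(tmat), mass_of(-tmat))
}

#' Cluster-based sign-flip permutation test on the channel x frequency grid
#'
#' Cells whose paired t exceeds the cluster-forming quantile (one-sided,
#' observed > surrogate, by default) are grouped into clusters by channel
#' adjacency or neighboring frequency bins; cluster mass is the summed t.
#' The null distribution of the maximum cluster mass is built by randomly
#' sign-flipping each subject's difference map: exhaustively over all `2^n`
#' flips when `2^n <= n_perm`, else by Monte-Carlo with the observed
#' labeling included. Cluster p = proportion of null masses >= the cluster's
#' mass.
#'
#' @param obs_stack,surr_stack as in [paired_tmap()].
#' @param graph [neighbor_graph()] matching the channel dimension.
#' @param cluster_alpha cluster-forming alpha (default 0.05).
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @param sided 1 (default, observed > surrogate) or 2.
#' @param freqs optional frequency grid for labeling the cluster table.
#' @return object of class `cluster_result`: `clusters` (list with cells,
#'   mass, p_value, sorted by descending mass), `tmap`, `threshold`,
#'   `null_distribution`, `p_min` (smallest cluster p; 1 when no cluster).
#' @export
cluster_permutation_test <- function(obs_stack, surr_stack, graph,
                                     cluster_alpha = 0.05, n_perm = 1000,
                                     seed = NULL, sided = 1, freqs = NULL) {
  stopifnot(inherits(graph, "neighbor_graph"))
  obs_stack <- as_subject_stack(obs_stack)
  surr_stack <- as_subject_stack(surr_stack)
  if (!all(dim(obs_stack) == dim(surr_stack)))
    stopf("observed and surrogate stacks differ in shape")
  n <- dim(obs_stack)[1]
  if (n < 2) stopf("need >= 2 subjects")
  if (n < 5) warning("fewer than 5 subjects: permutation null is very coarse")
  if (dim(obs_stack)[2] != nrow(graph$adjacency))
    stopf("channel dimension does not match the neighbor graph")
  d <- obs_stack - surr_stack
  df <- n - 1
  thr <- if (sided == 1) stats::qt(1 - cluster_alpha, df)
         else stats::qt(1 - cluster_alpha / 2, df)
  tmap <- tmap_from_diff(d)
  clusters <- find_clusters(tmap > thr, graph$adjacency)
  if (sided == 2) {
    neg <- find_clusters(-tmap > thr, graph$adjacency)
    clusters <- c(clusters, neg)
  }
  masses <- vapply(clusters, function(cells) sum(abs(tmap[cells])), numeric(1))
  exhaustive <- 2^n <= n_perm
  signs_mat <- if (exhaustive) {
    m <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(m) <- NULL
    m
  } else NULL
  n_null <- if (exhaustive) 2^n else n_perm
  null <- numeric(n_null)
  with_seed(seed, {
    for (p in seq_len(n_null)) {
      s <- if (exhaustive) signs_mat[p, ]
           else if (p == 1) rep(1, n)            # observed labeling included
           else sample(c(-1, 1), n, replace = TRUE)
      tp <- tmap_from_diff(d * s)
      null[p] <- max_cluster_mass(tp, thr, graph$adjacency, sided)
    }
  })
  ord <- order(masses, decreasing = TRUE)
  cl_out <- lapply(ord, function(i) {
    cells <- clusters[[i]]
    if (!is.null(freqs)) cells <- cbind(cells, freq_hz = freqs[cells[, "bin"]])
    list(cells = cells, mass = masses[i],
         p_value = mean(null >= masses[i] - 1e-12))
  })
  structure(list(clusters = cl_out, tmap = tmap, threshold = thr,
                 null_distribution = null, n_permutations = n_null,
                 exhaustive = exhaustive, cluster_alpha = cluster_alpha,
                 sided = sided,
                 p_min = if (length(cl_out)) cl_out[[1]]$p_value else 1),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d cluster(s), %d %s permutations, threshold t=%.2f>\n",
              length(x$clusters), x$n_permutations,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$threshold))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  #%d: %d cells, mass %.1f, p = %.4f\n",
                i, nrow(cl$cells), cl$mass, cl$p_value))
  }
  invisible(x)
}
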