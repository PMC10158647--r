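#' @keywords internal
"_PACKAGE"

# Run code with a local RNG state so generators are deterministic given their
# seed and never disturb the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a deterministic per-stage seed from a master seed
#'
#' Every stochastic stage of a run receives its own seed computed from the
#' master seed plus the stage name, so reproducibility needs no manual seed
#' bookkeeping. The result is always below 2^31.
#'
#' @param master_seed integer master seed.
#' @param stage stage name (character).
#' @return integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483647L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("`%s` must be a finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}
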