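#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  Every generator takes `seed` explicitly; nothing touches global
# RNG state outside this scope.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Small-sample corrected Akaike information criterion from a residual sum of
# squares, assuming iid Gaussian errors; `k` counts the mean-model parameters
# (the error variance is added here).  Comparable across models fitted to the
# same `n` observations and the same response scale.
aicc_from_ssr <- function(ssr, n, k) {
  k <- k + 1                      # + sigma^2
  if (n - k - 1 <= 0) return(Inf) # not enough d.o.f. for the correction
  n * log(max(ssr, .Machine$double.xmin) / n) + 2 * k +
    2 * k * (k + 1) / (n - k - 1)
}

logspace <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
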