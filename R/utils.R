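# Small numeric helpers shared across estimators.

# Moment coefficient of skewness, n-denominator. Returns 0 for a constant
# sample so a degenerate grid search is well defined.
moment_skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

# Weighted quantiles of a sample: left-continuous inverse of the weighted
# empirical CDF. probs outside the mass range clamp to the extremes.
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

weighted_mean <- function(x, w) sum(x * w) / sum(w)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_ds <- function(msg, class) {
  rlang::abort(msg, class = c(class, "dietshift_error"))
}
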