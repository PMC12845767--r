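# Independent oracles used across tests.

# truncated-normal mean by numerical quadrature (independent of the
# closed form in the package)
quad_truncnorm_mean <- function(mean, sd, lo, hi) {
  z <- stats::integrate(function(x) dnorm(x, mean, sd), lo, hi)$value
  stats::integrate(function(x) x * dnorm(x, mean, sd), lo, hi)$value / z
}

quad_truncnorm_sd <- function(mean, sd, lo, hi) {
  z <- stats::integrate(function(x) dnorm(x, mean, sd), lo, hi)$value
  m1 <- stats::integrate(function(x) x * dnorm(x, mean, sd), lo, hi)$value / z
  m2 <- stats::integrate(function(x) x^2 * dnorm(x, mean, sd), lo, hi)$value / z
  sqrt(m2 - m1^2)
}

# partial correlations of y with each column of X, controlling for the
# remaining columns, via the precision matrix of the rank-transformed data
# (a different algebraic route than the residual regressions in the package)
pcor_rank_oracle <- function(y, X) {
  R <- apply(cbind(y, X), 2, rank, ties.method = "average")
  P <- solve(stats::cor(R))
  vapply(seq_len(ncol(X)), function(j) {
    -P[1, j + 1] / sqrt(P[1, 1] * P[j + 1, j + 1])
  }, numeric(1))
}

default_params_cached <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- arsrisk::default_parameters()
    p
  }
})
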