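#' Distribution specifications
#'
#' A `dist_spec` is a small declarative description of a sampling
#' distribution used as a model input: a point mass, a uniform, a truncated
#' normal, or a lognormal, together with a unit tag. Every stochastic input
#' of the exposure model (environmental concentrations, transfer factors,
#' intakes, anthropometry) is expressed as a `dist_spec`, so a whole model
#' configuration is data, not code.
#'
#' Families and their parameters:
#' * `point`: `value`
#' * `uniform`: `lo`, `hi`
#' * `truncated_normal`: `mean`, `sd`, `lo`, `hi`
#' * `lognormal`: `geometric_mean`, `sigma_log` (sd of log concentration)
#'
#' @param value,lo,hi,mean,sd,geometric_mean,sigma_log Numeric parameters of
#'   the respective family.
#' @param units Character unit tag, e.g. `"mg/L"` or `"g/day"`.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_uniform(10.3, 22, units = "L/kg")              # bioaccumulation factor
#' dist_truncnorm(263, 872.8, 0, 2881.4, "g/day")      # rice intake
#' @name dist_spec
NULL

VALID_UNITS <- c("mg/L", "mg/kg", "ug/g", "ug/L", "g/day", "L/day",
                 "kg", "cm", "1")

new_dist_spec <- function(family, params, units) {
  stopifnot(is.character(family), length(family) == 1L)
  structure(list(family = family, params = params, units = units),
            class = "dist_spec")
}

check_units <- function(units) {
  if (!is.character(units) || length(units) != 1L) {
    abort("`units` must be a single string.")
  }
  if (!units %in% VALID_UNITS) {
    abort(sprintf("Unknown unit tag '%s'. Known units: %s.",
                  units, paste(VALID_UNITS, collapse = ", ")))
  }
  units
}

#' @rdname dist_spec
#' @export
dist_point <- function(value, units = "1") {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  new_dist_spec("point", list(value = value), check_units(units))
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(lo, hi, units = "1") {
  if (!is.finite(lo) || !is.finite(hi)) abort("`lo` and `hi` must be finite.")
  if (lo > hi) abort("Invalid uniform: `lo` must not exceed `hi`.")
  new_dist_spec("uniform", list(lo = lo, hi = hi), check_units(units))
}

#' @rdname dist_spec
#' @export
dist_truncnorm <- function(mean, sd, lo = -Inf, hi = Inf, units = "1") {
  if (!is.finite(mean)) abort("`mean` must be finite.")
  if (!is.finite(sd) || sd <= 0) abort("Invalid truncated normal: `sd` must be > 0.")
  if (lo >= hi) abort("Invalid truncated normal: `lo` must be < `hi`.")
  new_dist_spec("truncated_normal",
                list(mean = mean, sd = sd, lo = lo, hi = hi),
                check_units(units))
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(geometric_mean, sigma_log, units = "1") {
  if (!is.finite(geometric_mean) || geometric_mean <= 0) {
    abort("Invalid lognormal: `geometric_mean` must be > 0.")
  }
  if (!is.finite(sigma_log) || sigma_log < 0) {
    abort("Invalid lognormal: `sigma_log` must be >= 0.")
  }
  new_dist_spec("lognormal",
                list(geometric_mean = geometric_mean, sigma_log = sigma_log),
                check_units(units))
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- paste(names(x$params), signif(unlist(x$params), 6),
             sep = " = ", collapse = ", ")
  cat(sprintf("<dist_spec> %s(%s) [%s]\n", x$family, p, x$units))
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Support bounds of a distribution specification
#'
#' @param spec A [dist_spec].
#' @return Numeric vector `c(lo, hi)`; infinite where unbounded.
#' @export
dist_bounds <- function(spec) {
  stopifnot(is_dist_spec(spec))
  p <- spec$params
  switch(spec$family,
    point = c(p$value, p$value),
    uniform = c(p$lo, p$hi),
    truncated_normal = c(p$lo, p$hi),
    lognormal = c(0, Inf),
    abort(sprintf("Unknown distribution family '%s'.", spec$family))
  )
}

#' Analytic mean of a distribution specification
#'
#' Closed-form expectation for each supported family; used as the oracle
#' against which Monte Carlo sample means are checked.
#'
#' @param spec A [dist_spec].
#' @return The expectation, a length-one numeric.
#' @export
dist_mean <- function(spec) {
  stopifnot(is_dist_spec(spec))
  p <- spec$params
  switch(spec$family,
    point = p$value,
    uniform = (p$lo + p$hi) / 2,
    truncated_normal = truncated_normal_mean(p$mean, p$sd, p$lo, p$hi),
    lognormal = p$geometric_mean * exp(p$sigma_log^2 / 2),
    abort(sprintf("Unknown distribution family '%s'.", spec$family))
  )
}

#' Draw reproducible samples from a distribution specification
#'
#' Truncated normals are drawn by inverse-CDF: a uniform on
#' `[pnorm(a), pnorm(b)]` pushed through `qnorm`, which is exact, vectorised
#' and respects the bounds by construction.
#'
#' @param spec A [dist_spec].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer; when given, draws come from an isolated
#'   stream seeded with it and the caller's RNG state is untouched.
#' @return Numeric vector of length `n`, every value inside [dist_bounds()].
#' @examples
#' sample_dist(dist_point(1.791, "L/day"), 3)
#' sample_dist(dist_truncnorm(6.71, 4.5, 2.21, 13.66), 5, seed = 1)
#' @export
sample_dist <- function(spec, n, seed = NULL) {
  stopifnot(is_dist_spec(spec), is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, sample_dist(spec, n)))
  }
  p <- spec$params
  switch(spec$family,
    point = rep(p$value, n),
    uniform = runif(n, p$lo, p$hi),
    truncated_normal = rtruncnorm_inv(n, p$mean, p$sd, p$lo, p$hi),
    lognormal = {
      if (p$sigma_log == 0) rep(p$geometric_mean, n)
      else rlnorm(n, meanlog = log(p$geometric_mean), sdlog = p$sigma_log)
    },
    abort(sprintf("Unknown distribution family '%s'.", spec$family))
  )
}

# inverse-CDF truncated normal; parameters may be vectors (recycled to n)
rtruncnorm_inv <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  u <- plo + runif(n) * (phi - plo)
  x <- qnorm(u, mean, sd)
  pmin(pmax(x, lo), hi) # guard float spill at the edges
}

#' Analytic mean of a truncated normal distribution
#'
#' Standard closed form: for `a = (lo - mean)/sd`, `b = (hi - mean)/sd`,
#' the truncated mean is `mean + sd * (phi(a) - phi(b)) / (Phi(b) - Phi(a))`.
#' Infinite bounds are allowed.
#'
#' @param mean,sd Location and scale of the parent normal (`sd > 0`).
#' @param lo,hi Truncation bounds, `lo < hi`.
#' @return The expectation of the truncated distribution.
#' @examples
#' truncated_normal_mean(0, 1, 0, Inf)   # half-normal, sqrt(2/pi)
#' truncated_normal_mean(6.71, 4.5, 2.21, 13.66)
#' @export
truncated_normal_mean <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) abort("`sd` must be > 0.")
  if (lo >= hi) abort("Degenerate interval: `lo` must be < `hi`.")
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  if (z <= 0) abort("Truncation interval has zero probability mass.")
  mean + sd * (dnorm(a) - dnorm(b)) / z
}

#' Analytic standard deviation of a truncated normal distribution
#'
#' @inheritParams truncated_normal_mean
#' @return The standard deviation of the truncated distribution.
#' @export
truncated_normal_sd <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) abort("`sd` must be > 0.")
  if (lo >= hi) abort("Degenerate interval: `lo` must be < `hi`.")
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  if (z <= 0) abort("Truncation interval has zero probability mass.")
  ada <- if (is.finite(a)) a * dnorm(a) else 0
  bdb <- if (is.finite(b)) b * dnorm(b) else 0
  delta <- (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (ada - bdb) / z - delta^2)
  sqrt(v)
}

#' Calibrate a lognormal distribution to a printed concentration range
#'
#' Environmental trace-element concentrations are canonically right-skewed;
#' when a source reports only a `lo`-`hi` range, this builds the lognormal
#' whose central `coverage` interval has exactly those endpoints:
#' `geometric_mean = sqrt(lo * hi)` and
#' `sigma_log = log(hi / geometric_mean) / z`, with `z` the standard-normal
#' quantile of `(1 + coverage) / 2`.
#'
#' When the range is the observed minimum and maximum of `n` field samples,
#' a natural coverage is the Hazen plotting position of the extremes,
#' `1 - 1/n` (see [hazen_coverage()]); this is what the shipped default
#' drinking-water configuration uses.
#'
#' @param lo,hi Range endpoints, `0 < lo <= hi`.
#' @param coverage Central probability mass assigned to `[lo, hi]`,
#'   in (0, 1). Default 0.95.
#' @param units Unit tag for the returned spec.
#' @return A lognormal [dist_spec] whose quantiles at `(1 - coverage)/2` and
#'   `(1 + coverage)/2` equal `lo` and `hi`; the calibration inputs are kept
#'   in the `"calibration"` attribute.
#' @examples
#' calibrate_lognormal_from_range(0.000735, 0.11, units = "mg/L")
#' @export
calibrate_lognormal_from_range <- function(lo, hi, coverage = 0.95,
                                           units = "1") {
  if (!is.finite(lo) || lo <= 0) abort("Lognormal undefined: `lo` must be > 0.")
  if (!is.finite(hi) || hi < lo) abort("`hi` must be >= `lo`.")
  if (coverage <= 0 || coverage >= 1) abort("`coverage` must be in (0, 1).")
  gm <- sqrt(lo * hi)
  z <- qnorm((1 + coverage) / 2)
  sigma <- log(hi / gm) / z
  spec <- dist_lognormal(gm, sigma, units = units)
  attr(spec, "calibration") <- list(lo = lo, hi = hi, coverage = coverage)
  spec
}

#' Coverage of the sample extremes under Hazen plotting positions
#'
#' The observed minimum and maximum of `n` i.i.d. samples sit, under the
#' Hazen convention, at plotting positions `0.5/n` and `1 - 0.5/n`; the
#' central probability between them is `1 - 1/n`.
#'
#' @param n Number of field samples (>= 2).
#' @return Coverage in (0, 1) to pass to [calibrate_lognormal_from_range()].
#' @export
hazen_coverage <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  1 - 1 / n
}
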