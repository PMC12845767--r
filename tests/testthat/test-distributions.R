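test_that("point distributions return the constant", {
  expect_equal(sample_dist(dist_point(1.791, "L/day"), 3),
               c(1.791, 1.791, 1.791))
})

test_that("samplers respect their support bounds", {
  specs <- list(
    dist_uniform(10.3, 22),
    dist_truncnorm(263, 872.8, 0, 2881.4, "g/day"),
    dist_truncnorm(6.71, 4.5, 2.21, 13.66),
    dist_truncnorm(61.3, 9, 40, 155, "kg"),
    dist_lognormal(0.009, 1.0, "mg/L")
  )
  for (spec in specs) {
    x <- sample_dist(spec, 1e5, seed = 11)
    b <- dist_bounds(spec)
    expect_gte(min(x), b[1])
    expect_lte(max(x), b[2])
  }
})

test_that("same seed gives bit-identical draw sequences", {
  spec <- dist_truncnorm(59, 488.8, 0, 1525.4, "g/day")
  expect_identical(sample_dist(spec, 1000, seed = 5),
                   sample_dist(spec, 1000, seed = 5))
  expect_false(identical(sample_dist(spec, 1000, seed = 5),
                         sample_dist(spec, 1000, seed = 6)))
})

test_that("truncated-normal sample means match the quadrature oracle", {
  cases <- list(
    c(263, 872.8, 0, 2881.4),
    c(6.71, 4.5, 2.21, 13.66),
    c(8.5, 70.4, 0, 219.7),
    c(54.3, 8.5, 35, 145)
  )
  n <- 1e5
  for (cs in cases) {
    spec <- dist_truncnorm(cs[1], cs[2], cs[3], cs[4])
    x <- sample_dist(spec, n, seed = 17)
    m_oracle <- quad_truncnorm_mean(cs[1], cs[2], cs[3], cs[4])
    se <- quad_truncnorm_sd(cs[1], cs[2], cs[3], cs[4]) / sqrt(n)
    expect_lt(abs(mean(x) - m_oracle), 3 * se)
  }
})

test_that("truncated_normal_mean matches known closed forms and quadrature", {
  expect_equal(truncated_normal_mean(0, 1, -Inf, Inf), 0)
  expect_equal(truncated_normal_mean(0, 1, 0, Inf), sqrt(2 / pi))
  # seasonal multiplier of the fish concentration chain
  expect_equal(truncated_normal_mean(6.71, 4.5, 2.21, 13.66),
               quad_truncnorm_mean(6.71, 4.5, 2.21, 13.66),
               tolerance = 1e-8)
  # large-sample Monte Carlo cross-check
  x <- sample_dist(dist_truncnorm(6.71, 4.5, 2.21, 13.66), 1e6, seed = 3)
  se <- truncated_normal_sd(6.71, 4.5, 2.21, 13.66) / 1e3
  expect_lt(abs(mean(x) - truncated_normal_mean(6.71, 4.5, 2.21, 13.66)),
            3 * se)
})

test_that("truncated_normal_sd matches quadrature", {
  expect_equal(truncated_normal_sd(5.67, 3, 0, 14.67),
               quad_truncnorm_sd(5.67, 3, 0, 14.67), tolerance = 1e-7)
  expect_equal(truncated_normal_sd(0, 1, -Inf, Inf), 1)
})

test_that("dist_mean is the analytic expectation for every family", {
  expect_equal(dist_mean(dist_point(1.791)), 1.791)
  expect_equal(dist_mean(dist_uniform(10.3, 22)), 16.15)
  expect_equal(dist_mean(dist_truncnorm(5.67, 3, 0, 14.67)),
               quad_truncnorm_mean(5.67, 3, 0, 14.67), tolerance = 1e-8)
  gm <- 0.009
  expect_equal(dist_mean(dist_lognormal(gm, 1.2)), gm * exp(1.2^2 / 2))
})

test_that("invalid distribution parameters are rejected by name", {
  expect_error(dist_truncnorm(0, -1), "sd")
  expect_error(dist_truncnorm(0, 1, 5, 2), "lo")
  expect_error(dist_uniform(3, 1), "lo")
  expect_error(dist_lognormal(-1, 0.5), "geometric_mean")
  expect_error(dist_lognormal(1, -0.5), "sigma_log")
  expect_error(truncated_normal_mean(0, 1, 2, 2), "interval")
  expect_error(dist_uniform(0, 1, units = "furlongs"), "unit")
})

test_that("lognormal range calibration reproduces the closed-form oracle", {
  spec <- calibrate_lognormal_from_range(0.000735, 0.11, 0.95, "mg/L")
  # frozen from the closed form: gm = sqrt(lo*hi), sigma = log(hi/gm)/z(0.975)
  expect_equal(spec$params$geometric_mean, 0.008991662805, tolerance = 1e-9)
  expect_equal(spec$params$sigma_log, 1.277667647, tolerance = 1e-8)
})

test_that("calibrated lognormal quantiles reproduce the range endpoints", {
  cases <- list(c(0.000735, 0.11, 0.95), c(0.000735, 0.11, 1 - 1 / 72),
                c(0.5, 2, 0.5), c(1e-6, 1e-2, 0.99))
  for (cs in cases) {
    spec <- calibrate_lognormal_from_range(cs[1], cs[2], cs[3])
    p <- spec$params
    q <- qlnorm(c((1 - cs[3]) / 2, (1 + cs[3]) / 2),
                log(p$geometric_mean), p$sigma_log)
    expect_equal(q[1], cs[1], tolerance = 1e-6)
    expect_equal(q[2], cs[2], tolerance = 1e-6)
  }
})

test_that("degenerate range collapses to a point mass at the geometric mean", {
  eps <- 1e-12
  spec <- calibrate_lognormal_from_range(0.01, 0.01 + eps, 0.95)
  expect_lt(spec$params$sigma_log, 1e-8)
  x <- sample_dist(spec, 100, seed = 1)
  expect_equal(unique(round(x, 8)), 0.01)
  expect_error(calibrate_lognormal_from_range(0, 1), "lo")
  expect_error(calibrate_lognormal_from_range(0.001, 0.1, coverage = 1.2),
               "coverage")
})
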