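# small synthetic design with independent inputs and a known linear response
toy_design <- function(n = 4000, seed = 1, noise = 0) {
  withr::with_seed(seed, {
    d <- tibble::tibble(
      x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = runif(n)
    )
    d$total_dose <- 2 * d$x1 + d$x2 + noise * rnorm(n)
    d
  })
}

test_that("SRC recovers an identity regression", {
  d <- toy_design(2000, seed = 2)
  d$total_dose <- d$x1
  res <- suppressWarnings(src_sensitivity(d, inputs = c("x1", "x2", "x3", "x4")))
  expect_equal(res$src[res$input == "x1"], 1, tolerance = 1e-10)
  expect_true(all(abs(res$src[res$input != "x1"]) < 1e-10))
})

test_that("SRC matches the closed-form variance decomposition", {
  d <- toy_design(20000, seed = 3)
  res <- suppressWarnings(src_sensitivity(d, inputs = c("x1", "x2", "x3", "x4")))
  # y = 2 x1 + x2 with unit-variance inputs: SRCs 2/sqrt(5), 1/sqrt(5)
  expect_equal(res$src[res$input == "x1"], 2 / sqrt(5), tolerance = 0.02)
  expect_equal(res$src[res$input == "x2"], 1 / sqrt(5), tolerance = 0.02)
  expect_equal(res$src[res$input == "x1"] / res$src[res$input == "x2"], 2,
               tolerance = 0.05)
  # squared SRCs sum to ~R^2 (= 1 for the noise-free linear model); exact
  # only for orthogonal inputs, so allow finite-sample correlation slack
  expect_equal(sum(res$src^2), attr(res, "r_squared"), tolerance = 0.02)
})

test_that("PRCC is invariant under monotone transforms of an input", {
  d <- toy_design(1500, seed = 4, noise = 0.5)
  ins <- c("x1", "x2", "x3", "x4")
  r1 <- prcc_sensitivity(d, inputs = ins)
  d2 <- d
  d2$x1 <- exp(d2$x1)
  r2 <- prcc_sensitivity(d2, inputs = ins)
  expect_equal(r1$prcc, r2$prcc, tolerance = 1e-12)
})

test_that("PRCC matches the precision-matrix partial-correlation oracle", {
  d <- toy_design(5000, seed = 5, noise = 0.3)
  ins <- c("x1", "x2", "x3", "x4")
  res <- prcc_sensitivity(d, inputs = ins)
  oracle <- pcor_rank_oracle(d$total_dose, as.matrix(d[ins]))
  expect_equal(res$prcc, oracle, tolerance = 1e-8)
  expect_true(all(abs(res$prcc) <= 1))
})

test_that("PRCC p-values follow the documented t transform", {
  d <- toy_design(500, seed = 6, noise = 1)
  ins <- c("x1", "x2", "x3", "x4")
  res <- prcc_sensitivity(d, inputs = ins)
  df <- 500 - 2 - 3
  for (i in seq_len(nrow(res))) {
    tval <- res$prcc[i] * sqrt(df / (1 - res$prcc[i]^2))
    expect_equal(res$prcc_p[i], 2 * pt(-abs(tval), df), tolerance = 1e-12)
  }
})

test_that("a permuted input has a near-zero coefficient (negative control)", {
  n <- 5000
  run <- run_scenario("LB", n_iterations = n, seed = 77)
  design <- build_design_matrix(run)
  design$intake_clam <- withr::with_seed(78, sample(design$intake_clam))
  src <- src_sensitivity(design)
  prcc <- prcc_sensitivity(design)
  expect_lt(abs(src$src[src$input == "intake_clam"]), 3 / sqrt(n))
  expect_lt(abs(prcc$prcc[prcc$input == "intake_clam"]), 3 / sqrt(n))
})

test_that("degenerate designs are rejected with named columns", {
  d <- toy_design(200, seed = 7)
  d$x4 <- 1
  expect_error(src_sensitivity(d, inputs = c("x1", "x2", "x3", "x4")),
               "Constant.*x4")
  d <- toy_design(200, seed = 8)
  d$x4 <- 2 * d$x1
  expect_error(src_sensitivity(d, inputs = c("x1", "x2", "x3", "x4")),
               "collinear")
  expect_error(src_sensitivity(toy_design(10), inputs = c("x1", "x2", "x3", "x4"),
                               response = "missing_col"), "missing_col")
})

test_that("the full design matrix has the 18 model primitives", {
  run <- run_scenario("LB", n_iterations = 600, seed = 9)
  design <- build_design_matrix(run)
  expect_equal(setdiff(names(design), "total_dose"), arsrisk:::SENSITIVITY_INPUTS)
  expect_length(setdiff(names(design), "total_dose"), 18)
  expect_equal(design$total_dose, run$doses$total_dose)
})

test_that("run-level sensitivity behaves physically", {
  run <- run_scenario("LB", n_iterations = 4000, seed = 10)
  sens <- sensitivity_analysis(run)
  expect_equal(sort(sens$src_rank), 1:18)
  expect_equal(sort(sens$prcc_rank), 1:18)
  # dose ~ 1/BW forces a negative body-weight coefficient in both methods
  expect_lt(sens$src[sens$input == "body_weight"], 0)
  expect_lt(sens$prcc[sens$input == "body_weight"], 0)
  # SRC and PRCC agree in sign for clearly significant inputs
  strong <- abs(sens$prcc) > 0.1
  expect_true(all(sign(sens$src[strong]) == sign(sens$prcc[strong])))
})

test_that("tornado table orders by |coefficient| with alphabetical ties", {
  res <- tibble::tibble(
    input = c("b_in", "a_in", "c_in"),
    src = c(-0.5, 0.5, 0.1), src_p = c(0.01, 0.2, 0.7),
    prcc = c(-0.5, 0.5, 0.1), prcc_p = c(0.01, 0.2, 0.7)
  )
  tt <- tornado_table(res, "src")
  expect_equal(tt$input, c("a_in", "b_in", "c_in"))
  expect_equal(tt$significant, c(FALSE, TRUE, FALSE))
  run <- run_scenario("LB", n_iterations = 600, seed = 11)
  full <- tornado_table(sensitivity_analysis(run), "prcc")
  expect_equal(nrow(full), 18)
})
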