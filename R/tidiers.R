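#' Tidy a scenario run into a per-pathway summary
#'
#' @param x An `ias_run`.
#' @param ... Unused.
#' @return Tibble `pathway`, `mean_dose`, `percent`, `scenario`.
#' @export
tidy.ias_run <- function(x, ...) {
  x$contributions %>%
    mutate(scenario = x$scenario)
}

#' One-row summary of a scenario run
#'
#' @param x An `ias_run`.
#' @param ... Unused.
#' @return One-row tibble: scenario, n, seed, mean/sd/median/P5/P95 of the
#'   total dose, and the fractions of individuals with HQ > 1 and
#'   ECR > 1e-6.
#' @export
glance.ias_run <- function(x, ...) {
  s <- x$summary[x$summary$group == "all", ]
  tibble(
    scenario = x$scenario,
    n = x$n,
    seed = x$seed,
    mean_dose = s$mean,
    sd_dose = s$sd,
    median_dose = s$median,
    p5_dose = s$p5,
    p95_dose = s$p95,
    frac_hq_gt_1 = mean(x$risk$HQ > 1),
    frac_ecr_gt_1e6 = mean(x$risk$ECR > 1e-6)
  )
}

#' Tidy a sensitivity result into long method/coefficient form
#'
#' @param x An `ias_sensitivity` tibble.
#' @param ... Unused.
#' @return Tibble `input`, `method` (src/prcc), `coefficient`, `p_value`,
#'   `rank`, `scenario`.
#' @export
tidy.ias_sensitivity <- function(x, ...) {
  bind_rows(
    tibble(input = x$input, method = "src", coefficient = x$src,
           p_value = x$src_p, rank = x$src_rank),
    tibble(input = x$input, method = "prcc", coefficient = x$prcc,
           p_value = x$prcc_p, rank = x$prcc_rank)
  ) %>%
    mutate(scenario = x$scenario[1])
}

#' One-row summary of a sensitivity analysis
#'
#' @param x An `ias_sensitivity` tibble.
#' @param ... Unused.
#' @return One-row tibble: scenario, n, SRC regression R-squared, number of
#'   significant inputs per method at p < 0.05.
#' @export
glance.ias_sensitivity <- function(x, ...) {
  tibble(
    scenario = x$scenario[1],
    n = x$n[1],
    r_squared = attr(x, "r_squared") %||% NA_real_,
    n_significant_src = sum(x$src_p < 0.05),
    n_significant_prcc = sum(x$prcc_p < 0.05)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
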