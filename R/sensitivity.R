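#' Assemble the sensitivity design matrix
#'
#' Collects the 18 sampled primitive inputs of a run — four environmental
#' concentrations, the bioaccumulation factor, the dry-season multiplier,
#' the aquatic inorganic fraction, four transfer factors, six food intakes
#' and body weight — together with the total dose as response. The binary
#' season flag is not a continuous input and is excluded (its multiplier is
#' included); water intake and the terrestrial fraction are constants and
#' carry no variance.
#'
#' @param run An `ias_run` from [run_scenario()].
#' @return A tibble of 18 named input columns plus `total_dose`, row-aligned
#'   with the run's dose table.
#' @export
build_design_matrix <- function(run) {
  stopifnot(inherits(run, "ias_run"))
  conc <- run$concentrations
  pop <- run$population
  tbl <- tibble(
    water_As = conc$water_As,
    soil_As = conc$soil_As,
    lake_As = conc$lake_As,
    clam_total_As = conc$clam_total_As,
    BAF = conc$BAF,
    dry_season_multiplier = conc$dry_season_multiplier,
    aquatic_iAs_fraction = conc$aquatic_iAs_fraction,
    TF_rice = conc$tf_rice,
    TF_corn = conc$tf_corn,
    TF_vegetables = conc$tf_vegetables,
    TF_root = conc$tf_root_crops,
    intake_fish = pop$intake_fish,
    intake_clam = pop$intake_clam,
    intake_rice = pop$intake_rice,
    intake_corn = pop$intake_corn,
    intake_vegetables = pop$intake_vegetables,
    intake_root = pop$intake_root_crops,
    body_weight = pop$body_weight,
    total_dose = run$doses$total_dose
  )
  attr(tbl, "scenario") <- run$scenario
  tbl
}

SENSITIVITY_INPUTS <- c(
  "water_As", "soil_As", "lake_As", "clam_total_As", "BAF",
  "dry_season_multiplier", "aquatic_iAs_fraction",
  "TF_rice", "TF_corn", "TF_vegetables", "TF_root",
  "intake_fish", "intake_clam", "intake_rice", "intake_corn",
  "intake_vegetables", "intake_root", "body_weight")

check_design <- function(design, inputs, response) {
  missing <- setdiff(c(inputs, response), names(design))
  if (length(missing)) {
    abort(paste0("Design matrix is missing columns: ",
                 paste(missing, collapse = ", "), "."))
  }
  n <- nrow(design)
  if (n <= length(inputs) + 1) {
    abort("Need more rows than inputs + 1 for sensitivity analysis.")
  }
  X <- as.matrix(design[inputs])
  const <- inputs[apply(X, 2, function(v) sd(v) == 0)]
  if (length(const)) {
    abort(paste0("Constant input column(s): ",
                 paste(const, collapse = ", "), "."))
  }
  qrX <- qr(scale(X))
  if (qrX$rank < ncol(X)) {
    dropped <- inputs[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(dropped, collapse = ", "), "."))
  }
  X
}

#' Standardized regression coefficients
#'
#' Ordinary least squares of the standardized response on the standardized
#' inputs; coefficients are the SRCs, with two-sided p-values from the usual
#' t statistics. For a linear model with independent inputs, squared SRCs
#' approximate the variance fractions and sum to about R-squared.
#'
#' @param design Tibble with the input columns and a response column
#'   ([build_design_matrix()]).
#' @param inputs Character vector of input column names (default the 18
#'   model primitives).
#' @param response Response column name (default `"total_dose"`).
#' @return Tibble `input`, `src`, `src_p`, `src_rank` (rank 1 = largest
#'   |SRC|); the regression R-squared is attached as attribute `r_squared`.
#' @export
src_sensitivity <- function(design, inputs = SENSITIVITY_INPUTS,
                            response = "total_dose") {
  X <- check_design(design, inputs, response)
  y <- design[[response]]
  Z <- scale(X)
  zy <- as.numeric(scale(y))
  fit <- lm(zy ~ Z)
  cf <- summary(fit)$coefficients
  rows <- paste0("Z", inputs)
  out <- tibble(
    input = inputs,
    src = unname(cf[rows, "Estimate"]),
    src_p = unname(cf[rows, "Pr(>|t|)"])
  ) %>%
    mutate(src_rank = rank(-abs(.data$src), ties.method = "first"))
  attr(out, "r_squared") <- summary(fit)$r.squared
  out
}

#' Partial rank correlation coefficients
#'
#' Every column is rank-transformed (average ranks for ties); for each
#' input, the PRCC is the correlation between the residuals of the response
#' ranks and of that input's ranks, both regressed on all other inputs'
#' ranks. p-values use the t transform `t = r sqrt(df / (1 - r^2))` with
#' `df = n - 2 - k`, where `k = 17` is the number of controlled covariates.
#'
#' @inheritParams src_sensitivity
#' @return Tibble `input`, `prcc`, `prcc_p`, `prcc_rank`.
#' @export
prcc_sensitivity <- function(design, inputs = SENSITIVITY_INPUTS,
                             response = "total_dose") {
  check_design(design, inputs, response)
  n <- nrow(design)
  R <- apply(as.matrix(design[inputs]), 2, rank, ties.method = "average")
  ry <- rank(design[[response]], ties.method = "average")
  k <- length(inputs) - 1L
  df <- n - 2L - k
  res <- purrr::map_dfr(seq_along(inputs), function(j) {
    Zo <- cbind(1, R[, -j, drop = FALSE])
    ress <- stats::lm.fit(Zo, cbind(ry, R[, j]))$residuals
    r <- cor(ress[, 1], ress[, 2])
    tval <- r * sqrt(df / (1 - r^2))
    tibble(input = inputs[j], prcc = r,
           prcc_p = 2 * pt(-abs(tval), df))
  })
  res %>% mutate(prcc_rank = rank(-abs(.data$prcc), ties.method = "first"))
}

#' Global sensitivity analysis of the total dose
#'
#' Runs both sensitivity methods on a completed scenario run (or a design
#' matrix) and merges them into one table.
#'
#' @param x An `ias_run` or a design-matrix tibble.
#' @param inputs,response As in [src_sensitivity()].
#' @return A tibble of class `ias_sensitivity`: `input`, `src`, `src_p`,
#'   `src_rank`, `prcc`, `prcc_p`, `prcc_rank`, `scenario`, `n`.
#' @examples
#' run <- run_scenario("LB", n_iterations = 400, seed = 3)
#' sens <- sensitivity_analysis(run)
#' tornado_table(sens, method = "src")
#' @export
sensitivity_analysis <- function(x, inputs = SENSITIVITY_INPUTS,
                                 response = "total_dose") {
  design <- if (inherits(x, "ias_run")) build_design_matrix(x) else x
  scn <- attr(design, "scenario")
  src <- src_sensitivity(design, inputs, response)
  out <- left_join(src, prcc_sensitivity(design, inputs, response),
                   by = "input") %>%
    mutate(scenario = if (is.null(scn)) NA_character_ else scn,
           n = nrow(design))
  class(out) <- c("ias_sensitivity", class(out))
  attr(out, "r_squared") <- attr(src, "r_squared")
  out
}

#' Tornado ordering of sensitivity coefficients
#'
#' Sorts inputs by decreasing |coefficient| for one method, breaking ties
#' alphabetically, and flags significance at p < 0.05. All inputs are
#' retained regardless of significance.
#'
#' @param result An `ias_sensitivity` tibble (or any tibble with the
#'   relevant columns).
#' @param method `"src"` or `"prcc"`.
#' @return Tibble `input`, `coefficient`, `p_value`, `significant`, sorted
#'   for tornado plotting.
#' @export
tornado_table <- function(result, method = c("src", "prcc")) {
  method <- match.arg(method)
  pcol <- paste0(method, "_p")
  out <- tibble(
    input = result$input,
    coefficient = result[[method]],
    p_value = result[[pcol]]
  ) %>%
    mutate(significant = .data$p_value < 0.05) %>%
    arrange(desc(abs(.data$coefficient)), .data$input)
  out
}
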