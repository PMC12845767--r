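#' Non-cancer hazard quotient
#'
#' HQ = dose / RfD with the U.S. EPA oral reference dose for inorganic
#' arsenic (default 0.06 ug/kg-day). HQ > 1 flags potential non-cancer
#' concern.
#'
#' @param dose Daily dose, ug/kg bw/day (vector).
#' @param rfd Oral reference dose, ug/kg-day.
#' @return HQ, dimensionless.
#' @examples
#' hazard_quotient(0.06)  # exactly 1
#' hazard_quotient(3.0)   # 50
#' @export
hazard_quotient <- function(dose, rfd = 0.06) {
  if (rfd <= 0) abort("`rfd` must be > 0.")
  if (any(dose < 0)) abort("Doses must be >= 0.")
  dose / rfd
}

#' Lifetime excess cancer risk
#'
#' ECR = dose x CSF with the oral cancer slope factor for inorganic arsenic
#' (default 0.032 per ug/kg-day). The linear low-dose extrapolation is
#' reported as computed, without capping at 1; values near or above 1 mark
#' the breakdown of the linear approximation, not a literal probability.
#'
#' @param dose Daily dose, ug/kg bw/day (vector).
#' @param csf Cancer slope factor, (ug/kg-day)^-1.
#' @return ECR, dimensionless lifetime risk.
#' @export
excess_cancer_risk <- function(dose, csf = 0.032) {
  if (csf <= 0) abort("`csf` must be > 0.")
  if (any(dose < 0)) abort("Doses must be >= 0.")
  dose * csf
}

#' Per-individual risk table
#'
#' @param doses Dose tibble from [compute_pathway_doses()].
#' @param risk List with `rfd` and `csf` (defaults 0.06 and 0.032).
#' @return A tibble `iteration`, `scenario`, `sex`, `subgroup`,
#'   `total_dose`, `HQ`, `ECR`. By construction `ECR / HQ = rfd * csf`
#'   (0.00192 at the defaults) for every row.
#' @export
risk_table <- function(doses, risk = list(rfd = 0.06, csf = 0.032)) {
  tibble(
    iteration = doses$iteration,
    scenario = doses$scenario,
    sex = doses$sex,
    subgroup = doses$subgroup,
    total_dose = doses$total_dose,
    HQ = hazard_quotient(doses$total_dose, risk$rfd),
    ECR = excess_cancer_risk(doses$total_dose, risk$csf)
  )
}

#' Risk exceedance fractions and cumulative distribution grid
#'
#' Exceedance is counted with strict inequality (HQ > threshold,
#' ECR > threshold). Alongside the exceedance table, an empirical CDF grid
#' (default 1001 points, equally spaced probabilities) is returned for
#' plotting and export.
#'
#' @param risk Risk tibble from [risk_table()].
#' @param hq_thresholds HQ thresholds, ascending (default 1).
#' @param ecr_thresholds ECR thresholds, ascending (default 1e-6 and 1e-4,
#'   the conventional acceptable-risk benchmark range).
#' @param grid_points Number of CDF grid points (default 1001).
#' @return A list with `exceedance` (tibble `metric`, `threshold`,
#'   `fraction`) and `cdf` (tibble `prob`, `HQ`, `ECR` of quantiles).
#' @export
exceedance_summary <- function(risk, hq_thresholds = 1,
                               ecr_thresholds = c(1e-6, 1e-4),
                               grid_points = 1001) {
  if (nrow(risk) < 1) abort("Empty risk table.")
  if (is.unsorted(hq_thresholds) || is.unsorted(ecr_thresholds)) {
    abort("Thresholds must be sorted ascending.")
  }
  frac_gt <- function(x, t) mean(x > t)
  exceedance <- bind_rows(
    tibble(metric = "HQ", threshold = hq_thresholds,
           fraction = vapply(hq_thresholds, frac_gt, numeric(1),
                             x = risk$HQ)),
    tibble(metric = "ECR", threshold = ecr_thresholds,
           fraction = vapply(ecr_thresholds, frac_gt, numeric(1),
                             x = risk$ECR))
  )
  probs <- seq(0, 1, length.out = grid_points)
  cdf <- tibble(
    prob = probs,
    HQ = unname(quantile(risk$HQ, probs, type = 7)),
    ECR = unname(quantile(risk$ECR, probs, type = 7))
  )
  list(exceedance = exceedance, cdf = cdf)
}
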