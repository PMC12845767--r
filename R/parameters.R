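#' Default model parameterisation
#'
#' Builds the full input parameterisation of the exposure model: post-eruption
#' environmental arsenic concentrations, soil-to-crop transfer factors,
#' food and water intake distributions, sex-specific anthropometry, and the
#' toxicological constants used for risk characterisation.
#'
#' Concentration inputs:
#' * drinking water: total As lognormal calibrated so the measured range
#'   0.000735-0.11 mg/L (72 well samples) matches the central
#'   `water_coverage` interval; used directly as iAs (fraction 1).
#' * soil: total As uniform on 1.92-7.91 mg/kg.
#' * lake water: total As uniform on 0.005-0.0097 mg/L.
#' * clam: dry-weight total As truncated normal, mean 5.67, SD 3 mg/kg,
#'   truncated to `[0, mean + 3 SD]`.
#' * fish: derived as lake water x BAF (uniform 10.3-22 L/kg), with a
#'   dry-season multiplier TruncNorm(6.71, 4.50) on [2.21, 13.66] and an
#'   aquatic inorganic fraction uniform on 0.117-0.142 (shared with clams).
#'
#' Intakes are truncated normals bounded below at 0 g/day and above at
#' mean + 3 SD; drinking-water intake is fixed at 1.791 L/day.
#'
#' @param water_coverage Central coverage assigned to the drinking-water
#'   concentration range when calibrating its lognormal. Default
#'   `hazen_coverage(72)`, i.e. the range is read as the observed extremes of
#'   the 72 field samples.
#' @return A named list of class `ias_parameters` with elements
#'   `environment`, `transfer_factors`, `intakes`, `anthropometry`, `risk`.
#' @examples
#' params <- default_parameters()
#' params$environment$BAF
#' @export
default_parameters <- function(water_coverage = hazen_coverage(72)) {
  params <- list(
    environment = list(
      water_As = calibrate_lognormal_from_range(
        0.000735, 0.11, coverage = water_coverage, units = "mg/L"),
      soil_As = dist_uniform(1.92, 7.91, units = "mg/kg"),
      lake_As = dist_uniform(0.005, 0.0097, units = "mg/L"),
      clam_total_As_dw = dist_truncnorm(5.67, 3, 0, 5.67 + 3 * 3,
                                        units = "mg/kg"),
      BAF = dist_uniform(10.3, 22, units = "1"),
      dry_season_multiplier = dist_truncnorm(6.71, 4.50, 2.21, 13.66,
                                             units = "1"),
      aquatic_iAs_fraction = dist_uniform(0.117, 0.142, units = "1")
    ),
    transfer_factors = list(
      rice = dist_uniform(0.006, 0.036, units = "1"),
      corn = dist_uniform(0.005, 0.027, units = "1"),
      vegetables = dist_uniform(0.0003, 0.028, units = "1"),
      root_crops = dist_uniform(0.0028, 0.007, units = "1")
    ),
    intakes = list(
      fish = intake_truncnorm(59, 488.8),
      clam = intake_truncnorm(8.5, 70.4),
      rice = intake_truncnorm(263, 872.8),
      corn = intake_truncnorm(6, 541.2),
      vegetables = intake_truncnorm(58, 680.8),
      root_crops = intake_truncnorm(7, 104.7),
      water = dist_point(1.791, units = "L/day")
    ),
    anthropometry = list(
      prop_male = 0.506,
      male = list(
        body_weight = dist_truncnorm(61.3, 9.0, 40, 155, units = "kg"),
        height = dist_truncnorm(163.0, 6.5, 60, 220, units = "cm")
      ),
      female = list(
        body_weight = dist_truncnorm(54.3, 8.5, 35, 145, units = "kg"),
        height = dist_truncnorm(154.0, 6.0, 55, 210, units = "cm")
      )
    ),
    risk = list(rfd = 0.06, csf = 0.032)
  )
  class(params) <- "ias_parameters"
  validate_parameters(params)
}

# intake convention: lower bound 0 g/day, upper bound mean + 3 SD
intake_truncnorm <- function(mean, sd) {
  dist_truncnorm(mean, sd, 0, mean + 3 * sd, units = "g/day")
}

#' Validate a model parameterisation
#'
#' Checks structural completeness and the domain invariants (positive
#' concentrations, aquatic iAs fraction within 0.117-0.142, intake bounds at
#' 0 and mean + 3 SD, male proportion in (0, 1), positive RfD and CSF).
#'
#' @param params An `ias_parameters` list as built by [default_parameters()]
#'   or [read_parameters()].
#' @return `params`, invisibly unchanged, or an error naming the offending
#'   field.
#' @export
validate_parameters <- function(params) {
  need <- c("environment", "transfer_factors", "intakes", "anthropometry",
            "risk")
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    abort(paste0("Parameter set is missing: ",
                 paste(missing, collapse = ", "), "."))
  }
  env_need <- c("water_As", "soil_As", "lake_As", "clam_total_As_dw", "BAF",
                "dry_season_multiplier", "aquatic_iAs_fraction")
  check_fields(params$environment, env_need, "environment")
  check_fields(params$transfer_factors, CROPS, "transfer_factors")
  check_fields(params$intakes, c(FOODS, "water"), "intakes")
  for (grp in c("environment", "transfer_factors", "intakes")) {
    for (nm in names(params[[grp]])) {
      if (!is_dist_spec(params[[grp]][[nm]])) {
        abort(sprintf("Field %s$%s is not a dist_spec.", grp, nm))
      }
    }
  }
  frac <- dist_bounds(params$environment$aquatic_iAs_fraction)
  if (frac[1] < 0.117 - 1e-12 || frac[2] > 0.142 + 1e-12) {
    abort("environment$aquatic_iAs_fraction must lie within [0.117, 0.142].")
  }
  for (m in c("soil_As", "lake_As", "clam_total_As_dw")) {
    if (dist_bounds(params$environment[[m]])[1] < 0) {
      abort(sprintf("environment$%s admits negative concentrations.", m))
    }
  }
  for (food in FOODS) {
    sp <- params$intakes[[food]]
    if (sp$family == "truncated_normal") {
      p <- sp$params
      if (p$lo != 0) abort(sprintf("intakes$%s lower bound must be 0.", food))
      if (abs(p$hi - (p$mean + 3 * p$sd)) > 1e-9) {
        abort(sprintf("intakes$%s upper bound must be mean + 3*sd.", food))
      }
    }
  }
  an <- params$anthropometry
  if (!is.numeric(an$prop_male) || an$prop_male <= 0 || an$prop_male >= 1) {
    abort("anthropometry$prop_male must be in (0, 1).")
  }
  for (sx in c("male", "female")) {
    check_fields(an[[sx]], c("body_weight", "height"),
                 paste0("anthropometry$", sx))
  }
  if (params$risk$rfd <= 0) abort("risk$rfd must be > 0.")
  if (params$risk$csf <= 0) abort("risk$csf must be > 0.")
  invisible(params)
}

check_fields <- function(x, need, where) {
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(sprintf("%s is missing: %s.", where, paste(missing, collapse = ", ")))
  }
}

#' Scenario configuration
#'
#' The two published exposure scenarios differ only in the inorganic fraction
#' assumed for terrestrial crops: 50% for the lower bound (LB) and 90% for
#' the upper bound (UB). Aquatic foods use the sampled aquatic fraction and
#' drinking water is counted as fully inorganic in both scenarios.
#'
#' @param scenario `"LB"` or `"UB"`.
#' @param n_iterations Number of simulated individuals (default 10000).
#' @param seed Integer master seed.
#' @param subgroup_modifiers Optional named list of intake multipliers
#'   (names among fish, clam, rice, corn, vegetables, root_crops) applied to
#'   the pregnant subgroup; see [apply_subgroup_modifiers()].
#' @param pregnant_fraction Fraction of females flagged as pregnant
#'   (default 0: no subgroup).
#' @return A list of class `ias_scenario`.
#' @export
scenario_config <- function(scenario = c("LB", "UB"), n_iterations = 10000,
                            seed = 1L, subgroup_modifiers = NULL,
                            pregnant_fraction = 0) {
  scenario <- match.arg(scenario)
  if (!is.numeric(n_iterations) || length(n_iterations) != 1L ||
      n_iterations < 1 || n_iterations != floor(n_iterations)) {
    abort("`n_iterations` must be a positive integer.")
  }
  if (!is.null(subgroup_modifiers)) {
    bad <- setdiff(names(subgroup_modifiers), FOODS)
    if (length(bad)) {
      abort(paste0("Unknown food in subgroup_modifiers: ",
                   paste(bad, collapse = ", "), "."))
    }
    if (any(unlist(subgroup_modifiers) < 0)) {
      abort("subgroup_modifiers must be >= 0.")
    }
  }
  structure(list(scenario = scenario,
                 terrestrial_iAs_fraction = terrestrial_fraction(scenario),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 subgroup_modifiers = subgroup_modifiers,
                 pregnant_fraction = pregnant_fraction),
            class = "ias_scenario")
}

terrestrial_fraction <- function(scenario) {
  switch(scenario, LB = 0.5, UB = 0.9,
         abort("`scenario` must be 'LB' or 'UB'."))
}

#' Read and write model parameter files
#'
#' The full parameterisation round-trips through a YAML file whose schema
#' mirrors the in-memory structure: each input is a mapping with `family`,
#' its family-specific parameters, and a `units` tag. A lognormal entry may
#' instead carry a `calibrate_from_range` mapping (`lo`, `hi`, `coverage`)
#' which is resolved with [calibrate_lognormal_from_range()] on load.
#' The shipped default file is at
#' `system.file("extdata", "default_parameters.yaml", package = "arsrisk")`.
#'
#' @param path File path.
#' @param params An `ias_parameters` list.
#' @return `read_parameters()` returns a validated `ias_parameters` list;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  parse_group <- function(group) {
    lapply(group, parse_dist_entry)
  }
  params <- list(
    environment = parse_group(raw$environment),
    transfer_factors = parse_group(raw$transfer_factors),
    intakes = parse_group(raw$intakes),
    anthropometry = list(
      prop_male = raw$anthropometry$prop_male,
      male = parse_group(raw$anthropometry$male),
      female = parse_group(raw$anthropometry$female)
    ),
    risk = list(rfd = raw$risk$rfd, csf = raw$risk$csf)
  )
  class(params) <- "ias_parameters"
  validate_parameters(params)
  params
}

parse_dist_entry <- function(e) {
  if (is.null(e$family)) abort("Config entry lacks a `family` field.")
  units <- if (is.null(e$units)) "1" else e$units
  switch(e$family,
    point = dist_point(e$value, units),
    uniform = dist_uniform(e$lo, e$hi, units),
    truncated_normal = dist_truncnorm(e$mean, e$sd, e$lo, e$hi, units),
    lognormal = {
      if (!is.null(e$calibrate_from_range)) {
        cr <- e$calibrate_from_range
        calibrate_lognormal_from_range(cr$lo, cr$hi, cr$coverage, units)
      } else {
        dist_lognormal(e$geometric_mean, e$sigma_log, units)
      }
    },
    abort(sprintf("Unknown distribution family '%s' in config.", e$family))
  )
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  ser_group <- function(group) lapply(group, ser_dist)
  out <- list(
    environment = ser_group(params$environment),
    transfer_factors = ser_group(params$transfer_factors),
    intakes = ser_group(params$intakes),
    anthropometry = list(
      prop_male = params$anthropometry$prop_male,
      male = ser_group(params$anthropometry$male),
      female = ser_group(params$anthropometry$female)
    ),
    risk = params$risk
  )
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

ser_dist <- function(spec) {
  cal <- attr(spec, "calibration")
  if (spec$family == "lognormal" && !is.null(cal)) {
    return(list(family = "lognormal", calibrate_from_range = cal,
                units = spec$units))
  }
  c(list(family = spec$family), spec$params, list(units = spec$units))
}
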