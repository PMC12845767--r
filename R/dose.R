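#' Per-individual pathway and aggregate daily iAs doses
#'
#' Implements the aggregate dose equation: for individual j and medium i,
#' dose_ij = C_ij x IR_ij / BW_j, with C in ug/g (foods) or ug/L (water), IR
#' in g/day or L/day, BW in kg; the total is the sum over media, in
#' ug/kg bw/day.
#'
#' @param pop Population tibble ([sample_population()]).
#' @param conc Concentration tibble ([sample_concentrations()]), same row
#'   count and iteration order.
#' @return A tibble with `iteration`, `scenario`, `sex`, `subgroup`,
#'   `season`, one `dose_<pathway>` column per pathway (fish, clam, rice,
#'   corn, vegetables, root_crops, drinking_water) and `total_dose`, all in
#'   ug/kg bw/day.
#' @examples
#' params <- default_parameters()
#' pop <- sample_population(100, params, seed = 1)
#' conc <- sample_concentrations(params, "LB", 100, seed = 1)
#' doses <- compute_pathway_doses(pop, conc)
#' @export
compute_pathway_doses <- function(pop, conc) {
  if (nrow(pop) != nrow(conc)) {
    abort(sprintf("Row mismatch: population has %d rows, concentrations %d.",
                  nrow(pop), nrow(conc)))
  }
  if (any(pop$body_weight <= 0)) abort("Body weights must be > 0.")
  scenario <- attr(conc, "scenario")
  doses <- tibble(
    iteration = pop$iteration,
    scenario = if (is.null(scenario)) NA_character_ else scenario,
    sex = pop$sex,
    subgroup = pop$subgroup,
    season = conc$season
  )
  for (food in FOODS) {
    doses[[paste0("dose_", food)]] <-
      conc[[paste0("conc_", food)]] * pop[[paste0("intake_", food)]] /
      pop$body_weight
  }
  doses$dose_drinking_water <-
    conc$conc_drinking_water * pop$water_intake / pop$body_weight
  doses$total_dose <- rowSums(doses[paste0("dose_", PATHWAYS)])
  attr(doses, "seed") <- attr(conc, "seed")
  doses
}

#' Pathway contributions to the population mean dose
#'
#' Contribution of pathway i is 100 x mean(dose_i) / mean(total dose) — the
#' ratio of means, the convention behind pie-chart pathway shares — so the
#' percentages sum to 100 by construction.
#'
#' @param doses Dose tibble from [compute_pathway_doses()].
#' @return A tibble `pathway`, `mean_dose` (ug/kg bw/day), `percent`, in
#'   descending order of contribution.
#' @export
contribution_summary <- function(doses) {
  if (nrow(doses) < 1) abort("Empty dose table.")
  mean_total <- mean(doses$total_dose)
  if (mean_total <= 0) abort("Mean total dose is zero; contributions undefined.")
  out <- tibble(
    pathway = PATHWAYS,
    mean_dose = vapply(PATHWAYS, function(p) {
      mean(doses[[paste0("dose_", p)]])
    }, numeric(1), USE.NAMES = FALSE)
  ) %>%
    mutate(percent = 100 * .data$mean_dose / mean_total) %>%
    arrange(desc(.data$percent))
  attr(out, "scenario") <- doses$scenario[1]
  out
}

#' Summary statistics of the total dose by subgroup
#'
#' @param doses Dose tibble.
#' @return A tibble with one row for the whole population (`"all"`), one per
#'   sex, and one per non-general subgroup: n, mean, sd, median, 5th and
#'   95th percentiles of total dose.
#' @export
dose_summary <- function(doses) {
  one <- function(label, x) {
    tibble(group = label, n = length(x), mean = mean(x), sd = sd(x),
           median = median(x),
           p5 = unname(quantile(x, 0.05)), p95 = unname(quantile(x, 0.95)))
  }
  out <- bind_rows(
    one("all", doses$total_dose),
    one("male", doses$total_dose[doses$sex == "male"]),
    one("female", doses$total_dose[doses$sex == "female"])
  )
  for (sub in setdiff(unique(doses$subgroup), "general")) {
    out <- bind_rows(out, one(sub, doses$total_dose[doses$subgroup == sub]))
  }
  out
}

#' Run one full exposure scenario
#'
#' Orchestrates a complete Monte Carlo run: samples the population and the
#' concentration table under a common master seed, applies any pregnant
#' subgroup and intake modifiers, computes pathway and total doses, the
#' risk table, pathway contributions and dose summaries. Deterministic for
#' a given seed.
#'
#' @param scenario `"LB"` or `"UB"`.
#' @param n_iterations Number of simulated individuals (default 10000).
#' @param seed Master seed.
#' @param params Model parameterisation ([default_parameters()]).
#' @param pregnant_fraction Fraction of females flagged pregnant (default 0).
#' @param subgroup_modifiers Optional intake multipliers for the pregnant
#'   subgroup ([apply_subgroup_modifiers()]).
#' @param season_split Probability of dry-season exposure (default 0.5).
#' @return An object of class `ias_run`: a list with `scenario`, `n`,
#'   `seed`, `population`, `concentrations`, `doses`, `risk`,
#'   `contributions`, `summary`, `params`.
#' @examples
#' run <- run_scenario("LB", n_iterations = 500, seed = 7)
#' run$contributions
#' glance(run)
#' @export
run_scenario <- function(scenario = c("LB", "UB"), n_iterations = 10000,
                         seed = 1L, params = default_parameters(),
                         pregnant_fraction = 0, subgroup_modifiers = NULL,
                         season_split = 0.5) {
  scenario <- match.arg(scenario)
  cfg <- scenario_config(scenario, n_iterations, seed,
                         subgroup_modifiers, pregnant_fraction)
  pop <- sample_population(cfg$n_iterations, params, cfg$seed)
  if (pregnant_fraction > 0) {
    pop <- assign_pregnant(pop, pregnant_fraction, cfg$seed)
    if (!is.null(subgroup_modifiers)) {
      pop <- apply_subgroup_modifiers(pop, subgroup_modifiers)
    }
  }
  conc <- sample_concentrations(params, scenario, cfg$n_iterations,
                                cfg$seed, season_split)
  doses <- compute_pathway_doses(pop, conc)
  risk <- risk_table(doses, params$risk)
  structure(list(
    scenario = scenario,
    n = cfg$n_iterations,
    seed = cfg$seed,
    population = pop,
    concentrations = conc,
    doses = doses,
    risk = risk,
    contributions = contribution_summary(doses),
    summary = dose_summary(doses),
    params = params
  ), class = "ias_run")
}

#' Run both exposure scenarios under a common seed
#'
#' @inheritParams run_scenario
#' @param scenarios Character vector of scenarios (default both).
#' @return A named list of `ias_run` objects.
#' @export
run_scenarios <- function(scenarios = c("LB", "UB"), n_iterations = 10000,
                          seed = 1L, params = default_parameters(), ...) {
  setNames(lapply(scenarios, function(s) {
    run_scenario(s, n_iterations, seed, params, ...)
  }), scenarios)
}

#' @export
print.ias_run <- function(x, ...) {
  s <- x$summary[x$summary$group == "all", ]
  cat(sprintf("<ias_run> scenario %s, n = %d, seed = %d\n",
              x$scenario, x$n, x$seed))
  cat(sprintf("  total iAs dose: %.2f +/- %.2f ug/kg bw/day (median %.2f, P5 %.2f, P95 %.2f)\n",
              s$mean, s$sd, s$median, s$p5, s$p95))
  top <- head(x$contributions, 3)
  cat(sprintf("  top pathways: %s\n",
              paste(sprintf("%s %.1f%%", top$pathway, top$percent),
                    collapse = ", ")))
  invisible(x)
}
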