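#' Sample the simulated population
#'
#' Generates one row per simulated individual: sex (Bernoulli with the
#' census male proportion), body weight and height from sex-matched
#' truncated normals, independent food intakes, and the fixed drinking-water
#' intake. Height is carried for completeness but enters no dose
#' computation. Each variable is drawn on its own named random stream of the
#' master seed; body weight uses one uniform draw per row pushed through the
#' sex-specific inverse CDF, so the draw sequence is stable under changes to
#' the sex split.
#'
#' @param n Number of individuals.
#' @param params An `ias_parameters` list ([default_parameters()]).
#' @param seed Master seed.
#' @return A tibble: `iteration`, `sex`, `body_weight` (kg), `height` (cm),
#'   `intake_fish`, `intake_clam`, `intake_rice`, `intake_corn`,
#'   `intake_vegetables`, `intake_root_crops` (g/day),
#'   `water_intake` (L/day), `subgroup` (all `"general"`).
#' @examples
#' pop <- sample_population(100, default_parameters(), seed = 1)
#' @export
sample_population <- function(n, params = default_parameters(), seed = 1L) {
  validate_parameters(params)
  stopifnot(n >= 1)
  n <- as.integer(n)
  an <- params$anthropometry

  sex <- with_stream(seed, "sex",
                     ifelse(runif(n) < an$prop_male, "male", "female"))
  body_weight <- draw_sex_matched(n, sex, an$male$body_weight,
                                  an$female$body_weight, seed, "body_weight")
  height <- draw_sex_matched(n, sex, an$male$height, an$female$height,
                             seed, "height")

  pop <- tibble(
    iteration = seq_len(n),
    sex = sex,
    body_weight = body_weight,
    height = height
  )
  for (food in FOODS) {
    pop[[paste0("intake_", food)]] <-
      with_stream(seed, paste0("intake_", food),
                  sample_dist(params$intakes[[food]], n))
  }
  pop$water_intake <- sample_dist(params$intakes$water, n)
  pop$subgroup <- "general"
  attr(pop, "seed") <- as.integer(seed)
  pop
}

# one uniform per row, pushed through the sex-specific truncated-normal
# inverse CDF
draw_sex_matched <- function(n, sex, spec_m, spec_f, seed, stream) {
  pm <- spec_m$params
  pf <- spec_f$params
  male <- sex == "male"
  mean_ <- ifelse(male, pm$mean, pf$mean)
  sd_ <- ifelse(male, pm$sd, pf$sd)
  lo_ <- ifelse(male, pm$lo, pf$lo)
  hi_ <- ifelse(male, pm$hi, pf$hi)
  with_stream(seed, stream, rtruncnorm_inv(n, mean_, sd_, lo_, hi_))
}

#' Flag a pregnant subgroup within the simulated population
#'
#' Marks a random fraction of female individuals as `"pregnant"`. Their
#' anthropometrics are already drawn from the female distributions; intake
#' adjustments, if any, are applied separately with
#' [apply_subgroup_modifiers()].
#'
#' @param pop A population tibble from [sample_population()].
#' @param fraction Fraction of females to flag, in `[0, 1]`.
#' @param seed Master seed (stream `"pregnant"`).
#' @return The population tibble with an updated `subgroup` column.
#' @export
assign_pregnant <- function(pop, fraction, seed = 1L) {
  stopifnot(is.numeric(fraction), fraction >= 0, fraction <= 1)
  if (fraction == 0) return(pop)
  female <- pop$sex == "female"
  flag <- with_stream(seed, "pregnant", runif(nrow(pop)) < fraction)
  pop$subgroup[female & flag] <- "pregnant"
  pop
}

#' Scale intakes of a population subgroup
#'
#' Multiplies the intake columns of rows carrying `label` by food-specific
#' factors; all other rows are untouched. This is the mechanism by which
#' alternative consumption profiles (e.g. reduced seafood intake during
#' pregnancy) enter the model; no default profile is asserted.
#'
#' @param pop A population tibble.
#' @param modifiers Named list or vector of non-negative multipliers; names
#'   among `fish`, `clam`, `rice`, `corn`, `vegetables`, `root_crops`.
#' @param label Subgroup label to modify (default `"pregnant"`).
#' @return The modified population tibble.
#' @examples
#' pop <- sample_population(50, seed = 1)
#' pop$subgroup[1:5] <- "pregnant"
#' apply_subgroup_modifiers(pop, list(fish = 0.5, clam = 0.5))
#' @export
apply_subgroup_modifiers <- function(pop, modifiers, label = "pregnant") {
  if (is.null(modifiers) || !length(modifiers)) return(pop)
  bad <- setdiff(names(modifiers), FOODS)
  if (length(bad)) {
    abort(paste0("Unknown food key in modifiers: ",
                 paste(bad, collapse = ", "), "."))
  }
  if (any(unlist(modifiers) < 0)) abort("Modifiers must be >= 0.")
  rows <- pop$subgroup == label
  for (food in names(modifiers)) {
    col <- paste0("intake_", food)
    pop[[col]][rows] <- pop[[col]][rows] * modifiers[[food]]
  }
  pop
}
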