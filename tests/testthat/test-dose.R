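# minimal aligned population/concentration pair with controllable values
make_pair <- function(n = 4, conc_value = 0, intake_value = 0, bw = 50) {
  foods <- c("fish", "clam", "rice", "corn", "vegetables", "root_crops")
  pop <- tibble::tibble(iteration = seq_len(n), sex = "female",
                        body_weight = bw, height = 150)
  for (f in foods) pop[[paste0("intake_", f)]] <- intake_value
  pop$water_intake <- 0
  pop$subgroup <- "general"
  conc <- tibble::tibble(iteration = seq_len(n), season = "rainy")
  for (f in foods) conc[[paste0("conc_", f)]] <- conc_value
  conc$conc_drinking_water <- 0
  attr(conc, "scenario") <- "LB"
  list(pop = pop, conc = conc)
}

test_that("dose equation reduces to C x IR / BW", {
  pr <- make_pair(n = 3)
  pr$conc$conc_rice <- 0.1
  pr$pop$intake_rice <- 100
  d <- compute_pathway_doses(pr$pop, pr$conc)
  expect_equal(d$dose_rice, rep(0.2, 3))
  expect_equal(d$total_dose, rep(0.2, 3))
})

test_that("zero concentrations give zero doses", {
  pr <- make_pair(n = 5, intake_value = 100)
  d <- compute_pathway_doses(pr$pop, pr$conc)
  expect_true(all(as.matrix(d[grep("^dose_", names(d))]) == 0))
  expect_true(all(d$total_dose == 0))
})

test_that("total dose is the exact row sum of pathway doses", {
  p <- default_params_cached()
  pop <- sample_population(2000, p, seed = 5)
  conc <- sample_concentrations(p, "UB", 2000, seed = 5)
  d <- compute_pathway_doses(pop, conc)
  expect_equal(d$total_dose, rowSums(d[grep("^dose_", names(d))]))
  expect_true(all(as.matrix(d[grep("^dose_", names(d))]) >= 0))
})

test_that("row mismatch between tables is an error", {
  pr <- make_pair(n = 4)
  expect_error(compute_pathway_doses(pr$pop[1:3, ], pr$conc), "mismatch")
})

test_that("doses are scale-equivariant in the concentrations", {
  p <- default_params_cached()
  pop <- sample_population(300, p, seed = 7)
  conc <- sample_concentrations(p, "LB", 300, seed = 7)
  d1 <- compute_pathway_doses(pop, conc)
  conc2 <- conc
  for (cl in grep("^conc_", names(conc2), value = TRUE)) {
    conc2[[cl]] <- 3 * conc2[[cl]]
  }
  d2 <- compute_pathway_doses(pop, conc2)
  expect_equal(d2$total_dose, 3 * d1$total_dose)
})

test_that("equal pathway means give equal contributions summing to 100", {
  pr <- make_pair(n = 10)
  pr$conc$conc_fish <- 0.2
  pr$conc$conc_rice <- 0.2
  pr$pop$intake_fish <- 50
  pr$pop$intake_rice <- 50
  d <- compute_pathway_doses(pr$pop, pr$conc)
  contrib <- contribution_summary(d)
  expect_equal(sum(contrib$percent), 100, tolerance = 1e-10)
  expect_equal(contrib$percent[contrib$pathway == "fish"], 50)
  expect_equal(contrib$percent[contrib$pathway == "rice"], 50)
})

test_that("contributions of an all-zero dose table are an error", {
  pr <- make_pair(n = 3)
  d <- compute_pathway_doses(pr$pop, pr$conc)
  expect_error(contribution_summary(d), "zero")
})

test_that("a scenario run is deterministic given its seed", {
  a <- run_scenario("LB", n_iterations = 400, seed = 99)
  b <- run_scenario("LB", n_iterations = 400, seed = 99)
  expect_equal(a$doses, b$doses)
  expect_equal(a$contributions, b$contributions)
})

test_that("upper bound dominates lower bound individual-by-individual", {
  lb <- run_scenario("LB", n_iterations = 2000, seed = 14)
  ub <- run_scenario("UB", n_iterations = 2000, seed = 14)
  expect_true(all(ub$doses$total_dose >= lb$doses$total_dose))
  # the difference is exactly 0.8 x the LB terrestrial-crop dose sum
  crop_cols <- paste0("dose_", c("rice", "corn", "vegetables", "root_crops"))
  expect_equal(ub$doses$total_dose - lb$doses$total_dose,
               0.8 * rowSums(lb$doses[crop_cols]), tolerance = 1e-12)
})

test_that("dose summary reports population and subgroup statistics", {
  run <- run_scenario("LB", n_iterations = 1500, seed = 2,
                      pregnant_fraction = 0.2,
                      subgroup_modifiers = list(fish = 0.5, clam = 0.5))
  s <- run$summary
  expect_setequal(s$group, c("all", "male", "female", "pregnant"))
  expect_true(all(s$p5 <= s$median & s$median <= s$p95))
  expect_equal(s$n[s$group == "all"], 1500)
  g <- glance(run)
  expect_equal(g$mean_dose, mean(run$doses$total_dose))
  expect_equal(tidy(run)$scenario, rep("LB", 7))
})
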