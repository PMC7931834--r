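cfg <- default_config()

test_that("per-test unit costs are the exact component sums", {
  expect_equal(unit_test_cost("plasma", cfg$unit_costs), 18.40)
  expect_equal(unit_test_cost("dbs", cfg$unit_costs), 18.93)
  expect_equal(unit_test_cost("psc", cfg$unit_costs), 23.01)
  expect_equal(unit_test_cost(specimen_unit_cost("psc", 2.72, 0.47, 17.54)), 20.73)
  expect_error(unit_test_cost("urine", cfg$unit_costs), "no unit cost")
})

test_that("scenario costs reprice the published volumes to within a few dollars", {
  vols <- data.frame(specimen = "plasma", total = 930982)
  c1 <- scenario_costs(vols, cfg$unit_costs, 3.65, 3264509, visits = 931011)
  expect_equal(c1$plasma_testing, 17130067, tolerance = 1e-6)  # printed 17,130,067
  expect_equal(c1$dried_testing, 0)
  expect_equal(c1$system_total,
               c1$plasma_testing + c1$facility_visits + c1$transport)

  c2 <- scenario_costs(data.frame(specimen = "psc", total = 296308),
                       cfg$unit_costs, 3.65, 3637168)
  expect_equal(c2$dried_testing, 6818046, tolerance = 1e-6)  # printed 6,818,046

  c0 <- scenario_costs(data.frame(specimen = "plasma", total = 0),
                       cfg$unit_costs, 3.65, 1234)
  expect_equal(c0$system_total, 1234)
})

test_that("system cost is additive over partitioned volumes", {
  part1 <- data.frame(specimen = c("plasma", "dbs"), total = c(1000, 200))
  part2 <- data.frame(specimen = c("plasma", "psc"), total = c(500, 300))
  joint <- data.frame(specimen = c("plasma", "dbs", "psc"), total = c(1500, 200, 300))
  a <- scenario_costs(part1, cfg$unit_costs, 3.65, 0)
  b <- scenario_costs(part2, cfg$unit_costs, 3.65, 0)
  ab <- scenario_costs(joint, cfg$unit_costs, 3.65, 0)
  expect_equal(a$system_total + b$system_total, ab$system_total)
})

test_that("system cost strictly increases in every unit cost and in transport", {
  vols <- data.frame(specimen = c("plasma", "psc"), total = c(1000, 500))
  base <- scenario_costs(vols, cfg$unit_costs, 3.65, 100)$system_total
  set.seed(8)
  for (i in 1:20) {
    uc <- cfg$unit_costs
    bump <- runif(1, 0.01, 5)
    comp <- sample(c("consumables", "collection_overhead", "lab_analysis"), 1)
    sp <- sample(c("plasma", "psc"), 1)
    uc[[sp]][[comp]] <- uc[[sp]][[comp]] + bump
    expect_gt(scenario_costs(vols, uc, 3.65, 100)$system_total, base)
  }
  expect_gt(scenario_costs(vols, cfg$unit_costs, 3.65, 101)$system_total, base)
  expect_gt(scenario_costs(vols, cfg$unit_costs, 3.66, 100)$system_total, base)
})

test_that("cost ratios divide system cost by access and correct counts", {
  r <- cost_ratios(list(system_total = 23792767), 814066, 795342)
  expect_equal(round_half_away(r[["cost_per_result"]], 2), 29.23)
  expect_equal(round_half_away(r[["cost_per_correct"]], 2), 29.92)
  expect_gte(r[["cost_per_correct"]], r[["cost_per_result"]])

  r1 <- cost_ratios(list(system_total = 42), 1, 1)
  expect_equal(unname(r1), c(42, 42))
  expect_error(cost_ratios(list(system_total = 1), 0, 1), "zero")
  expect_error(cost_ratios(list(system_total = 1), 1, 0), "zero")
})
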