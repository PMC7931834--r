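cfg <- default_config()

test_that("one-way sweeps evaluate the metric at low, baseline and high", {
  m <- scenario_metric("plasma_psc", "cost_per_correct")  # anchored mode
  s <- one_way_sensitivity(cfg, "unit_costs.psc.consumables", 2.5, 7.5, m)
  expect_equal(unname(s$values), c(2.5, 5.0, 7.5))
  # baseline reproduces the published partial-PSC cost per correct result
  expect_equal(round_half_away(s$metric[["baseline"]], 2), 31.62)
  expect_lt(s$metric[["low"]], s$metric[["baseline"]])
  expect_gt(s$metric[["high"]], s$metric[["baseline"]])

  # degenerate range: all three evaluations coincide
  s0 <- one_way_sensitivity(cfg, "unit_costs.psc.consumables", 5, 5, m)
  expect_equal(unname(s0$metric), rep(s0$metric[["baseline"]], 3))

  expect_error(one_way_sensitivity(cfg, "unit_costs.psc.consumables", 7, 2, m),
               "low.*high")
  expect_error(one_way_sensitivity(cfg, "unit_costs.rna.consumables", 1, 2, m),
               "not found")
})

test_that("cost per correct falls monotonically as DBS specificity rises", {
  m <- scenario_metric("plasma_dbs", "cost_per_correct", mode = "model")
  grid <- seq(0.90, 0.99, by = 0.03)
  vals <- vapply(grid, function(v)
    m(cfg_set(cfg, "assays.dbs_capctm.specificity", v)), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("two-way grids are consistent with one-way sweeps and monotone", {
  m <- scenario_metric("plasma_dbs", "cost_per_correct", mode = "model")
  g_se <- c(0.90, 0.948, 0.98)
  g_sp <- c(0.90, 0.939, 0.98)
  tw <- two_way_sensitivity(cfg, "assays.dbs_capctm.sensitivity",
                            "assays.dbs_capctm.specificity", g_se, g_sp, m)
  expect_equal(dim(tw$metric), c(3L, 3L))
  # monotone decreasing along each axis (better assay, cheaper correct result)
  expect_true(all(apply(tw$metric, 1, diff) < 0))
  expect_true(all(apply(tw$metric, 2, diff) < 0))

  # the row at baseline specificity equals the one-way sensitivity sweep
  ow <- one_way_sensitivity(cfg, "assays.dbs_capctm.sensitivity",
                            g_se[1], g_se[3], m)
  expect_equal(unname(tw$metric[, 2]), unname(ow$metric))

  # 1x1 grid at the baselines is the baseline metric
  tw1 <- two_way_sensitivity(cfg, "assays.dbs_capctm.sensitivity",
                             "assays.dbs_capctm.specificity",
                             0.948, 0.939, m)
  expect_equal(unname(tw1$metric[1, 1]), m(cfg))
})

test_that("threshold solving recovers a linear root to tolerance", {
  # metric linear in the parameter with a known root at the bracket midpoint
  lin <- function(c) cfg_get(c, "unit_costs.psc.consumables") - 2.5
  thr <- threshold_solve(cfg, "unit_costs.psc.consumables", lin, c(0, 5), tol = 1e-9)
  expect_equal(thr$value, 2.5, tolerance = 1e-9)
  expect_lt(thr$residual, 1e-9)

  expect_error(threshold_solve(cfg, "unit_costs.psc.consumables", lin, c(3, 5)),
               "no sign change.*0\\.5.*2\\.5")
})

test_that("PSC kit break-even prices match the published sensitivity analysis", {
  gap_correct <- scenario_gap_metric("plasma_psc", "plasma_dbs", "cost_per_correct")
  thr1 <- threshold_solve(cfg, "unit_costs.psc.consumables", gap_correct, c(0, 5))
  expect_equal(thr1$value, 2.72, tolerance = 0.01)

  gap_result <- scenario_gap_metric("plasma_psc", "plasma_dbs", "cost_per_result")
  thr2 <- threshold_solve(cfg, "unit_costs.psc.consumables", gap_result, c(0, 5))
  expect_equal(thr2$value, 1.72, tolerance = 0.01)

  # at the break-even price the two scenarios' metrics agree to the cent
  expect_lt(thr1$residual, 0.005)
  expect_lt(thr2$residual, 0.005)
})

test_that("sensitivity evaluation is side-effect free", {
  before <- vlcea:::object_hash(unclass(cfg))
  m <- scenario_metric("plasma_psc", "cost_per_correct")
  invisible(one_way_sensitivity(cfg, "unit_costs.psc.consumables", 1, 9, m))
  invisible(threshold_solve(cfg, "unit_costs.psc.consumables",
                            scenario_gap_metric("plasma_psc", "plasma_dbs"), c(0, 5)))
  expect_identical(vlcea:::object_hash(unclass(cfg)), before)
})
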