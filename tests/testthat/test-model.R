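cfg <- default_config()

test_that("the pipeline produces five scenario outcomes and a league table", {
  fit <- vl_model(cfg, mode = "model")
  expect_s3_class(fit, "vl_model")
  expect_length(fit$outcomes, 5)
  expect_named(fit$outcomes, c("plasma_only", "plasma_dbs", "plasma_psc",
                               "dbs_only", "psc_only"))
  expect_s3_class(fit$cea, "vl_cea_table")
  expect_true("icer" %in% names(fit$cea))
  d <- as.data.frame(fit)
  expect_identical(nrow(d), 5L)
  expect_true(all(d$system_cost == d$dried_testing + d$plasma_testing +
                    d$facility_visits + d$transport))
  expect_true(all(d$cost_per_correct >= d$cost_per_result))
})

test_that("a single-scenario config runs without a CEA table", {
  one <- cfg
  one$scenarios <- cfg$scenarios[1]
  fit <- vl_model(one, mode = "model")
  expect_length(fit$outcomes, 1)
  expect_null(fit$cea)
})

test_that("stage failures report the scenario and stage", {
  broken <- cfg
  broken$visit_transport$transport$partial <- NULL
  expect_error(vl_model(broken, mode = "model"),
               "scenario plasma_dbs, stage pipeline")
})

test_that("re-running with the same config and seed is byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- run_pipeline(cfg, out_dir = d1, mode = "model")
  f2 <- run_pipeline(cfg, out_dir = d2, mode = "model")
  for (f in c("scenario_outcomes.csv", "cea_table.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  m1$timestamp <- m2$timestamp <- NULL
  expect_identical(m1, m2)
  expect_identical(f1$manifest$config_hash, f2$manifest$config_hash)
})

test_that("rendered tables carry identical numbers in every format", {
  fit <- vl_model(cfg, mode = "golden")
  md <- render_table(fit, "markdown")
  csv <- render_table(fit, "csv")
  tsv <- render_table(fit, "tsv")
  expect_error(render_table(fit, "latex"))

  # golden mode shows the published ratio rows
  expect_match(csv, "Cost per patient with a VL result,29.23,", fixed = TRUE)
  expect_match(csv, "29.92")
  expect_match(md, "\\| 29\\.23 \\|")
  # the base scenario's CER cell is the published "..." placeholder
  avg_row <- grep("Average cost", strsplit(csv, "\n")[[1]], value = TRUE)
  expect_match(avg_row, "^[^,]+,\\.\\.\\.")

  strip <- function(s) unlist(regmatches(s, gregexpr("[0-9]+(\\.[0-9]+)?", s)))
  expect_identical(strip(csv), strip(tsv))
  expect_setequal(strip(gsub("---", "", md)), strip(csv))
})

test_that("anchored mode reprices published volumes from the cost inputs", {
  fit <- vl_model(cfg, mode = "anchored")
  o <- fit$outcomes$plasma_only
  expect_equal(o$access$total_patients, 814066)
  expect_equal(o$costs$plasma_testing, 930982 * 18.40)
  expect_equal(o$costs$facility_visits, 931011 * 3.65)
  expect_equal(round_half_away(o$cost_per_result, 2), 29.23)

  # repricing responds to a changed unit cost; golden mode does not
  cheap <- cfg_set(cfg, "unit_costs.psc.consumables", 2.72)
  fa <- vl_model(cheap, mode = "anchored")
  fg <- vl_model(cheap, mode = "golden")
  expect_lt(fa$outcomes$plasma_psc$costs$system_total,
            vl_model(cfg, mode = "anchored")$outcomes$plasma_psc$costs$system_total)
  expect_equal(fg$outcomes$plasma_psc$costs$system_total,
               vl_model(cfg, mode = "golden")$outcomes$plasma_psc$costs$system_total)
})
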