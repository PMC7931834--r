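#' Run the viral-load scale-up cost-outcomes model
#'
#' The main entry point. For every scenario in the configuration it chains
#' the pipeline — facility access, effective assay performance under the
#' platform mix, screen-positivity and confirmatory test volumes, correct
#' results, component costs, cost ratios — then ranks scenarios by
#' incremental cost-effectiveness with dominance classification.
#'
#' Three run modes:
#' \describe{
#'   \item{`"model"`}{everything computed from primitives: the facility
#'     panel, access multipliers, assay performance, calibrated failure
#'     prevalence and unit costs.}
#'   \item{`"anchored"`}{patient and test volumes pinned to the published
#'     base-case table ([table3_printed()]); cost components re-priced from
#'     the configuration's unit, visit and transport costs. This isolates
#'     price questions (sensitivity and break-even analysis) from the
#'     under-determined parts of the volume model.}
#'   \item{`"golden"`}{volumes *and* component costs pinned to the published
#'     table; only ratios and the CEA ranking are recomputed. Used for
#'     arithmetic-identity checks.}
#' }
#'
#' @param config a `vl_config` (default [default_config()]).
#' @param panel a [vl_panel]; default [zambia_panel()] seeded from
#'   `config$seed`. Ignored by the anchored/golden modes.
#' @param mode `"model"`, `"anchored"` or `"golden"`.
#' @param correctness_model override for `config$epi$correctness_model`.
#' @return object of class `vl_model`: list with `outcomes` (one
#'   [vl_outcome] per scenario), `cea` (a `vl_cea_table`), `config`, `mode`
#'   and `manifest` (config hash, seed, version, timestamp).
#' @export
#' @examples
#' fit <- vl_model()
#' summary(fit)
vl_model <- function(config = default_config(), panel = NULL,
                     mode = c("model", "anchored", "golden"),
                     correctness_model = NULL) {
  mode <- match.arg(mode)
  if (!is.null(correctness_model))
    config$epi$correctness_model <- match.arg(correctness_model,
                                              c("product", "prevalence_weighted"))
  if (is.null(panel)) panel <- zambia_panel(seed = config$seed)

  outcomes <- lapply(config$scenarios, function(spec) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("scenario %s, stage %s: %s", spec$name, what, conditionMessage(e)),
             call. = FALSE))
    }
    if (mode == "model")
      stage("pipeline", outcome_model(config, panel, spec))
    else
      stage("pipeline", outcome_pinned(config, spec, pin_costs = (mode == "golden")))
  })
  names(outcomes) <- vapply(outcomes, function(o) o$scenario, character(1))

  cea <- if (length(outcomes) >= 2) incremental_analysis(outcomes) else NULL
  manifest <- list(config_hash = object_hash(unclass(config)),
                   seed = config$seed, mode = mode,
                   version = as.character(utils::packageVersion("vlcea")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  structure(list(outcomes = outcomes, cea = cea, config = config,
                 panel = panel, mode = mode, manifest = manifest),
            class = "vl_model")
}

#' Scenario outcome container
#'
#' One column of the results table: the access result, test volumes, correct
#' results, cost breakdown and the two cost ratios for a single scenario.
#' Built by [vl_model()]; rarely constructed directly.
#'
#' @name vl_outcome
NULL

new_outcome <- function(scenario, access, volumes, correct, costs) {
  ratios <- cost_ratios(costs, access$total_patients, correct$correct)
  structure(list(scenario = scenario, access = access, volumes = volumes,
                 correct = correct, costs = costs,
                 cost_per_result = unname(ratios["cost_per_result"]),
                 cost_per_correct = unname(ratios["cost_per_correct"])),
            class = "vl_outcome")
}

outcome_model <- function(config, panel, spec) {
  access <- annual_access(panel, spec, config$multipliers)
  perf <- scenario_performance(config, spec)
  p <- config$epi$failure_prevalence
  q <- lapply(perf, function(pf) positivity_rate(p, pf))
  volumes <- test_volumes(access, q)
  correct <- correct_results(access, perf, p, config$epi$correctness_model)
  transport <- config$visit_transport$transport[[spec$transport_key]]
  costs <- scenario_costs(volumes, config$unit_costs,
                          config$visit_transport$visit_cost, transport)
  new_outcome(spec$name, access, volumes, correct, costs)
}

outcome_pinned <- function(config, spec, pin_costs) {
  t3 <- table3_printed()
  row <- t3[t3$scenario == spec$name, ]
  check_that(nrow(row) == 1,
             "scenario '%s' has no published base-case row; use mode = \"model\"",
             spec$name)
  access <- structure(list(scenario = spec$name, cells = NULL,
                           total_patients = row$access,
                           facilities_reached = row$facilities),
                      class = "vl_access")
  by_sp <- data.frame(specimen = "plasma", initial = NA_real_,
                      confirmatory = NA_real_, total = row$plasma_tests,
                      q = NA_real_, stringsAsFactors = FALSE)
  if (!is.na(row$dried_specimen))
    by_sp <- rbind(by_sp, data.frame(specimen = row$dried_specimen,
                                     initial = NA_real_, confirmatory = NA_real_,
                                     total = row$dried_tests, q = NA_real_))
  volumes <- structure(list(scenario = spec$name, by_specimen = by_sp,
                            initial = NA_real_, confirmatory = NA_real_,
                            total = sum(by_sp$total)),
                       class = "vl_volumes")
  correct <- structure(list(scenario = spec$name, correct = row$correct,
                            by_cell = NULL, model_used = "published"),
                       class = "vl_correct")
  costs <- if (pin_costs) {
    structure(list(dried_testing = row$dried_cost, plasma_testing = row$plasma_cost,
                   facility_visits = row$visit_cost, transport = row$transport_cost,
                   visits = row$visits,
                   system_total = row$dried_cost + row$plasma_cost +
                     row$visit_cost + row$transport_cost),
              class = "vl_costs")
  } else {
    scenario_costs(volumes, config$unit_costs, config$visit_transport$visit_cost,
                   config$visit_transport$transport[[spec$transport_key]],
                   visits = row$visits)
  }
  new_outcome(spec$name, access, volumes, correct, costs)
}

#' @export
print.vl_model <- function(x, ...) {
  cat(sprintf("<vl_model> %d scenarios, mode \"%s\"\n", length(x$outcomes), x$mode))
  for (o in x$outcomes)
    cat(sprintf("  %-12s access %9s  correct %9s  cost %12s  $/correct %6.2f\n",
                o$scenario, fmt_money(o$access$total_patients),
                fmt_money(o$correct$correct), fmt_money(o$costs$system_total),
                o$cost_per_correct))
  invisible(x)
}

#' @export
summary.vl_model <- function(object, ...) {
  cat(sprintf("Viral-load scale-up cost-outcomes model (mode \"%s\")\n", object$mode))
  cat(sprintf("Config %s, seed %d, version %s\n\n",
              substr(object$manifest$config_hash, 1, 8), object$manifest$seed,
              object$manifest$version))
  print(object$cea)
  base <- object$outcomes[[1]]
  alts <- object$outcomes[-1]
  if (length(alts)) {
    inc <- vapply(alts, function(o) access_increase(base$access, o$access), numeric(1))
    cat(sprintf("\nAccess vs %s: %s\n", base$scenario,
                paste(sprintf("%s %+.0f%%", names(alts), round_half_away(inc)),
                      collapse = ", ")))
  }
  invisible(object)
}

#' Scenario outcomes as a data frame
#'
#' @param x a `vl_model`.
#' @param ... unused.
#' @return data frame with one row per scenario: access, facilities,
#'   correct results, component costs, system cost and the cost ratios.
#' @export
as.data.frame.vl_model <- function(x, ...) {
  do.call(rbind, lapply(x$outcomes, function(o) data.frame(
    scenario = o$scenario,
    access = o$access$total_patients,
    facilities = o$access$facilities_reached,
    correct = o$correct$correct,
    total_tests = o$volumes$total,
    dried_testing = o$costs$dried_testing,
    plasma_testing = o$costs$plasma_testing,
    facility_visits = o$costs$facility_visits,
    transport = o$costs$transport,
    system_cost = o$costs$system_total,
    cost_per_result = o$cost_per_result,
    cost_per_correct = o$cost_per_correct,
    row.names = NULL, stringsAsFactors = FALSE)))
}

#' Render the results table
#'
#' Rows in the published layout: access, facilities reached, correct
#' results, dried/plasma test volumes and costs, visits, transport, system
#' cost, the two cost ratios, average CERs and frontier ICERs. Money totals
#' are rounded to whole USD, ratios to 2 decimals; empty cells render as
#' `"..."`. CSV, TSV and markdown carry identical numeric content.
#'
#' @param x a `vl_model`.
#' @param format `"csv"`, `"tsv"` or `"markdown"`.
#' @return a single string (the rendered table).
#' @export
render_table <- function(x, format = c("csv", "tsv", "markdown")) {
  format <- match.arg(format)
  outs <- x$outcomes
  cea <- x$cea
  num <- function(v) ifelse(is.na(v), "...", fmt_money(v))
  rat <- function(v) ifelse(is.na(v), "...", sprintf("%.2f", round_half_away(v, 2)))
  col <- function(o) {
    nmc <- if (!is.null(cea)) {
      r <- cea[cea$scenario == o$scenario, ]
      c(rat(r$avg_cer),
        if (r$status == "undominated") rat(r$icer) else gsub("_", " ", r$status))
    } else c("...", "...")
    dried <- sum(o$volumes$by_specimen$total[o$volumes$by_specimen$specimen %in%
                                               dried_specimens])
    plasma <- sum(o$volumes$by_specimen$total[o$volumes$by_specimen$specimen == "plasma"])
    c(num(o$access$total_patients), num(o$access$facilities_reached),
      num(round_half_away(o$correct$correct)),
      num(dried), num(round_half_away(o$costs$dried_testing)),
      num(plasma), num(round_half_away(o$costs$plasma_testing)),
      num(o$costs$visits), num(round_half_away(o$costs$facility_visits)),
      num(round_half_away(o$costs$transport)),
      num(round_half_away(o$costs$system_total)),
      rat(o$cost_per_result), rat(o$cost_per_correct), nmc)
  }
  rows <- c("Patients accessing VL tests/y", "ART facilities reached",
            "Patients with correct VL results",
            "VLs on dried specimens", "Dried specimen cost (USD)",
            "VLs on plasma specimens", "Plasma specimen cost (USD)",
            "Facility visits required", "Facility visit cost (USD)",
            "Transport cost (USD)", "Annual system cost (USD)",
            "Cost per patient with a VL result",
            "Cost per patient with correct VL results",
            "Average cost per additional correct result vs base",
            "Incremental cost per additional correct result")
  m <- cbind(rows, sapply(outs, col))
  colnames(m) <- c("quantity", names(outs))
  sep <- switch(format, csv = ",", tsv = "\t", markdown = " | ")
  body <- apply(m, 1, paste, collapse = sep)
  header <- paste(colnames(m), collapse = sep)
  if (format == "markdown") {
    header <- paste0("| ", header, " |")
    body <- paste0("| ", body, " |")
    rule <- paste0("|", paste(rep("---", ncol(m)), collapse = "|"), "|")
    paste(c(header, rule, body), collapse = "\n")
  } else {
    paste(c(header, gsub('"', "", body)), collapse = "\n")
  }
}

#' Run the full pipeline and write machine-readable outputs
#'
#' Convenience wrapper around [vl_model()] that writes
#' `scenario_outcomes.csv`, `cea_table.csv` and `manifest.json` to a
#' directory. Re-running with the same config and seed produces
#' byte-identical CSVs (the manifest differs only in its timestamp).
#'
#' @param config a `vl_config`.
#' @param out_dir output directory (created if missing).
#' @param ... passed to [vl_model()].
#' @return the `vl_model`, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir = ".", ...) {
  fit <- vl_model(config, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(out_dir, "scenario_outcomes.csv")
  f2 <- file.path(out_dir, "cea_table.csv")
  f3 <- file.path(out_dir, "manifest.json")
  utils::write.csv(as.data.frame(fit), f1, row.names = FALSE)
  utils::write.csv(as.data.frame(fit$cea), f2, row.names = FALSE)
  fit$manifest$files <- basename(c(f1, f2, f3))
  jsonlite::write_json(fit$manifest, f3, auto_unbox = TRUE, pretty = TRUE)
  invisible(fit)
}
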