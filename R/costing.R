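#' Total unit cost per viral-load test for a specimen
#'
#' Sum of the three cost components: collection consumables, collection
#' staff/equipment/overhead, and laboratory analysis. A single lab-analysis
#' cost applies per specimen type regardless of platform.
#'
#' @param specimen specimen name, or a [specimen_unit_cost()] directly.
#' @param unit_costs named list of [specimen_unit_cost()] (ignored when the
#'   first argument is already a `specimen_unit_cost`).
#' @return USD per test.
#' @export
#' @examples
#' cfg <- default_config()
#' unit_test_cost("plasma", cfg$unit_costs)  # 18.40
#' unit_test_cost("psc", cfg$unit_costs)     # 23.01
unit_test_cost <- function(specimen, unit_costs = NULL) {
  u <- if (inherits(specimen, "specimen_unit_cost")) specimen else unit_costs[[specimen]]
  check_that(!is.null(u), "unit_test_cost: no unit cost registered for specimen '%s'",
             as.character(specimen)[1])
  u$consumables + u$collection_overhead + u$lab_analysis
}

dried_specimens <- c("dbs", "psc")

#' Annual system cost of a scenario
#'
#' Four components: dried-specimen testing (tests x unit cost), plasma
#' testing (tests x unit cost), facility visits for results (one visit per
#' test performed, at the visit unit cost), and the scenario's annual
#' transport-network cost. The system total is the exact sum of the four.
#'
#' @param volumes a `vl_volumes` from [test_volumes()], or a data frame with
#'   columns `specimen` and `total`.
#' @param unit_costs named list of [specimen_unit_cost()].
#' @param visit_cost USD per facility visit.
#' @param transport annual transport cost (USD) for this scenario.
#' @param visits optional visit count override (defaults to total tests).
#' @return object of class `vl_costs`: `dried_testing`, `plasma_testing`,
#'   `facility_visits`, `transport`, `system_total`, plus the visit count.
#' @export
scenario_costs <- function(volumes, unit_costs, visit_cost, transport,
                           visits = NULL) {
  by_sp <- if (inherits(volumes, "vl_volumes")) volumes$by_specimen else volumes
  check_that(all(by_sp$total >= 0), "scenario_costs: negative test volume")
  check_that(is_nonneg(transport), "scenario_costs: transport cost missing or negative")
  testing <- vapply(seq_len(nrow(by_sp)), function(i)
    by_sp$total[i] * unit_test_cost(by_sp$specimen[i], unit_costs), numeric(1))
  dried <- sum(testing[by_sp$specimen %in% dried_specimens])
  plasma <- sum(testing[by_sp$specimen == "plasma"])
  if (is.null(visits)) visits <- sum(by_sp$total)
  visit_total <- visits * visit_cost
  structure(list(dried_testing = dried, plasma_testing = plasma,
                 facility_visits = visit_total, transport = transport,
                 visits = visits,
                 system_total = dried + plasma + visit_total + transport),
            class = "vl_costs")
}

#' @export
print.vl_costs <- function(x, ...) {
  cat("<vl_costs> USD/year\n")
  cat(sprintf("  dried testing    %14s\n", fmt_money(x$dried_testing)))
  cat(sprintf("  plasma testing   %14s\n", fmt_money(x$plasma_testing)))
  cat(sprintf("  facility visits  %14s\n", fmt_money(x$facility_visits)))
  cat(sprintf("  transport        %14s\n", fmt_money(x$transport)))
  cat(sprintf("  system total     %14s\n", fmt_money(x$system_total)))
  invisible(x)
}

#' Cost per patient with a result and per patient with a correct result
#'
#' @param costs a `vl_costs` (or any list with `system_total`).
#' @param access number of patients accessing testing (> 0).
#' @param correct number of patients with a correct result (> 0).
#' @return named numeric: `cost_per_result`, `cost_per_correct`; unrounded
#'   (report rendering rounds to 2 decimals).
#' @export
#' @examples
#' cost_ratios(list(system_total = 23792767), 814066, 795342)
#' # 29.23 and 29.92 after rounding
cost_ratios <- function(costs, access, correct) {
  check_that(access > 0, "cost_ratios: zero patients accessing")
  check_that(correct > 0, "cost_ratios: zero correct results")
  c(cost_per_result = costs$system_total / access,
    cost_per_correct = costs$system_total / correct)
}
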