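#' Per-test unit cost of a specimen type
#'
#' Three components, all in USD per viral-load test: sample collection
#' consumables (tubes, cards, lancets), sample collection staff/equipment/
#' overhead, and sample analysis at the centralized laboratory. Result-return
#' costs after analysis are excluded.
#'
#' @param specimen one of `"plasma"`, `"dbs"`, `"psc"`.
#' @param consumables,collection_overhead,lab_analysis non-negative USD/test.
#' @return object of class `specimen_unit_cost`.
#' @seealso [unit_test_cost()] for the per-test total.
#' @export
specimen_unit_cost <- function(specimen, consumables, collection_overhead, lab_analysis) {
  specimen <- match.arg(specimen, c("plasma", "dbs", "psc"))
  for (nm in c("consumables", "collection_overhead", "lab_analysis")) {
    v <- get(nm)
    check_that(is_nonneg(v), "unit cost %s: %s = %s is negative or not scalar",
               specimen, nm, format(v))
  }
  structure(list(specimen = specimen, consumables = consumables,
                 collection_overhead = collection_overhead,
                 lab_analysis = lab_analysis),
            class = "specimen_unit_cost")
}

#' Scenario definition: which specimen goes where
#'
#' A scenario assigns a specimen type to each facility stratum, fixes the
#' platform mix for dried specimens, and names the transport-cost entry that
#' applies. Facilities unreachable by the plasma cold-chain network can only
#' be served when the low-volume specimen is dried, so `include_unreachable`
#' must agree with the low-volume specimen choice.
#'
#' @param name scenario identifier.
#' @param specimen_high,specimen_low specimen used at high-volume and
#'   low-volume facilities.
#' @param include_unreachable logical; serve plasma-unreachable facilities.
#' @param platform_mix named non-negative weights over platforms for dried
#'   specimens (must sum to 1); `NULL` for all-plasma scenarios.
#' @param transport_key name of the transport-cost entry in the config's
#'   `visit_transport$transport` table.
#' @return object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec("plasma_psc", "plasma", "psc", include_unreachable = TRUE,
#'               platform_mix = c(capctm = 0.42, cobas8800 = 0.58),
#'               transport_key = "partial")
scenario_spec <- function(name, specimen_high, specimen_low, include_unreachable,
                          platform_mix = NULL, transport_key = name) {
  specimen_high <- match.arg(specimen_high, c("plasma", "dbs", "psc"))
  specimen_low <- match.arg(specimen_low, c("plasma", "dbs", "psc"))
  check_that(is.logical(include_unreachable) && length(include_unreachable) == 1L,
             "scenario %s: include_unreachable must be a single logical", name)
  dried_low <- specimen_low != "plasma"
  check_that(identical(include_unreachable, dried_low),
             paste0("scenario %s: include_unreachable must be TRUE exactly when the ",
                    "low-volume specimen is dried (got %s with specimen_low = %s)"),
             name, include_unreachable, specimen_low)
  if (!is.null(platform_mix)) {
    check_that(!is.null(names(platform_mix)) && all(platform_mix >= 0),
               "scenario %s: platform_mix must be named and non-negative", name)
    check_that(abs(sum(platform_mix) - 1) <= 1e-9,
               "scenario %s: platform_mix weights sum to %s, not 1",
               name, format(sum(platform_mix)))
  }
  structure(list(name = name, specimen_high = specimen_high,
                 specimen_low = specimen_low,
                 include_unreachable = include_unreachable,
                 platform_mix = platform_mix, transport_key = transport_key),
            class = "scenario_spec")
}

#' Assemble a model configuration
#'
#' @param assays named list of [assay_performance()] objects.
#' @param unit_costs named list (by specimen) of [specimen_unit_cost()].
#' @param multipliers list with elements `high_volume`, `low_volume_plasma`,
#'   `low_volume_dried`, `unreachable_dried` — annual patient-access
#'   proportions by facility stratum and specimen class.
#' @param epi list with `failure_prevalence` (proportion of tested patients in
#'   true virological failure) and `correctness_model` (`"product"` or
#'   `"prevalence_weighted"`).
#' @param visit_transport list with `visit_cost` (USD per facility visit) and
#'   `transport` (named USD/year transport-network costs).
#' @param scenarios list of [scenario_spec()].
#' @param seed integer seed for panel generation.
#' @return object of class `vl_config`.
#' @seealso [default_config()], [load_config()], [validate_config()]
#' @export
vl_config <- function(assays, unit_costs, multipliers, epi, visit_transport,
                      scenarios, seed = 1L) {
  cfg <- structure(list(assays = assays, unit_costs = unit_costs,
                        multipliers = multipliers, epi = epi,
                        visit_transport = visit_transport,
                        scenarios = scenarios, seed = as.integer(seed)),
                   class = "vl_config")
  findings <- validate_config(cfg)
  check_that(length(findings) == 0, "invalid configuration:\n  %s",
             paste(findings, collapse = "\n  "))
  cfg
}

#' Validate a model configuration
#'
#' Checks every structural invariant and returns findings instead of
#' throwing: proportions in \[0, 1\], bound ordering, non-negative costs,
#' platform-mix weights, and that every specimen referenced by a scenario has
#' exactly one unit cost and at least one assay entry.
#'
#' @param cfg a `vl_config` (possibly hand-edited).
#' @return character vector of findings; empty when all invariants hold.
#' @export
validate_config <- function(cfg) {
  findings <- character(0)
  note <- function(fmt, ...) findings <<- c(findings, sprintf(fmt, ...))

  for (key in names(cfg$assays)) {
    a <- cfg$assays[[key]]
    for (nm in c("sensitivity", "specificity", "sens_low", "sens_high",
                 "spec_low", "spec_high"))
      if (!is_prop(a[[nm]]))
        note("assays.%s.%s: %s not a proportion in [0,1]", key, nm, format(a[[nm]]))
    if (is_prop(a$sens_low) && is_prop(a$sensitivity) && is_prop(a$sens_high) &&
        !(a$sens_low <= a$sensitivity && a$sensitivity <= a$sens_high))
      note("assays.%s: sensitivity bounds out of order (%s, %s, %s)",
           key, a$sens_low, a$sensitivity, a$sens_high)
    if (is_prop(a$spec_low) && is_prop(a$specificity) && is_prop(a$spec_high) &&
        !(a$spec_low <= a$specificity && a$specificity <= a$spec_high))
      note("assays.%s: specificity bounds out of order (%s, %s, %s)",
           key, a$spec_low, a$specificity, a$spec_high)
  }
  for (key in names(cfg$unit_costs)) {
    u <- cfg$unit_costs[[key]]
    for (nm in c("consumables", "collection_overhead", "lab_analysis"))
      if (!is_nonneg(u[[nm]]))
        note("unit_costs.%s.%s: negative or missing", key, nm)
  }
  for (nm in c("high_volume", "low_volume_plasma", "low_volume_dried", "unreachable_dried"))
    if (!is_prop(cfg$multipliers[[nm]]))
      note("multipliers.%s: not a proportion in [0,1]", nm)
  if (!is_prop(cfg$epi$failure_prevalence))
    note("epi.failure_prevalence: not a proportion in [0,1]")
  if (!cfg$epi$correctness_model %in% c("product", "prevalence_weighted"))
    note("epi.correctness_model: unknown model '%s'", cfg$epi$correctness_model)
  if (!is_nonneg(cfg$visit_transport$visit_cost))
    note("visit_transport.visit_cost: negative or missing")
  for (nm in names(cfg$visit_transport$transport))
    if (!is_nonneg(cfg$visit_transport$transport[[nm]]))
      note("visit_transport.transport.%s: negative or missing", nm)

  assay_specimens <- vapply(cfg$assays, function(a) a$specimen, character(1))
  for (sc in cfg$scenarios) {
    for (sp in unique(c(sc$specimen_high, sc$specimen_low))) {
      if (is.null(cfg$unit_costs[[sp]]))
        note("scenario %s: specimen '%s' has no unit cost entry", sc$name, sp)
      if (!any(assay_specimens == sp))
        note("scenario %s: specimen '%s' has no assay entry", sc$name, sp)
    }
    if (is.null(cfg$visit_transport$transport[[sc$transport_key]]))
      note("scenario %s: transport key '%s' not found", sc$name, sc$transport_key)
  }
  findings
}

#' The packaged Zambia base-case configuration
#'
#' Loads the configuration shipped with the package: assay performance of
#' plasma, DBS and PSC on the CAP/CTM and Cobas 8800 platforms, per-test unit
#' costs, facility-access multipliers (80% at high-volume sites, 40% for
#' plasma / 80% for dried specimens at low-volume sites), visit and scenario
#' transport costs, and the five national scale-up scenarios (plasma only,
#' plasma + DBS, plasma + PSC, DBS only, PSC only). The failure prevalence is
#' the value calibrated from the base-case plasma testing volumes; see
#' [calibrate_failure_prevalence()].
#'
#' @return a `vl_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$assays$plasma_capctm$sensitivity  # 0.983
default_config <- function() {
  load_config(system.file("extdata", "zambia.yaml", package = "vlcea", mustWork = TRUE))
}

scenario_from_list <- function(x) {
  mix <- x$platform_mix
  if (!is.null(mix)) mix <- unlist(mix)
  scenario_spec(x$name, x$specimen_high, x$specimen_low,
                isTRUE(x$include_unreachable), platform_mix = mix,
                transport_key = if (is.null(x$transport_key)) x$name else x$transport_key)
}

read_assays_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("key", "specimen", "platform", "sensitivity", "specificity",
            "sens_low", "sens_high", "spec_low", "spec_high")
  check_that(all(need %in% names(d)), "assays table %s: missing columns %s",
             path, paste(setdiff(need, names(d)), collapse = ", "))
  out <- lapply(seq_len(nrow(d)), function(i)
    assay_performance(d$specimen[i], d$platform[i], d$sensitivity[i], d$specificity[i],
                      d$sens_low[i], d$sens_high[i], d$spec_low[i], d$spec_high[i]))
  names(out) <- d$key
  out
}

read_unit_costs_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "consumables", "collection_overhead", "lab_analysis")
  check_that(all(need %in% names(d)), "unit cost table %s: missing columns %s",
             path, paste(setdiff(need, names(d)), collapse = ", "))
  out <- lapply(seq_len(nrow(d)), function(i)
    specimen_unit_cost(d$specimen[i], d$consumables[i], d$collection_overhead[i],
                       d$lab_analysis[i]))
  names(out) <- d$specimen
  out
}

#' Load a model configuration from YAML or JSON
#'
#' The document holds `multipliers`, `epi`, `visit_transport`, `scenarios`
#' and `seed` directly, and either inline `assays`/`unit_costs` sections or
#' `assays_csv`/`unit_costs_csv` paths (relative to the document) pointing at
#' CSV tables with documented column names (`key, specimen, platform,
#' sensitivity, specificity, sens_low, sens_high, spec_low, spec_high` and
#' `specimen, consumables, collection_overhead, lab_analysis`).
#'
#' @param source path to a `.yaml`/`.yml`/`.json` file, or a single string
#'   containing a YAML document.
#' @return a validated `vl_config`; malformed input raises an error naming
#'   the offending field and value.
#' @seealso [write_config()] for the inverse; round-tripping a config through
#'   `write_config()` and `load_config()` is lossless.
#' @export
load_config <- function(source) {
  from_file <- length(source) == 1L && !grepl("\n", source) && file.exists(source)
  if (from_file) {
    raw <- if (grepl("\\.json$", source, ignore.case = TRUE))
      jsonlite::read_json(source) else yaml::read_yaml(source)
    base_dir <- dirname(source)
  } else {
    raw <- yaml::yaml.load(source)
    base_dir <- "."
  }

  assays <- if (!is.null(raw$assays_csv))
    read_assays_csv(file.path(base_dir, raw$assays_csv))
  else lapply(raw$assays, function(a)
    assay_performance(a$specimen, a$platform, a$sensitivity, a$specificity,
                      a$sens_low %||% a$sensitivity, a$sens_high %||% a$sensitivity,
                      a$spec_low %||% a$specificity, a$spec_high %||% a$specificity))
  unit_costs <- if (!is.null(raw$unit_costs_csv))
    read_unit_costs_csv(file.path(base_dir, raw$unit_costs_csv))
  else lapply(raw$unit_costs, function(u)
    specimen_unit_cost(u$specimen, u$consumables, u$collection_overhead, u$lab_analysis))
  if (is.null(names(unit_costs)) || any(names(unit_costs) == ""))
    names(unit_costs) <- vapply(unit_costs, function(u) u$specimen, character(1))

  check_that(!is.null(raw$multipliers), "config: missing required field 'multipliers'")
  check_that(!is.null(raw$epi), "config: missing required field 'epi'")
  check_that(!is.null(raw$visit_transport), "config: missing required field 'visit_transport'")
  check_that(!is.null(raw$scenarios), "config: missing required field 'scenarios'")

  vl_config(assays = assays, unit_costs = unit_costs,
            multipliers = raw$multipliers, epi = raw$epi,
            visit_transport = raw$visit_transport,
            scenarios = lapply(raw$scenarios, scenario_from_list),
            seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a configuration to a single YAML document
#'
#' Writes every input inline (assay and unit-cost tables included) so the
#' result is self-contained. `load_config(write_config(cfg, f))` reproduces
#' `cfg` exactly.
#'
#' @param cfg a `vl_config`.
#' @param path output file; `NULL` returns the YAML text instead.
#' @return `path` invisibly, or the YAML string when `path` is `NULL`.
#' @export
write_config <- function(cfg, path = NULL) {
  strip <- function(x) lapply(unclass(x), function(v) if (is.list(v)) strip(v) else v)
  doc <- list(
    assays = lapply(cfg$assays, unclass),
    unit_costs = lapply(cfg$unit_costs, unclass),
    multipliers = cfg$multipliers,
    epi = cfg$epi,
    visit_transport = cfg$visit_transport,
    scenarios = lapply(cfg$scenarios, function(s) {
      s <- unclass(s)
      if (!is.null(s$platform_mix)) s$platform_mix <- as.list(s$platform_mix)
      s
    }),
    seed = cfg$seed)
  txt <- yaml::as.yaml(doc, precision = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.vl_config <- function(x, ...) {
  cat("<vl_config>\n")
  cat(sprintf("  assays: %s\n", paste(names(x$assays), collapse = ", ")))
  cat(sprintf("  specimens costed: %s\n", paste(names(x$unit_costs), collapse = ", ")))
  cat(sprintf("  scenarios: %s\n",
              paste(vapply(x$scenarios, function(s) s$name, character(1)), collapse = ", ")))
  cat(sprintf("  failure prevalence: %.4f (%s correctness model)\n",
              x$epi$failure_prevalence, x$epi$correctness_model))
  invisible(x)
}
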