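#' Screen-positivity rate of a testing cascade
#'
#' Probability that an initial viral-load test reads above the 1000
#' copies/mL threshold, triggering a confirmatory repeat test:
#' `q = p * Se + (1 - p) * (1 - Sp)`, where `p` is the true prevalence of
#' virological failure among tested patients.
#'
#' @param p failure prevalence, proportion in \[0, 1\].
#' @param perf an [assay_performance()].
#' @return proportion `q`.
#' @export
#' @examples
#' plasma <- assay_performance("plasma", "capctm", 0.983, 0.994)
#' positivity_rate(0.1409, plasma)  # about 0.1437
positivity_rate <- function(p, perf) {
  check_that(is_prop(p), "positivity_rate: p = %s not a proportion", format(p))
  p * perf$sensitivity + (1 - p) * (1 - perf$specificity)
}

#' Calibrate failure prevalence from an observed testing volume
#'
#' Inverts [positivity_rate()]: given that each screen-positive patient
#' receives one confirmatory test, total tests / patients = 1 + q, so the
#' underlying failure prevalence is
#' `p = (tests/patients - 1 - (1 - Sp)) / (Se - (1 - Sp))`.
#' Used to recover the unreported base-case prevalence from the published
#' plasma-only volumes (930,982 tests for 814,066 patients gives p ~ 0.1409).
#'
#' @param observed_tests total tests performed (may be non-integer).
#' @param patients patients tested once each initially.
#' @param perf an [assay_performance()]; requires an informative assay
#'   (`Se + Sp > 1`).
#' @return calibrated proportion, clipped to \[0, 1\] with a warning if the
#'   observed ratio is outside the attainable range.
#' @export
calibrate_failure_prevalence <- function(observed_tests, patients, perf) {
  check_that(observed_tests >= patients,
             "calibrate_failure_prevalence: tests (%s) < patients (%s)",
             format(observed_tests), format(patients))
  se <- perf$sensitivity; fp <- 1 - perf$specificity
  check_that(se + perf$specificity > 1,
             "calibrate_failure_prevalence: non-informative assay (Se + Sp <= 1)")
  q <- observed_tests / patients - 1
  p <- (q - fp) / (se - fp)
  if (p < 0 || p > 1) {
    warning(sprintf("calibrated prevalence %.4f outside [0,1]; clipped", p))
    p <- min(max(p, 0), 1)
  }
  p
}

#' Effective performance of each specimen used in a scenario
#'
#' Plasma is always run on CAP/CTM; dried specimens are volume-weighted over
#' the scenario's platform mix via [effective_performance()].
#'
#' @param cfg a `vl_config`.
#' @param spec a [scenario_spec()].
#' @return named list (by specimen) of [assay_performance()] objects covering
#'   every specimen the scenario uses.
#' @export
scenario_performance <- function(cfg, spec) {
  specimens <- unique(c(spec$specimen_high, spec$specimen_low))
  out <- lapply(specimens, function(sp) {
    matches <- Filter(function(a) a$specimen == sp, cfg$assays)
    check_that(length(matches) > 0, "no assay entry for specimen '%s'", sp)
    if (sp == "plasma" || is.null(spec$platform_mix)) {
      cap <- Filter(function(a) a$platform == "capctm", matches)
      return(if (length(cap)) cap[[1]] else matches[[1]])
    }
    comps <- lapply(names(spec$platform_mix), function(pl) {
      m <- Filter(function(a) a$platform == pl, matches)
      check_that(length(m) == 1,
                 "scenario %s: need exactly one %s assay on platform %s, found %d",
                 spec$name, sp, pl, length(m))
      list(weight = spec$platform_mix[[pl]], perf = m[[1]])
    })
    effective_performance(comps)
  })
  names(out) <- specimens
  out
}

#' Testing volumes implied by access and positivity
#'
#' Each patient accessing receives one initial test on their facility's
#' specimen; each screen-positive receives one confirmatory test on the same
#' specimen (single-repeat cascade). Confirmatory counts are rounded
#' half-away-from-zero per specimen cell.
#'
#' @param access a `vl_access` from [annual_access()].
#' @param q_by_specimen named positivity rates per specimen (see
#'   [positivity_rate()]).
#' @param round logical; round confirmatory counts to integers (default
#'   `TRUE`). Set `FALSE` for exact algebraic volumes (e.g. calibration
#'   round-trips).
#' @return object of class `vl_volumes`: data frame `by_specimen` (specimen,
#'   initial, confirmatory, total) plus grand totals.
#' @export
test_volumes <- function(access, q_by_specimen, round = TRUE) {
  specimens <- unique(access$cells$specimen)
  rows <- lapply(specimens, function(sp) {
    q <- q_by_specimen[[sp]]
    check_that(!is.null(q) && is_prop(q), "test_volumes: q for '%s' missing or not in [0,1]", sp)
    initial <- sum(access$cells$patients[access$cells$specimen == sp])
    confirmatory <- if (round) round_half_away(initial * q) else initial * q
    data.frame(specimen = sp, initial = initial, confirmatory = confirmatory,
               total = initial + confirmatory, q = q, stringsAsFactors = FALSE)
  })
  by_specimen <- do.call(rbind, rows)
  structure(list(scenario = access$scenario, by_specimen = by_specimen,
                 initial = sum(by_specimen$initial),
                 confirmatory = sum(by_specimen$confirmatory),
                 total = sum(by_specimen$total)),
            class = "vl_volumes")
}

#' @export
print.vl_volumes <- function(x, ...) {
  cat(sprintf("<vl_volumes> scenario %s: %s tests (%s initial + %s confirmatory)\n",
              x$scenario, format(x$total, big.mark = " "),
              format(x$initial, big.mark = " "), format(x$confirmatory, big.mark = " ")))
  print.data.frame(x$by_specimen, row.names = FALSE)
  invisible(x)
}

#' Patients receiving a correct viral-load result
#'
#' Two counting models are provided. `"product"`: a patient's result is
#' correct when both the initial and (if triggered) confirmatory readings are
#' consistent with the truth, approximated as `N * Se * Sp` per cell — this
#' reproduces the published plasma-only base case to within 0.02%.
#' `"prevalence_weighted"`: the standard expected fraction of correct
#' classifications, `N * (p * Se + (1 - p) * Sp)` — preferred for prospective
#' analyses. Correct counts are kept real-valued; rounding happens at report
#' time.
#'
#' @param access a `vl_access`.
#' @param perf_by_specimen named list of [assay_performance()] per specimen
#'   (see [scenario_performance()]).
#' @param p failure prevalence (used by the prevalence-weighted model).
#' @param model `"product"` or `"prevalence_weighted"`.
#' @return object of class `vl_correct`: `correct` (total), `by_cell` data
#'   frame, and `model_used`.
#' @export
correct_results <- function(access, perf_by_specimen, p,
                            model = c("product", "prevalence_weighted")) {
  model <- match.arg(model)
  cells <- access$cells
  correct <- vapply(seq_len(nrow(cells)), function(i) {
    perf <- perf_by_specimen[[cells$specimen[i]]]
    check_that(!is.null(perf), "correct_results: no performance for specimen '%s'",
               cells$specimen[i])
    n <- cells$patients[i]
    switch(model,
           product = n * perf$sensitivity * perf$specificity,
           prevalence_weighted = n * (p * perf$sensitivity + (1 - p) * perf$specificity))
  }, numeric(1))
  by_cell <- cbind(cells[c("class", "specimen", "patients")], correct = correct)
  structure(list(scenario = access$scenario, correct = sum(correct),
                 by_cell = by_cell, model_used = model),
            class = "vl_correct")
}

#' @export
print.vl_correct <- function(x, ...) {
  cat(sprintf("<vl_correct> scenario %s: %s correct results (%s model)\n",
              x$scenario, fmt_money(x$correct), x$model_used))
  invisible(x)
}
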