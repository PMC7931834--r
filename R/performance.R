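#' Assay performance of a specimen-platform pair
#'
#' Sensitivity and specificity of a viral-load assay at the 1000 copies/mL
#' virological-failure threshold, for one specimen type (plasma, dried blood
#' spot, or plasma separation card) on one laboratory platform, with
#' uncertainty bounds. Bounds are carried for sensitivity analysis only; the
#' point estimates drive all base-case computations.
#'
#' @param specimen one of `"plasma"`, `"dbs"`, `"psc"`.
#' @param platform one of `"capctm"` (Roche Cobas Ampliprep/Cobas TaqMan) or
#'   `"cobas8800"`.
#' @param sensitivity,specificity point estimates, proportions in \[0, 1\].
#' @param sens_low,sens_high,spec_low,spec_high uncertainty bounds; default to
#'   the point estimates.
#' @return an object of class `assay_performance`.
#' @export
#' @examples
#' assay_performance("plasma", "capctm", 0.983, 0.994,
#'                   sens_low = 0.967, sens_high = 0.993)
assay_performance <- function(specimen, platform, sensitivity, specificity,
                              sens_low = sensitivity, sens_high = sensitivity,
                              spec_low = specificity, spec_high = specificity) {
  specimen <- match.arg(specimen, c("plasma", "dbs", "psc"))
  platform <- match.arg(platform, c("capctm", "cobas8800"))
  for (nm in c("sensitivity", "specificity", "sens_low", "sens_high",
               "spec_low", "spec_high")) {
    v <- get(nm)
    check_that(is_prop(v), "assay %s/%s: %s = %s is not a proportion in [0,1]",
               specimen, platform, nm, format(v))
  }
  check_that(sens_low <= sensitivity && sensitivity <= sens_high,
             "assay %s/%s: sensitivity bounds violate low <= point <= high (%s, %s, %s)",
             specimen, platform, sens_low, sensitivity, sens_high)
  check_that(spec_low <= specificity && specificity <= spec_high,
             "assay %s/%s: specificity bounds violate low <= point <= high (%s, %s, %s)",
             specimen, platform, spec_low, specificity, spec_high)
  structure(list(specimen = specimen, platform = platform,
                 sensitivity = sensitivity, specificity = specificity,
                 sens_low = sens_low, sens_high = sens_high,
                 spec_low = spec_low, spec_high = spec_high),
            class = "assay_performance")
}

#' @export
print.assay_performance <- function(x, ...) {
  cat(sprintf("<assay_performance> %s on %s: Se %.3f [%.3f, %.3f], Sp %.3f [%.3f, %.3f]\n",
              x$specimen, x$platform, x$sensitivity, x$sens_low, x$sens_high,
              x$specificity, x$spec_low, x$spec_high))
  invisible(x)
}

#' Effective performance of a specimen under a platform mix
#'
#' When a dried specimen is run on several platforms (e.g. PSC split between
#' CAP/CTM and Cobas 8800 according to network volumes), the effective
#' network-level sensitivity and specificity are volume-weighted averages of
#' the platform-specific values. Uncertainty bounds are weight-averaged the
#' same way.
#'
#' @param components list of `list(weight =, perf =)` pairs, where each
#'   `perf` is an [assay_performance()]. All components must share a specimen
#'   type; weights must be non-negative and sum to 1 (tolerance 1e-9).
#' @return an [assay_performance()] with platform `"capctm"` when mixed
#'   platforms are combined (the platform label of a mix is nominal).
#' @export
#' @examples
#' psc_cap <- assay_performance("psc", "capctm", 0.91, 0.99)
#' psc_cob <- assay_performance("psc", "cobas8800", 0.970, 0.972)
#' effective_performance(list(list(weight = 0.61, perf = psc_cap),
#'                            list(weight = 0.39, perf = psc_cob)))
effective_performance <- function(components) {
  check_that(length(components) >= 1, "effective_performance: no components")
  w <- vapply(components, function(c) c$weight, numeric(1))
  check_that(all(w >= 0), "effective_performance: negative weight")
  check_that(abs(sum(w) - 1) <= 1e-9,
             "effective_performance: weights sum to %s, not 1", format(sum(w)))
  specimens <- vapply(components, function(c) c$perf$specimen, character(1))
  check_that(length(unique(specimens)) == 1L,
             "effective_performance: mixed specimen types (%s)",
             paste(unique(specimens), collapse = ", "))
  wavg <- function(field) sum(w * vapply(components, function(c) c$perf[[field]], numeric(1)))
  platform <- if (length(components) == 1L) components[[1]]$perf$platform else "capctm"
  se <- wavg("sensitivity"); sp <- wavg("specificity")
  # bounds envelope the point: a swept point estimate outside the stored
  # uncertainty range (e.g. during sensitivity analysis) widens the range
  assay_performance(specimens[1], platform,
                    sensitivity = se, specificity = sp,
                    sens_low = min(wavg("sens_low"), se),
                    sens_high = max(wavg("sens_high"), se),
                    spec_low = min(wavg("spec_low"), sp),
                    spec_high = max(wavg("spec_high"), sp))
}
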