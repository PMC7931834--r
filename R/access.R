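#' Annual patients accessing viral-load testing under a scenario
#'
#' Applies flat access multipliers by facility class and specimen: a fixed
#' share of ART patients at high-volume facilities access testing annually
#' (default 80%, for any specimen); at low-volume plasma-reachable facilities
#' the share is lower with plasma (default 40%, reflecting cold-chain and
#' transport-schedule losses) and restored to the high-volume level with
#' dried specimens (default 80%); facilities unreachable for plasma transport
#' contribute only when the scenario's low-volume specimen is dried. Patient
#' counts are rounded half-away-from-zero per class cell; access is
#' deterministic given the panel.
#'
#' @param panel a [vl_panel].
#' @param spec a [scenario_spec()].
#' @param mult access multipliers list (`high_volume`, `low_volume_plasma`,
#'   `low_volume_dried`, `unreachable_dried`), e.g. `default_config()$multipliers`.
#' @return object of class `vl_access`: list with `cells` (data frame of
#'   class, specimen, patients, facilities), `total_patients`,
#'   `facilities_reached`, and the scenario name.
#' @export
#' @examples
#' cfg <- default_config()
#' a <- annual_access(zambia_panel(), cfg$scenarios[[1]], cfg$multipliers)
#' a$total_patients  # 814066
annual_access <- function(panel, spec, mult) {
  s <- summarize_panel(panel)
  tot <- function(k) s$art_patients[s$class == k]
  nfac <- function(k) s$facilities[s$class == k]
  fac_reached <- function(k, m) {
    if (m <= 0) return(0L)
    cls <- panel_class(panel)
    sum(cls == k & panel$art_patients > 0)
  }

  low_mult <- if (spec$specimen_low == "plasma") mult$low_volume_plasma else mult$low_volume_dried
  cells <- data.frame(
    class = c("high_volume", "low_volume_reachable"),
    specimen = c(spec$specimen_high, spec$specimen_low),
    patients = c(round_half_away(mult$high_volume * tot("high_volume")),
                 round_half_away(low_mult * tot("low_volume_reachable"))),
    facilities = c(fac_reached("high_volume", mult$high_volume),
                   fac_reached("low_volume_reachable", low_mult)),
    stringsAsFactors = FALSE)
  if (spec$include_unreachable) {
    cells <- rbind(cells, data.frame(
      class = "low_volume_unreachable", specimen = spec$specimen_low,
      patients = round_half_away(mult$unreachable_dried * tot("low_volume_unreachable")),
      facilities = fac_reached("low_volume_unreachable", mult$unreachable_dried)))
  }
  structure(list(scenario = spec$name, cells = cells,
                 total_patients = sum(cells$patients),
                 facilities_reached = sum(cells$facilities)),
            class = "vl_access")
}

#' @export
print.vl_access <- function(x, ...) {
  cat(sprintf("<vl_access> scenario %s: %s patients/y at %d facilities\n",
              x$scenario, format(x$total_patients, big.mark = " "), x$facilities_reached))
  print.data.frame(x$cells, row.names = FALSE)
  invisible(x)
}

#' Percentage increase in access between two scenarios
#'
#' @param base,alt `vl_access` results (or any objects with `total_patients`).
#' @return percentage, `100 * (alt - base) / base`; unrounded.
#' @export
#' @examples
#' access_increase(list(total_patients = 814066), list(total_patients = 965587))
#' # 18.61 -> reported as a 19% increase at integer rounding
access_increase <- function(base, alt) {
  check_that(base$total_patients > 0, "access_increase: base access is zero")
  100 * (alt$total_patients - base$total_patients) / base$total_patients
}
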