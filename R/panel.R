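#' Facility panels: synthetic stand-ins for geospatial transport-model output
#'
#' A facility panel is a data frame with one row per health facility and
#' columns `id`, `stratum` (`"high_volume"` >= 10 anticipated VL specimens
#' per day, else `"low_volume"`), `plasma_reachable` (on the cold-chain
#' sample-transport network), `art_patients` and `province`, plus an
#' attribute `transport` holding annual transport-network costs (USD) keyed
#' by scenario transport key. High-volume facilities are always
#' plasma-reachable (they sit on daily transport routes).
#'
#' @name vl_panel
NULL

new_panel <- function(facilities, transport) {
  check_that(!anyDuplicated(facilities$id), "facility ids must be unique")
  check_that(all(facilities$art_patients >= 0), "art_patients must be >= 0")
  check_that(sum(facilities$art_patients) > 0, "panel has no ART patients")
  check_that(!any(facilities$stratum == "high_volume" & !facilities$plasma_reachable),
             "high-volume facilities must be plasma-reachable")
  structure(facilities, transport = as.list(transport), class = c("vl_panel", "data.frame"))
}

# largest-remainder apportionment of `total` across positive weights,
# guaranteeing every facility at least one patient
apportion <- function(weights, total) {
  n <- length(weights)
  check_that(total >= n, "infeasible totals: %d patients for %d facilities", total, n)
  shares <- weights / sum(weights)
  raw <- shares * (total - n)  # reserve one patient per facility
  base <- floor(raw)
  rem <- total - n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base + 1
}

#' Generate a synthetic facility panel
#'
#' Emulates the output of an upstream geospatial route-optimization model:
#' facilities in three access classes (high-volume, low-volume reachable by
#' weekly plasma transport, low-volume unreachable for plasma), with
#' facility-level ART patient counts drawn from a skewed (lognormal)
#' distribution and then apportioned so each class's total matches the
#' requested total exactly. Facility-level allocation is modelling
#' convenience only — all scenario outcomes depend on the class totals, which
#' are guaranteed.
#'
#' @param n_high,n_low_reachable,n_low_unreachable facility counts (> 0,
#'   except `n_low_unreachable` which may be 0).
#' @param patient_totals numeric length 3: total ART patients in the
#'   high-volume, low-volume reachable, and low-volume unreachable classes.
#'   Each must be at least the class's facility count.
#' @param dispersion lognormal `sdlog` of the facility-size distribution
#'   (default 1; larger means more skew).
#' @param seed integer; the draw is deterministic given the seed, and the
#'   caller's RNG state is left untouched.
#' @param transport named list of annual transport costs to attach.
#' @return a [vl_panel] data frame.
#' @export
#' @examples
#' p <- generate_panel(3, 4, 2, c(3000, 400, 100), seed = 7)
#' summarize_panel(p)
generate_panel <- function(n_high, n_low_reachable, n_low_unreachable,
                           patient_totals, dispersion = 1, seed = 1L,
                           transport = list()) {
  check_that(n_high > 0 && n_low_reachable > 0 && n_low_unreachable >= 0,
             "facility counts must be positive (unreachable may be 0)")
  check_that(length(patient_totals) == 3, "patient_totals must have length 3")
  check_that(dispersion > 0, "dispersion must be positive")

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  classes <- list(
    list(n = n_high, total = patient_totals[1], stratum = "high_volume", reach = TRUE,
         prefix = "HV"),
    list(n = n_low_reachable, total = patient_totals[2], stratum = "low_volume",
         reach = TRUE, prefix = "LV"),
    list(n = n_low_unreachable, total = patient_totals[3], stratum = "low_volume",
         reach = FALSE, prefix = "LU"))
  rows <- lapply(classes, function(cl) {
    if (cl$n == 0) return(NULL)
    w <- stats::rlnorm(cl$n, meanlog = 0, sdlog = dispersion)
    data.frame(id = sprintf("%s%04d", cl$prefix, seq_len(cl$n)),
               stratum = cl$stratum, plasma_reachable = cl$reach,
               art_patients = apportion(w, cl$total),
               province = sprintf("P%02d", 1 + (seq_len(cl$n) %% 10)),
               stringsAsFactors = FALSE)
  })
  new_panel(do.call(rbind, rows), transport)
}

#' The calibrated Zambia facility panel
#'
#' A synthetic panel whose class totals are calibrated so the access model
#' reproduces the national base-case figures: 885,656 ART patients at 152
#' high-volume facilities, 263,853 at 648 low-volume plasma-reachable
#' facilities, and 57,475 at 241 facilities unreachable for plasma transport
#' (reached facilities: 800 with plasma, 1,041 with dried specimens). Annual
#' transport costs attached are 3,264,509 / 3,637,168 / 2,390,317 USD for the
#' plasma-only, partial-adoption and full-adoption networks. The class totals
#' are exact by construction; within-class facility sizes are stochastic.
#'
#' @param seed integer seed for the within-class allocation.
#' @param dispersion lognormal sdlog of facility sizes.
#' @return a [vl_panel].
#' @export
#' @examples
#' summarize_panel(zambia_panel())
zambia_panel <- function(seed = 1L, dispersion = 1) {
  generate_panel(152, 648, 241,
                 patient_totals = c(885656, 263853, 57475),
                 dispersion = dispersion, seed = seed,
                 transport = list(plasma_only = 3264509,
                                  partial = 3637168,
                                  full = 2390317))
}

#' Summarize a facility panel
#'
#' @param panel a [vl_panel].
#' @return data frame with one row per access class (`high_volume`,
#'   `low_volume_reachable`, `low_volume_unreachable`): facility count and
#'   total ART patients. Totals equal sums over facilities.
#' @export
summarize_panel <- function(panel) {
  cls <- panel_class(panel)
  out <- do.call(rbind, lapply(c("high_volume", "low_volume_reachable",
                                 "low_volume_unreachable"), function(k) {
    sel <- cls == k
    data.frame(class = k, facilities = sum(sel),
               art_patients = sum(panel$art_patients[sel]))
  }))
  rownames(out) <- NULL
  out
}

# access class of each facility row
panel_class <- function(panel) {
  ifelse(panel$stratum == "high_volume", "high_volume",
         ifelse(panel$plasma_reachable, "low_volume_reachable", "low_volume_unreachable"))
}

#' Read or write a facility panel as CSV
#'
#' One row per facility with the documented columns; transport costs are
#' carried in `transport.<key>` columns repeated on every row so the file is
#' self-contained and interoperable with real geospatial-model exports.
#'
#' @param panel a [vl_panel].
#' @param path CSV file path.
#' @return `write_panel`: `path` invisibly. `read_panel`: a [vl_panel].
#' @export
write_panel <- function(panel, path) {
  d <- as.data.frame(panel)
  tr <- attr(panel, "transport")
  for (k in names(tr)) d[[paste0("transport.", k)]] <- tr[[k]]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr_cols <- grep("^transport\\.", names(d), value = TRUE)
  transport <- lapply(tr_cols, function(cn) d[[cn]][1])
  names(transport) <- sub("^transport\\.", "", tr_cols)
  new_panel(d[setdiff(names(d), tr_cols)], transport)
}

#' @export
print.vl_panel <- function(x, ...) {
  s <- summarize_panel(x)
  cat(sprintf("<vl_panel> %d facilities, %s ART patients\n",
              nrow(x), format(sum(x$art_patients), big.mark = " ")))
  print.data.frame(s, row.names = FALSE)
  invisible(x)
}
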