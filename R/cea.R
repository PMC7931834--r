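#' Average cost-effectiveness ratio versus a fixed comparator
#'
#' `(cost_alt - cost_base) / (effect_alt - effect_base)`: USD per additional
#' patient with a correct viral-load result relative to a fixed baseline
#' scenario (the status quo).
#'
#' @param alt,base scenario outcomes ([vl_outcome] objects), or any lists
#'   with `costs$system_total` and `correct$correct`.
#' @return USD per additional correct result.
#' @export
#' @examples
#' a <- list(costs = list(system_total = 28436396), correct = list(correct = 920243))
#' b <- list(costs = list(system_total = 23792767), correct = list(correct = 795342))
#' average_cer(a, b)  # 37.18
average_cer <- function(alt, base) {
  d_eff <- alt$correct$correct - base$correct$correct
  check_that(d_eff != 0, "average_cer: scenarios have equal effects; ratio undefined")
  (alt$costs$system_total - base$costs$system_total) / d_eff
}

#' Dominance ranking of cost/effect pairs
#'
#' Core league-table computation on raw vectors. Options are sorted by
#' effect; an option is *dominated* (strictly) when some other option has at
#' least the effect for at most the cost, with one inequality strict;
#' remaining options are checked for *extended (weak) dominance* by the
#' standard iterative rule — an option whose incremental cost-effectiveness
#' ratio (ICER) against the previous remaining option exceeds the next
#' option's ICER is eliminated, until frontier ICERs are non-decreasing.
#' ICERs are reported along the efficient frontier only.
#'
#' @param cost,effect numeric vectors (cost in USD, effect in correct
#'   results or any scalar effect).
#' @param names option labels; ties in effect are broken by label for
#'   determinism.
#' @return data frame (class `vl_cea_table`) ordered by effect: `scenario`,
#'   `cost`, `effect`, `status` (`undominated`, `dominated`,
#'   `weakly_dominated`), `icer` (NA off the frontier and for the cheapest
#'   frontier option).
#' @seealso [incremental_analysis()] for the method on scenario outcomes.
#' @export
cea_rank <- function(cost, effect, names = as.character(seq_along(cost))) {
  n <- length(cost)
  check_that(n >= 2, "cea_rank: need at least 2 options")
  ord <- order(effect, names)
  d <- data.frame(scenario = names[ord], cost = cost[ord], effect = effect[ord],
                  stringsAsFactors = FALSE)
  status <- rep("undominated", n)

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (d$cost[j] <= d$cost[i] && d$effect[j] >= d$effect[i] &&
          (d$cost[j] < d$cost[i] || d$effect[j] > d$effect[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }

  # iterative extended-dominance elimination on the strictly undominated set
  repeat {
    live <- which(status == "undominated")
    if (length(live) < 3) break
    icers <- diff(d$cost[live]) / diff(d$effect[live])
    bad <- which(utils::head(icers, -1) > utils::tail(icers, -1))
    if (length(bad) == 0) break
    status[live[bad[1] + 1]] <- "weakly_dominated"
  }

  live <- which(status == "undominated")
  icer <- rep(NA_real_, n)
  if (length(live) >= 2)
    icer[live[-1]] <- diff(d$cost[live]) / diff(d$effect[live])
  d$status <- status
  d$icer <- icer
  class(d) <- c("vl_cea_table", "data.frame")
  d
}

#' Incremental cost-effectiveness analysis of scenario outcomes
#'
#' Builds the league table across scenarios: average cost-effectiveness
#' ratio of each scenario versus the base comparator, dominance status, and
#' ICERs along the efficient frontier (each frontier scenario compared to
#' the next least costly frontier scenario). The effect axis is patients
#' with correct viral-load results.
#'
#' @param outcomes list of [vl_outcome] objects (>= 2).
#' @param base name of the comparator scenario for average CERs; defaults to
#'   the least costly scenario.
#' @return a `vl_cea_table` with an `avg_cer` column (NA for the comparator).
#' @export
incremental_analysis <- function(outcomes, base = NULL) {
  nm <- vapply(outcomes, function(o) o$scenario, character(1))
  cost <- vapply(outcomes, function(o) o$costs$system_total, numeric(1))
  effect <- vapply(outcomes, function(o) o$correct$correct, numeric(1))
  tab <- cea_rank(cost, effect, nm)
  if (is.null(base)) base <- nm[which.min(cost)]
  check_that(base %in% nm, "incremental_analysis: unknown base scenario '%s'", base)
  b <- which(tab$scenario == base)
  tab$avg_cer <- ifelse(
    seq_len(nrow(tab)) == b | tab$effect == tab$effect[b], NA_real_,
    (tab$cost - tab$cost[b]) / (tab$effect - tab$effect[b]))
  tab[c("scenario", "cost", "effect", "avg_cer", "status", "icer")]
}

#' @export
print.vl_cea_table <- function(x, ...) {
  d <- as.data.frame(x)
  d$cost <- fmt_money(d$cost)
  d$effect <- fmt_money(d$effect)
  if ("avg_cer" %in% names(d)) d$avg_cer <- ifelse(is.na(d$avg_cer), "...",
                                                   sprintf("%.2f", d$avg_cer))
  d$icer <- ifelse(is.na(d$icer), "...", sprintf("%.2f", d$icer))
  cat("<vl_cea_table> ordered by effect (correct VL results)\n")
  print.data.frame(d, row.names = FALSE)
  invisible(x)
}
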