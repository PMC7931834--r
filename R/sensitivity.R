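#' Metric extractors over the model configuration
#'
#' Builds a pure function `cfg -> scalar` that runs [vl_model()] and pulls
#' one quantity out of one scenario, for use with the sensitivity and
#' threshold operations. `scenario_gap_metric` returns the difference of the
#' same quantity between two scenarios (its root is a break-even point).
#'
#' @param scenario scenario name (`a`, `b` for the gap).
#' @param value which quantity: `"cost_per_correct"`, `"cost_per_result"`,
#'   `"system_cost"`, `"correct"` or `"access"`.
#' @param mode run mode passed to [vl_model()]; `"anchored"` (the default)
#'   evaluates price questions at the published base-case volumes, `"model"`
#'   recomputes volumes and correct results so performance and epidemiology
#'   parameters take effect.
#' @param panel optional [vl_panel] for `"model"` mode.
#' @return a function of one argument (a `vl_config`) returning a scalar.
#' @export
#' @examples
#' m <- scenario_metric("plasma_psc", "cost_per_correct")
#' m(default_config())  # 31.62
scenario_metric <- function(scenario, value = c("cost_per_correct", "cost_per_result",
                                                "system_cost", "correct", "access"),
                            mode = "anchored", panel = NULL) {
  value <- match.arg(value)
  function(cfg) {
    fit <- vl_model(cfg, panel = panel, mode = mode)
    o <- fit$outcomes[[scenario]]
    check_that(!is.null(o), "scenario '%s' not in configuration", scenario)
    switch(value,
           cost_per_correct = o$cost_per_correct,
           cost_per_result = o$cost_per_result,
           system_cost = o$costs$system_total,
           correct = o$correct$correct,
           access = o$access$total_patients)
  }
}

#' @rdname scenario_metric
#' @param a,b scenario names whose metric difference (`a` minus `b`) is
#'   returned.
#' @export
scenario_gap_metric <- function(a, b, value = "cost_per_correct",
                                mode = "anchored", panel = NULL) {
  ma <- scenario_metric(a, value, mode, panel)
  mb <- scenario_metric(b, value, mode, panel)
  function(cfg) ma(cfg) - mb(cfg)
}

#' One-way deterministic sensitivity analysis
#'
#' Evaluates a metric at the low, baseline and high values of a single
#' parameter (dotted path, see [cfg_get()]) with everything else held fixed.
#' The evaluation is side-effect free: the input configuration is never
#' modified.
#'
#' @param cfg a `vl_config`.
#' @param parameter dotted parameter path, e.g.
#'   `"unit_costs.psc.consumables"`.
#' @param low,high range endpoints (`low <= high`, bracketing is not
#'   required to include the baseline).
#' @param metric function `cfg -> scalar` (see [scenario_metric()]).
#' @param metric_name label for reports.
#' @return object of class `vl_sensitivity`: grid `values` (low, baseline,
#'   high), matching `metric` values, and the tornado entry
#'   (`metric_low`/`metric_high`).
#' @export
#' @examples
#' cfg <- default_config()
#' one_way_sensitivity(cfg, "unit_costs.psc.consumables", 2.5, 7.5,
#'                     scenario_metric("plasma_psc", "cost_per_correct"))
one_way_sensitivity <- function(cfg, parameter, low, high, metric,
                                metric_name = "metric") {
  check_that(low <= high, "one_way_sensitivity: low (%s) > high (%s)",
             format(low), format(high))
  base <- cfg_get(cfg, parameter)
  grid <- c(low = low, baseline = base, high = high)
  vals <- vapply(grid, function(v) metric(cfg_set(cfg, parameter, v)), numeric(1))
  structure(list(parameter = parameter, values = grid, metric = vals,
                 metric_name = metric_name,
                 metric_low = vals[["low"]], metric_high = vals[["high"]]),
            class = "vl_sensitivity")
}

#' Two-way deterministic sensitivity analysis
#'
#' Evaluates the metric on the cross product of two parameter grids. The row
#' (column) through the baseline of the other parameter reproduces the
#' corresponding one-way sweep.
#'
#' @inheritParams one_way_sensitivity
#' @param parameter_a,parameter_b dotted parameter paths.
#' @param grid_a,grid_b non-empty numeric grids.
#' @return object of class `vl_sensitivity_2d`: `metric` matrix of shape
#'   `length(grid_a) x length(grid_b)` with the grids as dimnames.
#' @export
two_way_sensitivity <- function(cfg, parameter_a, parameter_b, grid_a, grid_b,
                                metric, metric_name = "metric") {
  check_that(length(grid_a) >= 1 && length(grid_b) >= 1,
             "two_way_sensitivity: empty grid")
  m <- outer(seq_along(grid_a), seq_along(grid_b),
             Vectorize(function(i, j) {
               metric(cfg_set(cfg_set(cfg, parameter_a, grid_a[i]),
                              parameter_b, grid_b[j]))
             }))
  dimnames(m) <- list(format(grid_a), format(grid_b))
  structure(list(parameter_a = parameter_a, parameter_b = parameter_b,
                 grid_a = grid_a, grid_b = grid_b, metric = m,
                 metric_name = metric_name),
            class = "vl_sensitivity_2d")
}

#' Break-even (threshold) solve on a scalar parameter
#'
#' Finds the parameter value at which a metric equals a target (default 0 —
#' with a [scenario_gap_metric()] this is the price at which two scenarios
#' cost the same). Uses derivative-free root bracketing ([stats::uniroot]);
#' the metric difference must change sign over the bracket.
#'
#' @inheritParams one_way_sensitivity
#' @param bracket length-2 numeric `(lo, hi)`.
#' @param target metric value to hit.
#' @param tol tolerance on the achieved metric residual (default $0.005 for
#'   money metrics).
#' @return object of class `vl_threshold`: `value` (the solution),
#'   `residual` (achieved `|metric - target|`), and the endpoints evaluated.
#' @export
#' @examples
#' cfg <- default_config()
#' thr <- threshold_solve(cfg, "unit_costs.psc.consumables",
#'                        scenario_gap_metric("plasma_psc", "plasma_dbs"),
#'                        bracket = c(0, 5))
#' thr$value  # about 2.73: the PSC kit price equalizing cost per correct result
threshold_solve <- function(cfg, parameter, metric, bracket, target = 0,
                            tol = 0.005) {
  g <- function(v) metric(cfg_set(cfg, parameter, v)) - target
  f_lo <- g(bracket[1]); f_hi <- g(bracket[2])
  check_that(is.finite(f_lo) && is.finite(f_hi) && sign(f_lo) != sign(f_hi),
             paste0("threshold_solve: no sign change over bracket [%s, %s]: ",
                    "metric - target is %.6g and %.6g"),
             format(bracket[1]), format(bracket[2]), f_lo, f_hi)
  root <- stats::uniroot(g, bracket, f.lower = f_lo, f.upper = f_hi,
                         tol = .Machine$double.eps^0.5)
  res <- abs(g(root$root))
  if (res > tol)
    warning(sprintf("threshold residual %.3g exceeds tolerance %.3g", res, tol))
  structure(list(parameter = parameter, value = root$root, residual = res,
                 target = target, bracket = bracket,
                 endpoint_values = c(f_lo, f_hi) + target),
            class = "vl_threshold")
}

#' @export
print.vl_sensitivity <- function(x, ...) {
  cat(sprintf("<vl_sensitivity> %s over %s\n", x$metric_name, x$parameter))
  print(rbind(value = x$values, metric = x$metric))
  invisible(x)
}

#' @export
print.vl_threshold <- function(x, ...) {
  cat(sprintf("<vl_threshold> %s = %.4f (residual %.3g, target %.4g)\n",
              x$parameter, x$value, x$residual, x$target))
  invisible(x)
}

#' Tornado plot of one-way sensitivity results
#'
#' Horizontal bars from the low-value to the high-value metric for each
#' swept parameter, widest effect on top, with the baseline as a vertical
#' reference.
#'
#' @param x a list of `vl_sensitivity` objects (or a single one).
#' @param ... passed to [graphics::barplot] (unused otherwise).
#' @return invisibly, the data frame behind the plot.
#' @export
plot_tornado <- function(x, ...) {
  if (inherits(x, "vl_sensitivity")) x <- list(x)
  d <- data.frame(
    parameter = vapply(x, function(s) s$parameter, character(1)),
    low = vapply(x, function(s) s$metric_low, numeric(1)),
    base = vapply(x, function(s) s$metric[["baseline"]], numeric(1)),
    high = vapply(x, function(s) s$metric_high, numeric(1)))
  d <- d[order(abs(d$high - d$low)), ]
  n <- nrow(d)
  xlim <- range(d$low, d$high, d$base)
  graphics::plot(NULL, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = x[[1]]$metric_name, ylab = "",
                 main = "One-way sensitivity")
  graphics::abline(v = d$base[1], lty = 2)
  for (i in seq_len(n))
    graphics::rect(min(d$low[i], d$high[i]), i - 0.3,
                   max(d$low[i], d$high[i]), i + 0.3, col = "grey70")
  graphics::axis(2, at = seq_len(n), labels = d$parameter, las = 1, cex.axis = 0.7)
  invisible(d)
}

#' @export
plot.vl_model <- function(x, ...) {
  eff <- vapply(x$outcomes, function(o) o$correct$correct, numeric(1))
  cost <- vapply(x$outcomes, function(o) o$costs$system_total, numeric(1))
  st <- x$cea$status[match(names(x$outcomes), x$cea$scenario)]
  graphics::plot(eff, cost, pch = ifelse(st == "undominated", 19, 1),
                 xlab = "Patients with correct VL results",
                 ylab = "Annual system cost (USD)", ...)
  front <- x$cea[x$cea$status == "undominated", ]
  graphics::lines(front$effect, front$cost, lty = 2)
  graphics::text(eff, cost, names(x$outcomes), pos = 3, cex = 0.7)
  invisible(x)
}
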