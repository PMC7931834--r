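#' Round half away from zero
#'
#' Commercial rounding used for all patient/test counts and report-time money
#' figures. Base R's [round()] rounds half to even, which cannot reproduce
#' published count tables; half-away-from-zero can.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(0.5)   # 1, where round(0.5) is 0
#' round_half_away(-2.5)  # -3
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stopifnot-style check with a formatted message
check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

is_prop <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
is_nonneg <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0

#' Get or set a scalar configuration parameter by dotted path
#'
#' Parameters anywhere in a [vl_config()] are addressed by dotted paths such
#' as `"unit_costs.psc.consumables"`, `"assays.dbs_capctm.specificity"`,
#' `"multipliers.low_volume_plasma"` or `"epi.failure_prevalence"`, so any
#' scalar input can be swept by the sensitivity module without bespoke code.
#'
#' @param cfg a `vl_config` (any nested list works).
#' @param path dotted address string.
#' @param value replacement scalar (for `cfg_set`).
#' @return `cfg_get`: the scalar at `path`. `cfg_set`: a modified copy of
#'   `cfg` (the input is never mutated).
#' @export
#' @examples
#' cfg <- default_config()
#' cfg_get(cfg, "unit_costs.psc.consumables")  # 5.00
#' cfg2 <- cfg_set(cfg, "unit_costs.psc.consumables", 2.72)
cfg_get <- function(cfg, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]]))
      stop(sprintf("parameter path '%s' not found (missing component '%s')", path, k),
           call. = FALSE)
    node <- node[[k]]
  }
  node
}

#' @rdname cfg_get
#' @export
cfg_set <- function(cfg, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  cfg_get(cfg, path)  # errors early if the path does not resolve
  rec <- function(node, keys) {
    if (length(keys) == 1L) {
      node[[keys]] <- value
      return(node)
    }
    node[[keys[1]]] <- rec(node[[keys[1]]], keys[-1])
    node
  }
  rec(cfg, keys)
}

# md5 of a deparsed R object; used for run manifests
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

fmt_money <- function(x, digits = 0) {
  formatC(round_half_away(x, digits), format = "f", digits = digits, big.mark = " ")
}
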