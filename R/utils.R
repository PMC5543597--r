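`%||%` <- function(x, y) if (is.null(x)) y else x

clip01 <- function(p) pmin(1, pmax(0, p))

#' Convert an annual probability to a per-cycle probability
#'
#' Uses the constant-rate (exponential) convention: the per-cycle
#' probability `p_c` satisfies `1 - (1 - p_c)^k = p_annual` for `k` cycles
#' per year, i.e. `p_c = 1 - (1 - p_annual)^(1/k)`.
#'
#' @param p_annual annual probability in `[0, 1]` (vectorised).
#' @param cycles_per_year number of model cycles per year (default 12,
#'   monthly cycles).
#' @return per-cycle probability of the same length as `p_annual`.
#' @export
annual_to_cycle_probability <- function(p_annual, cycles_per_year = 12L) {
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual > 1)) {
    stop("annual probability must lie in [0, 1]")
  }
  if (cycles_per_year < 1) stop("cycles_per_year must be >= 1")
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' Compound a per-cycle probability back to an annual probability
#'
#' Inverse of [annual_to_cycle_probability()].
#'
#' @param p_cycle per-cycle probability in `[0, 1]`.
#' @param cycles_per_year cycles per year.
#' @return annual probability.
#' @export
cycle_to_annual_probability <- function(p_cycle, cycles_per_year = 12L) {
  if (any(p_cycle < 0) || any(p_cycle > 1)) stop("probability must lie in [0, 1]")
  1 - (1 - p_cycle)^cycles_per_year
}
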