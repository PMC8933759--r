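# Internal helpers shared across modules.

#' Signal a classed hemifc error
#'
#' All validation failures raise conditions whose class carries the failure
#' kind (e.g. `hemifc_error_duplicate_roi`), so callers can distinguish them
#' programmatically instead of parsing messages.
#'
#' @noRd
hemifc_stop <- function(subclass, msg, call. = FALSE) {
  cond <- structure(
    class = c(subclass, "hemifc_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

hemifc_warn <- function(subclass, msg) {
  cond <- structure(
    class = c(subclass, "hemifc_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cond)
}

#' Fisher z-transform with clamping
#'
#' Correlations are clamped to +/-(1 - 1e-12) before `atanh` so perfectly
#' correlated columns yield a large finite score instead of +/-Inf.
#'
#' @param r numeric vector or matrix of correlations in `[-1, 1]`.
#' @return `atanh` of the clamped input, same shape.
#' @export
#' @examples
#' fisher_z(0.25)
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in the
#' reporting module use the conventional half-up rule instead.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-unit sub-seed derived from a master seed; kept below
# 2^31 so it is always a valid R integer seed.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 16807) %% 2147483647)
}
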