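# Module II (model V2): long-range bipole grouping. Each channel's two
# collinear lobes are filtered separately and their (saturated) responses
# multiplied, so a cell fires only when both sides of its axis receive
# aligned input -- gap bridging with suppression of isolated responses.

#' Saturating transfer for bipole subfields
#'
#' Naka-Rushton style soft saturation `x / (s + x)` on rectified input:
#' zero at zero (so the multiplicative AND is exact), linear for small
#' input, bounded by 1.
#'
#' @param x numeric (lobe correlation output).
#' @param s semi-saturation constant.
#' @keywords internal
bipole_transfer <- function(x, s = 0.1) {
  x <- pmax(x, 0)
  x / (s + x)
}

#' Multiplicative bipole combination
#'
#' Per (orientation, frequency) channel:
#' `g(lobe1 * v1) x g(lobe2 * v1)` with `g` the saturating transfer.
#' The response is zero wherever either subfield receives no input.
#'
#' @param v1 nonnegative `feature_stack` (module I output).
#' @param lobes a `filter_bank` of kind `"bipole_lobes"` on the same
#'   `(theta, omega)` grid.
#' @param transfer_s semi-saturation constant of the subfield transfer.
#' @param plan optional precomputed [conv_plan()].
#' @return a nonnegative `feature_stack`.
#' @export
bipole_combine <- function(v1, lobes, transfer_s = 0.05, plan = NULL) {
  stopifnot(inherits(v1, "feature_stack"),
            inherits(lobes, "filter_bank"), lobes$kind == "bipole_lobes")
  spec <- lobes$spec
  if (!isTRUE(all.equal(attr(v1, "thetas"), spec$thetas)) ||
      !isTRUE(all.equal(attr(v1, "omegas"), spec$omegas))) {
    stop("bipole_combine: (theta, omega) grid mismatch with module I stack")
  }
  if (is.null(plan)) plan <- conv_plan(dim(v1)[1:2], bank_flat_kernels(lobes))
  vals <- array(0, dim(v1))
  for (o in seq_len(spec$n_orientations)) {
    for (f in seq_len(spec$n_frequencies)) {
      tag <- paste0("o", o, "f", f)
      r <- conv_apply(plan, v1[, , o, f],
                      which = paste0(tag, c(".lobe1", ".lobe2")))
      vals[, , o, f] <- bipole_transfer(r[[1]], transfer_s) *
                        bipole_transfer(r[[2]], transfer_s)
    }
  }
  feature_stack(vals, spec$thetas, spec$omegas)
}

#' Module II: grouped, normalized V2 stack
#'
#' Bipole combination as the drive into the generic cascade stage. The
#' higher-module feedback (sketch and depth pathways) enters through the
#' standard gated modulation.
#'
#' @inheritParams bipole_combine
#' @param params a [cascade_params()].
#' @param feedback NULL or a `feature_stack` on the same grid.
#' @param n_cycles fixed-point sweeps within the stage.
#' @return a nonnegative `feature_stack`.
#' @export
module_II <- function(v1, lobes, params = cascade_params(),
                      feedback = NULL, n_cycles = 1L, transfer_s = 0.05,
                      plan = NULL) {
  run_stage(v1, lobes,
            combine = function(x, bk) bipole_combine(x, bk, transfer_s, plan),
            feedback_source = feedback, p = params, n_cycles = n_cycles)
}
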