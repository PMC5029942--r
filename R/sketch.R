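# Module III (model V4 orientation contrast): borderlines of regions
# grouped by orientation similarity, sharpened by center-surround
# enhancement and cascade normalization; the maximum over channels is the
# 2D sketch (white = boundary/ridge).

#' Edge/line responses on grouped maps
#'
#' Applies the matching-orientation second-derivative kernel to each
#' (orientation, frequency) channel of the grouped stack. Responses are
#' signed; they are rectified on entry into the cascade.
#'
#' @param v2 a `feature_stack` (module II output).
#' @param bank a `filter_bank` of kind `"second_derivative"` on the same
#'   grid.
#' @param plan optional precomputed [conv_plan()].
#' @return a signed `feature_stack`.
#' @export
edge_line_responses <- function(v2, bank, plan = NULL) {
  stopifnot(inherits(v2, "feature_stack"),
            inherits(bank, "filter_bank"), bank$kind == "second_derivative")
  spec <- bank$spec
  if (!isTRUE(all.equal(attr(v2, "thetas"), spec$thetas)) ||
      !isTRUE(all.equal(attr(v2, "omegas"), spec$omegas))) {
    stop("edge_line_responses: grid mismatch with module II stack")
  }
  if (is.null(plan)) plan <- conv_plan(dim(v2)[1:2], bank_flat_kernels(bank))
  vals <- array(0, dim(v2))
  for (o in seq_len(spec$n_orientations)) {
    for (f in seq_len(spec$n_frequencies)) {
      vals[, , o, f] <- conv_apply(plan, v2[, , o, f],
                                   which = paste0("o", o, "f", f))[[1]]
    }
  }
  feature_stack(vals, spec$thetas, spec$omegas, signed = TRUE)
}

#' Center-surround enhancement of a stack
#'
#' Correlates every channel with an isotropic difference-of-Gaussians
#' kernel and rectifies, sharpening ridges without widening them.
#'
#' @param resp a `feature_stack` (rectified edge/line responses).
#' @param dog a DoG kernel from [make_dog_kernel()].
#' @return a nonnegative `feature_stack`.
#' @export
dog_enhance <- function(resp, dog) {
  stopifnot(inherits(resp, "feature_stack"))
  plan <- conv_plan(dim(resp)[1:2], list(dog = dog))
  vals <- array(0, dim(resp))
  d <- dim(resp)
  for (o in seq_len(d[3])) for (f in seq_len(d[4])) {
    vals[, , o, f] <- pmax(conv_apply(plan, resp[, , o, f])[[1]], 0)
  }
  fs_like(vals, resp)
}

#' Module III: normalized orientation-contrast stack
#'
#' Second-derivative filtering, rectification and DoG enhancement as the
#' drive into the generic cascade stage.
#'
#' @inheritParams edge_line_responses
#' @param dog DoG kernel (see [make_dog_kernel()]).
#' @param params a [cascade_params()].
#' @param feedback NULL or higher-module `feature_stack`.
#' @param n_cycles fixed-point sweeps within the stage.
#' @return a nonnegative `feature_stack`.
#' @export
module_III <- function(v2, bank, dog = make_dog_kernel(1, 2),
                       params = cascade_params(), feedback = NULL,
                       n_cycles = 1L, plan = NULL) {
  combine <- function(x, bk) {
    dog_enhance(rect(edge_line_responses(x, bk, plan = plan)), dog)
  }
  run_stage(v2, bank, combine, feedback_source = feedback,
            p = params, n_cycles = n_cycles)
}

#' 2D sketch map
#'
#' Runs the module III cascade (when given a grouped stack) and collapses
#' it by the maximum over orientation and frequency: a single map whose
#' bright values trace boundaries and ridges of the grouped regions.
#'
#' @param x either a module III output `feature_stack`, or a module II
#'   stack (in which case `bank` must be supplied and the cascade is run
#'   first).
#' @param bank optional `second_derivative` bank (when `x` is a module II
#'   stack).
#' @param ... further arguments passed to [module_III()].
#' @return numeric matrix (the sketch).
#' @export
sketch_map <- function(x, bank = NULL, ...) {
  stopifnot(inherits(x, "feature_stack"))
  if (!is.null(bank)) x <- module_III(x, bank, ...)
  fs_max_feat(x)
}

#' Write a sketch (or any single map) as an 8-bit PNG
#'
#' Values are linearly rescaled to `[0, 1]`; white marks boundaries.
#'
#' @param map numeric matrix.
#' @param path output PNG path.
#' @export
export_map_png <- function(map, path) {
  rng <- range(map, finite = TRUE)
  z <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
  z[!is.finite(z)] <- 0
  png::writePNG(z, path)
  invisible(path)
}
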