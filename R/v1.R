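# Module I (model V1): multi-orientation, multi-frequency texture-energy
# decomposition of the input image.

#' Quadrature texture energy
#'
#' Amplitude of the complex Gabor response,
#' `sqrt(even^2 + odd^2)` per (orientation, frequency) channel. Because
#' both kernels are zero-mean the amplitude is invariant to a global
#' illumination offset.
#'
#' @param image numeric matrix, grayscale in `[0, 1]` (any finite range is
#'   accepted; only offsets are guaranteed irrelevant).
#' @param bank a `filter_bank` of kind `"gabor"` (see [make_gabor_bank()]).
#' @param plan optional precomputed [conv_plan()] over the bank's flattened
#'   kernels (reused across feedback cycles by the full model).
#' @return a nonnegative `feature_stack`.
#' @export
texture_energy <- function(image, bank, plan = NULL) {
  if (!is.matrix(image) || !all(is.finite(image))) {
    stop("image must be a finite 2D numeric matrix")
  }
  stopifnot(inherits(bank, "filter_bank"), bank$kind == "gabor")
  spec <- bank$spec
  if (is.null(plan)) plan <- conv_plan(dim(image), bank_flat_kernels(bank))
  resp <- conv_apply(plan, image)
  vals <- array(0, c(dim(image), spec$n_orientations, spec$n_frequencies))
  for (o in seq_len(spec$n_orientations)) {
    for (f in seq_len(spec$n_frequencies)) {
      tag <- paste0("o", o, "f", f)
      vals[, , o, f] <- sqrt(resp[[paste0(tag, ".even")]]^2 +
                             resp[[paste0(tag, ".odd")]]^2)
    }
  }
  feature_stack(vals, spec$thetas, spec$omegas)
}

#' Module I: normalized V1 stack
#'
#' Texture energy as the drive into the generic cascade stage
#' (normalization plus optional modulatory feedback from higher modules).
#'
#' @inheritParams texture_energy
#' @param params a [cascade_params()].
#' @param feedback NULL or a `feature_stack` on the same grid (higher
#'   module activity resampled to V1's channels).
#' @param n_cycles fixed-point sweeps within the stage.
#' @return a nonnegative `feature_stack`.
#' @export
module_I <- function(image, bank, params = cascade_params(),
                     feedback = NULL, n_cycles = 1L, plan = NULL) {
  run_stage(image, bank,
            combine = function(im, bk) texture_energy(im, bk, plan = plan),
            feedback_source = feedback, p = params, n_cycles = n_cycles)
}
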