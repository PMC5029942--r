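# Full model configuration: channel grids, per-module cascade parameters,
# filter shape parameters and feedback wiring. The per-module cascade
# constants are implementer defaults tuned on the package's property suite
# (flat-scene null, slant monotonicity, ridge reduction under feedback);
# every one of them is exposed here.

#' Model configuration
#'
#' @param n_orientations,n_frequencies channel grid (see
#'   [filter_bank_spec()]).
#' @param freq_range frequency range in cycles/pixel.
#' @param n_cycles total number of model passes; the first pass is pure
#'   feedforward, later passes add the gated feedback (so `n_cycles = 1`
#'   or `feedback = FALSE` is the feedforward regime).
#' @param feedback enable the descending feedback paths.
#' @param relax relaxation factor of the damped synchronous update
#'   (`new <- relax * computed + (1 - relax) * previous`); 1 is the raw
#'   update, values below 1 damp feedback-loop oscillation.
#' @param params_v1,params_v2,params_v3,params_v4 per-module
#'   [cascade_params()].
#' @param fb_gains named list of per-edge feedback gains:
#'   `I_from_II`, `I_from_IV`, `II_from_III`, `II_from_IV`.
#' @param gabor_aspect V1 envelope across/along sigma ratio.
#' @param band_gain frequency-weighting exponent of the V1 bank (see
#'   [make_gabor_bank()]): finer bands get gain `(omega/freq_min)^band_gain`,
#'   making summed texture energy increase under compression.
#' @param bipole_length,bipole_aspect,bipole_separation V2 lobe length
#'   (relative to the Gabor envelope), across/along ratio and half
#'   separation (in lobe sigmas).
#' @param transfer_s semi-saturation of the bipole subfield transfer.
#' @param sd_elongation,dog_sigmas module III second-derivative elongation
#'   and DoG `c(center, surround)` sigmas.
#' @param fd_elongation module IV first-derivative elongation.
#' @param fd_sigma_scale scale multiplier of the gradient bank (see
#'   [make_first_derivative_bank()]).
#' @param fd_gain_sigma local contrast gain pool (pixels) applied to the
#'   gradient responses (see [energy_gradient()]'s `gain_sigma`).
#' @param border_taper raised-cosine apodization width (pixels) applied to
#'   the gradient responses at the image border before integration (the
#'   frame edge is not a texture gradient).
#' @param it_extent IT integration reach in pixels; NULL scales it to a
#'   third of the object mask diameter.
#' @param it_sharpness sigmoid truncation slope of the IT lobes (1/px).
#' @param it_lateral lateral sigma of the IT lobes as a fraction of the
#'   integration reach (see [make_it_integration_bank()]).
#' @param it_drive_gain scalar gain of the integrated depth drive (sets
#'   module IV's normalization operating point; see
#'   [directed_integration()]).
#' @param it_opponent opponent weight of the opposing integration path
#'   (see [directed_integration()]; 0, the default, is the plain hard
#'   maximum).
#' @param contour_direction assumed integration direction in radians for
#'   contour textures (NULL = none; both integration paths weighted
#'   equally).
#' @param direction_low_weight weight floor for IT lobes misaligned with
#'   `contour_direction`.
#' @param sketch_input `"per_channel"` routes each (orientation,
#'   frequency) grouped map to module III; `"freq_summed"` first sums the
#'   grouped stack over frequency.
#' @param patch_sigma pooling sigma of the surface-orientation estimator.
#' @param smooth_sigma final depth smoothing sigma.
#' @param v1_transfer optional pointwise nonlinearity applied to the V1
#'   texture-energy drive (identity by default).
#' @return an object of class `texdepth_config`.
#' @export
texdepth_config <- function(n_orientations = 8L, n_frequencies = 4L,
                            freq_range = c(0.03, 0.25),
                            n_cycles = 3L, feedback = TRUE, relax = 0.8,
                            params_v1 = cascade_params(pool_sigma = 3),
                            params_v2 = cascade_params(lambda_fb = 0.2,
                                                       pool_sigma = 6),
                            params_v3 = cascade_params(pool_sigma = 6),
                            params_v4 = cascade_params(pool_sigma = 8),
                            fb_gains = list(I_from_II = 2, I_from_IV = 0,
                                            II_from_III = 1, II_from_IV = 3),
                            gabor_aspect = 1, band_gain = 1,
                            bipole_length = 2.5, bipole_aspect = 0.25,
                            bipole_separation = 2,
                            transfer_s = 0.05,
                            sd_elongation = 2, dog_sigmas = c(1, 2),
                            fd_elongation = 2, fd_sigma_scale = 1,
                            fd_gain_sigma = 36, border_taper = 12,
                            it_extent = NULL, it_sharpness = 1,
                            it_lateral = 0.35, it_opponent = 0,
                            it_drive_gain = 10,
                            contour_direction = NULL,
                            direction_low_weight = 0.1,
                            sketch_input = c("freq_summed", "per_channel"),
                            patch_sigma = 8, smooth_sigma = 3,
                            v1_transfer = identity) {
  sketch_input <- match.arg(sketch_input)
  stopifnot(n_cycles >= 1L, length(freq_range) == 2L,
            freq_range[1] < freq_range[2])
  structure(list(n_orientations = as.integer(n_orientations),
                 n_frequencies = as.integer(n_frequencies),
                 freq_range = freq_range,
                 n_cycles = as.integer(n_cycles), feedback = feedback,
                 relax = relax,
                 params_v1 = params_v1, params_v2 = params_v2,
                 params_v3 = params_v3, params_v4 = params_v4,
                 fb_gains = fb_gains,
                 gabor_aspect = gabor_aspect, band_gain = band_gain,
                 bipole_length = bipole_length,
                 bipole_aspect = bipole_aspect,
                 bipole_separation = bipole_separation,
                 transfer_s = transfer_s,
                 sd_elongation = sd_elongation, dog_sigmas = dog_sigmas,
                 fd_elongation = fd_elongation,
                 fd_sigma_scale = fd_sigma_scale,
                 fd_gain_sigma = fd_gain_sigma,
                 border_taper = border_taper,
                 it_extent = it_extent, it_sharpness = it_sharpness,
                 it_lateral = it_lateral, it_opponent = it_opponent,
                 it_drive_gain = it_drive_gain,
                 contour_direction = contour_direction,
                 direction_low_weight = direction_low_weight,
                 sketch_input = sketch_input,
                 patch_sigma = patch_sigma, smooth_sigma = smooth_sigma,
                 v1_transfer = v1_transfer),
            class = "texdepth_config")
}

#' @export
print.texdepth_config <- function(x, ...) {
  cat(sprintf("<texdepth_config> %d orientations x %d bands on [%.3g, %.3g] c/px, %d cycle(s), feedback %s\n",
              x$n_orientations, x$n_frequencies, x$freq_range[1],
              x$freq_range[2], x$n_cycles,
              if (x$feedback) "on" else "off"))
  invisible(x)
}
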