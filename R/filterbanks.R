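# Receptive-field kernel families for the four model areas.
#
# Orientation convention: theta is the axis of elongation (the orientation
# of the stripes/contours a kernel responds to), in radians on [0, pi),
# measured from the +x (column) axis toward increasing row index. Axial
# identification theta == theta + pi holds throughout. Frequencies omega
# are carrier frequencies in cycles/pixel, log-spaced.

# sigma of the Gabor envelope across the stripes for ~1 octave half-power
# bandwidth: sigma = C / omega with
GABOR_BW_CONST <- sqrt(log(2) / 2) / pi * (2^1 + 1) / (2^1 - 1)  # ~0.562

#' Filter bank specification
#'
#' Describes the orientation/frequency grid and shape parameters shared by
#' the kernel constructors. Orientations are linearly spaced on `[0, pi)`;
#' frequencies are logarithmically spaced on `[freq_min, freq_max]`.
#'
#' @param n_orientations number of orientation channels (>= 2).
#' @param n_frequencies number of spatial-frequency bands (>= 1).
#' @param freq_min,freq_max frequency range in cycles/pixel.
#' @param aspect_ratio ratio of across-axis to along-axis Gaussian sigma
#'   (< 1 means elongated along the orientation axis).
#' @param lobe_separation center-to-center half-separation of paired lobes,
#'   in units of the lobe's along-axis sigma.
#' @param sigmoid_sharpness slope (1/pixels) of the sigmoidal truncation
#'   used by the IT integration bank.
#' @return an object of class `filter_bank_spec`.
#' @export
filter_bank_spec <- function(n_orientations = 8L, n_frequencies = 4L,
                             freq_min = 0.03, freq_max = 0.25,
                             aspect_ratio = 1, lobe_separation = 2,
                             sigmoid_sharpness = 1) {
  stopifnot(n_orientations >= 2L, n_frequencies >= 1L)
  if (n_frequencies > 1L && !(freq_min < freq_max)) {
    stop("freq_min must be < freq_max")
  }
  stopifnot(aspect_ratio > 0, lobe_separation > 0, sigmoid_sharpness >= 0)
  thetas <- seq(0, pi, length.out = n_orientations + 1L)[seq_len(n_orientations)]
  omegas <- if (n_frequencies == 1L) freq_min else {
    exp(seq(log(freq_min), log(freq_max), length.out = n_frequencies))
  }
  structure(list(n_orientations = as.integer(n_orientations),
                 n_frequencies = as.integer(n_frequencies),
                 freq_min = freq_min, freq_max = freq_max,
                 thetas = thetas, omegas = omegas,
                 aspect_ratio = aspect_ratio,
                 lobe_separation = lobe_separation,
                 sigmoid_sharpness = sigmoid_sharpness),
            class = "filter_bank_spec")
}

#' @keywords internal
new_filter_bank <- function(kind, spec, kernels) {
  structure(list(kind = kind, spec = spec, kernels = kernels),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank>", x$kind, ":", x$spec$n_orientations, "orientations x",
      x$spec$n_frequencies, "frequency bands\n")
  invisible(x)
}

#' Fetch one kernel (or lobe set) from a bank
#' @param bank a `filter_bank`.
#' @param o,f orientation and frequency index.
#' @export
bank_kernel <- function(bank, o, f = 1L) bank$kernels[[o]][[f]]

#' @keywords internal
check_support <- function(h, sigma_max, max_support = NULL) {
  if (!is.null(max_support) && max_support < 3 * sigma_max) {
    stop("kernel support truncates the Gaussian envelope below 3*sigma; ",
         "increase the support or reduce the spatial scale")
  }
  if (!is.null(max_support)) min(h, as.integer(max_support)) else h
}

#' Quadrature Gabor bank (model V1)
#'
#' One even (cosine-phase) and one odd (sine-phase) Gabor per
#' (orientation, frequency). The carrier runs perpendicular to `theta`, so
#' `theta` is the orientation of the stripes the filter prefers. The even
#' kernel is DC-corrected to exactly zero mean; the odd kernel sums to zero
#' by antisymmetry. Envelope sigma across the stripes is
#' `0.562 / omega` (about one octave of bandwidth).
#'
#' @param spec a [filter_bank_spec()].
#' @param max_support optional cap (in pixels) on the kernel half-width;
#'   an error is raised if it would truncate the envelope below 3 sigma.
#' @param band_gain exponent of the frequency weighting
#'   `(omega / freq_min)^band_gain` applied to each band's gain. With 0
#'   every band responds with unit gain to its matched grating and summed
#'   texture energy is invariant to texture compression; the default 1
#'   weights finer bands more, so compression (foreshortening) raises the
#'   summed energy -- the texture-gradient signal the depth pathway
#'   integrates.
#' @return a `filter_bank` of kind `"gabor"`, each cell a list with
#'   elements `even` and `odd`.
#' @export
make_gabor_bank <- function(spec, max_support = NULL, band_gain = 1) {
  stopifnot(inherits(spec, "filter_bank_spec"))
  kernels <- lapply(seq_len(spec$n_orientations), function(o) {
    th <- spec$thetas[o]
    lapply(seq_len(spec$n_frequencies), function(f) {
      om <- spec$omegas[f]
      sv <- GABOR_BW_CONST / om            # across stripes (carrier axis)
      su <- sv / spec$aspect_ratio         # along stripes
      h <- as.integer(ceiling(3 * max(su, sv)))
      h <- check_support(h, max(su, sv), max_support)
      g <- rot_grid(h, th)
      env <- exp(-(g$u^2 / (2 * su^2) + g$v^2 / (2 * sv^2)))
      even <- cos(2 * pi * om * g$v) * env
      even <- even - env * (sum(even) / sum(env))  # zero DC, keep envelope
      odd <- sin(2 * pi * om * g$v) * env
      # unit gain at freq_min: a matched grating of amplitude a yields
      # amplitude ~ a * (om/freq_min)^band_gain
      scale <- sum(env) / 2 / (om / spec$omegas[1])^band_gain
      list(even = even / scale, odd = odd / scale)
    })
  })
  new_filter_bank("gabor", spec, kernels)
}

#' Bipole lobe pair (model V2 long-range grouping)
#'
#' Two collinear anisotropic Gaussian lobes displaced at +/- along the
#' orientation axis (the classic figure-eight layout). Each lobe is
#' nonnegative and normalised to unit sum; the pair is mirror symmetric
#' through the center. Lobe scale is inversely proportional to omega:
#' the along-axis sigma is `length_factor` times half the Gabor envelope
#' sigma at the same band, so the pair spans roughly `length_factor`
#' Gabor envelopes and can bridge texture gaps.
#'
#' @param spec a [filter_bank_spec()]; `aspect_ratio` here is the
#'   across/along sigma ratio of each lobe and `lobe_separation` the
#'   center offset in units of the along-axis sigma.
#' @param length_factor lobe length relative to the Gabor envelope.
#' @param overlap_max maximal tolerated fraction of one lobe's mass on the
#'   far side of the center; exceeding it signals lobes too close for
#'   their scale and raises an error.
#' @return a `filter_bank` of kind `"bipole_lobes"`, cells are lists with
#'   `lobe1` (displaced toward +theta) and `lobe2`.
#' @export
make_bipole_lobes <- function(spec, length_factor = 2.5, overlap_max = 0.2) {
  stopifnot(inherits(spec, "filter_bank_spec"))
  kernels <- lapply(seq_len(spec$n_orientations), function(o) {
    th <- spec$thetas[o]
    lapply(seq_len(spec$n_frequencies), function(f) {
      om <- spec$omegas[f]
      su <- length_factor * GABOR_BW_CONST / om / 2
      sv <- spec$aspect_ratio * su
      d <- spec$lobe_separation * su
      overlap <- stats::pnorm(-d / su)
      if (overlap > overlap_max) {
        stop("bipole lobes overlap beyond ", overlap_max,
             ": separation too small for the lobe scale")
      }
      h <- as.integer(ceiling(d + 3 * su))
      l1 <- aniso_gauss(h, th, su, sv, u0 = d)
      l2 <- aniso_gauss(h, th, su, sv, u0 = -d)
      list(lobe1 = l1 / sum(l1), lobe2 = l2 / sum(l2))
    })
  })
  new_filter_bank("bipole_lobes", spec, kernels)
}

#' Second-derivative (three-lobe) bank (model V4 orientation contrast)
#'
#' A positive central anisotropic Gaussian flanked across the orientation
#' axis by two negative Gaussians of half its mass: an edge/line detector
#' for boundaries between regions grouped per orientation. Total weight is
#' exactly zero, so constants are annihilated.
#'
#' @inheritParams make_gabor_bank
#' @param elongation along-axis sigma relative to the across-axis sigma.
#' @export
make_second_derivative_bank <- function(spec, elongation = 2,
                                        max_support = NULL) {
  stopifnot(inherits(spec, "filter_bank_spec"))
  kernels <- lapply(seq_len(spec$n_orientations), function(o) {
    th <- spec$thetas[o]
    lapply(seq_len(spec$n_frequencies), function(f) {
      om <- spec$omegas[f]
      sv <- GABOR_BW_CONST / om
      su <- elongation * sv
      s <- 2 * sv
      h <- as.integer(ceiling(max(3 * su, s + 3 * sv)))
      h <- check_support(h, max(su, sv), max_support)
      gc <- aniso_gauss(h, th, su, sv); gc <- gc / sum(gc)
      gp <- aniso_gauss(h, th, su, sv, v0 = s); gp <- gp / sum(gp)
      gm <- aniso_gauss(h, th, su, sv, v0 = -s); gm <- gm / sum(gm)
      gc - 0.5 * gp - 0.5 * gm
    })
  })
  new_filter_bank("second_derivative", spec, kernels)
}

#' Isotropic difference-of-Gaussians kernel
#'
#' Center-surround enhancement kernel: unit-mass center Gaussian minus
#' unit-mass surround Gaussian, hence exactly zero total weight.
#'
#' @param sigma_center,sigma_surround Gaussian sigmas in pixels,
#'   `sigma_center < sigma_surround`.
#' @return a square, odd-sided numeric matrix.
#' @export
make_dog_kernel <- function(sigma_center = 1, sigma_surround = 2) {
  stopifnot(sigma_center < sigma_surround)
  h <- max(1L, as.integer(ceiling(3 * sigma_surround)))
  gc <- aniso_gauss(h, 0, sigma_center, sigma_center)
  gs <- aniso_gauss(h, 0, sigma_surround, sigma_surround)
  gc / sum(gc) - gs / sum(gs)
}

#' First-derivative (two-lobe) bank (model V4 texture-energy gradient)
#'
#' One positive and one negative unit-mass anisotropic Gaussian displaced
#' at +/- one across-axis sigma along the gradient direction
#' (perpendicular to the elongation axis theta). Total weight is zero.
#' Applied in a single contrast polarity, its response is signed: positive
#' where the input increases along the `theta + pi/2` direction.
#'
#' @inheritParams make_second_derivative_bank
#' @param sigma_scale multiplier on the per-band Gaussian sigma: values
#'   above 1 differentiate the energy field at a coarser scale than the
#'   texture itself, suppressing element-scale fluctuations while keeping
#'   surface-scale gradients.
#' @export
make_first_derivative_bank <- function(spec, elongation = 2,
                                       max_support = NULL, sigma_scale = 1) {
  stopifnot(inherits(spec, "filter_bank_spec"), sigma_scale > 0)
  kernels <- lapply(seq_len(spec$n_orientations), function(o) {
    th <- spec$thetas[o]
    lapply(seq_len(spec$n_frequencies), function(f) {
      om <- spec$omegas[f]
      sv <- sigma_scale * GABOR_BW_CONST / om
      su <- elongation * sv
      s <- sv
      h <- as.integer(ceiling(max(3 * su, s + 3 * sv)))
      h <- check_support(h, max(su, sv), max_support)
      gp <- aniso_gauss(h, th, su, sv, v0 = s); gp <- gp / sum(gp)
      gm <- aniso_gauss(h, th, su, sv, v0 = -s); gm <- gm / sum(gm)
      gp - gm
    })
  })
  new_filter_bank("first_derivative", spec, kernels)
}

#' Signed one-sided integration lobes (model IT directed integration)
#'
#' For each orientation theta, a pair of large anisotropic Gaussian lobes
#' displaced along the integration direction `theta + pi/2` and truncated
#' by a 2D sigmoid so that each keeps weight on only one side of the
#' center. The positive lobe has support behind the cell (toward
#' `theta - pi/2`), so its response accumulates in the direction of
#' increasing input; the negative lobe is its sign-flipped mirror image and
#' realises the opposite integration path. Lobes are elongated along theta
#' and normalised to unit absolute mass. Their extent is set by `extent`
#' (typically a fraction of the object size), not by the frequency grid, so
#' the bank usually carries a single frequency band.
#'
#' @param spec a [filter_bank_spec()]; `sigmoid_sharpness` sets the
#'   truncation slope in 1/pixels (at 0 the truncation degenerates to the
#'   constant 1/2 and each lobe is proportional to its full Gaussian).
#' @param extent integration reach in pixels (lobe length along the
#'   integration direction).
#' @param lateral_factor lateral (along-theta) sigma as a fraction of
#'   `extent`; larger values pool more texture across the integration
#'   path and reduce realization noise in the depth field.
#' @param length_factor sigma of the lobe along the integration direction
#'   as a fraction of `extent`; values well above 1 make the weighting
#'   nearly flat over the reach, so integration approaches a one-sided
#'   cumulative sum.
#' @param offset_factor displacement of the lobe center along the
#'   integration direction as a fraction of `extent`.
#' @param max_support optional cap (pixels) on the kernel half-width.
#' @param normalize `"mass"` (default) scales each lobe to unit total
#'   mass; `"path"` scales to unit lateral mass at the strongest
#'   cross-section (the two differ only by a scalar; the cascade's
#'   operating point is set separately by the drive gain).
#' @return a `filter_bank` of kind `"it_signed_lobes"`, cells are lists
#'   with `pos` (all weights >= 0) and `neg` (all weights <= 0).
#' @export
make_it_integration_bank <- function(spec, extent = 50,
                                     lateral_factor = 0.35,
                                     length_factor = 0.5,
                                     offset_factor = 0.5,
                                     max_support = NULL,
                                     normalize = c("mass", "path")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(spec, "filter_bank_spec"), extent > 0,
            spec$sigmoid_sharpness >= 0, lateral_factor > 0,
            length_factor > 0, offset_factor >= 0)
  kappa <- spec$sigmoid_sharpness
  kernels <- lapply(seq_len(spec$n_orientations), function(o) {
    th <- spec$thetas[o]
    lapply(seq_len(spec$n_frequencies), function(f) {
      su <- lateral_factor * extent        # along theta (lateral pooling)
      sv <- length_factor * extent         # along integration direction
      d <- offset_factor * extent
      h <- as.integer(ceiling(max(3 * su, d + 2.5 * sv)))
      if (!is.null(max_support)) h <- min(h, as.integer(max_support))
      g <- rot_grid(h, th)
      sig <- function(z) 1 / (1 + exp(kappa * z))   # ~1 for z<0 when kappa>0
      base <- exp(-(g$u^2 / (2 * su^2)))
      pos <- base * exp(-((g$v + d)^2 / (2 * sv^2))) * sig(g$v)
      neg <- base * exp(-((g$v - d)^2 / (2 * sv^2))) * sig(-g$v)
      scale_of <- function(k) {
        if (normalize == "mass") return(sum(k))
        # strongest lateral cross-section: bin weights by the rounded
        # along-path coordinate and take the largest section mass
        max(tapply(as.vector(k), round(as.vector(g$v)), sum))
      }
      list(pos = pos / scale_of(pos), neg = -neg / scale_of(neg))
    })
  })
  new_filter_bank("it_signed_lobes", spec, kernels)
}

#' @keywords internal
bank_flat_kernels <- function(bank) {
  # flatten to a named list "o<i>f<j>" or "o<i>f<j>.<part>" for conv plans
  out <- list()
  for (o in seq_len(bank$spec$n_orientations)) {
    for (f in seq_len(bank$spec$n_frequencies)) {
      k <- bank$kernels[[o]][[f]]
      tag <- paste0("o", o, "f", f)
      if (is.matrix(k)) {
        out[[tag]] <- k
      } else {
        for (part in names(k)) out[[paste0(tag, ".", part)]] <- k[[part]]
      }
    }
  }
  out
}

#' Export a bank as a PNG kernel gallery
#'
#' Writes a grid of kernel images (orientations as rows, frequencies --
#' and lobes, where a cell holds several -- as columns), each kernel
#' rescaled symmetrically so zero maps to mid gray.
#'
#' @param bank a `filter_bank`.
#' @param path output PNG file path.
#' @export
export_bank_gallery <- function(bank, path) {
  cells <- list()
  for (o in seq_len(bank$spec$n_orientations)) {
    row <- list()
    for (f in seq_len(bank$spec$n_frequencies)) {
      k <- bank$kernels[[o]][[f]]
      row <- c(row, if (is.matrix(k)) list(k) else unname(k))
    }
    cells[[o]] <- row
  }
  ncell <- max(vapply(cells, length, integer(1)))
  side <- max(unlist(lapply(cells, function(r) vapply(r, nrow, integer(1)))))
  img <- matrix(0.5, length(cells) * side, ncell * side)
  for (o in seq_along(cells)) {
    for (j in seq_along(cells[[o]])) {
      k <- cells[[o]][[j]]
      m <- max(abs(k), 1e-12)
      tile <- 0.5 + k / (2 * m)
      r0 <- (o - 1L) * side + (side - nrow(k)) %/% 2L
      c0 <- (j - 1L) * side + (side - ncol(k)) %/% 2L
      img[r0 + seq_len(nrow(k)), c0 + seq_len(ncol(k))] <- tile
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
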