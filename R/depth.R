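# Module IV (model V4 gradient + model IT directed integration) and the
# top-level estimator. The total grouped texture energy from module II is
# differentiated by signed first-derivative filters; the signed responses
# are integrated by one-sided IT lobes, so activity accumulates in the
# direction of increasing energy (positive responses) and of decreasing
# energy (negative responses, opposite path). The per-channel maximum of
# the two paths is summed over channels into a raw activity field in which
# higher activity means farther away; finalization masks, smooths, inverts
# and rescales it to [0, 1] with 1 nearest.

#' Signed texture-energy gradient
#'
#' Applies the first-derivative bank to the total (summed over all
#' channels) module II activity map. Responses are positive where the
#' summed energy increases along `theta + pi/2` and cancel exactly over
#' spatially constant energy, however anisotropic the underlying texture.
#'
#' @param total numeric matrix: summed module II activity.
#' @param bank a `filter_bank` of kind `"first_derivative"`.
#' @param plan optional precomputed [conv_plan()].
#' @param taper width (pixels) of a raised-cosine apodization of the
#'   responses at the image border; the frame edge is not a texture
#'   gradient, and untapered responses there would be integrated as
#'   spurious depth steps. 0 disables.
#' @param coverage a precomputed [gradient_coverage()] calibration, or
#'   TRUE to compute one on the fly. Near the mirror-padded border an
#'   antisymmetric kernel's response cancels against its own reflection;
#'   dividing by the kernel's response to an ideal unit ramp flat-fields
#'   that attenuation. Off (FALSE) by default: on the textured scenes this
#'   package targets, the correction amplifies border realization noise
#'   by more than it removes systematic attenuation.
#' @param gain_sigma sigma (pixels) of the local gain pool: each signed
#'   response is divided by the Gaussian-pooled magnitude of its own
#'   channel (`x / (c + pool(|x|))`, with `c` a fifth of the channel's
#'   mean magnitude). This contrast gain control equalises the rectified
#'   noise floor across the image -- without it the floor tracks local
#'   texture coarseness, which under perspective projection is itself a
#'   depth correlate of the wrong sign. 0 disables.
#' @return a signed `feature_stack`.
#' @export
energy_gradient <- function(total, bank, plan = NULL, taper = 0,
                            coverage = FALSE, gain_sigma = 0) {
  stopifnot(is.matrix(total), inherits(bank, "filter_bank"),
            bank$kind == "first_derivative")
  spec <- bank$spec
  if (is.null(plan)) plan <- conv_plan(dim(total), bank_flat_kernels(bank))
  if (isTRUE(coverage)) coverage <- gradient_coverage(dim(total), bank, plan)
  resp <- conv_apply(plan, total)
  w <- border_window(dim(total), taper)
  vals <- array(0, c(dim(total), spec$n_orientations, spec$n_frequencies))
  for (o in seq_len(spec$n_orientations)) {
    for (f in seq_len(spec$n_frequencies)) {
      tag <- paste0("o", o, "f", f)
      r <- resp[[tag]]
      if (is.list(coverage)) r <- r / coverage[[tag]]
      if (gain_sigma > 0) {
        r <- r / (0.5 * mean(abs(r)) + gauss_smooth(abs(r), gain_sigma))
      }
      vals[, , o, f] <- r * w
    }
  }
  feature_stack(vals, spec$thetas, spec$omegas, signed = TRUE)
}

#' Border attenuation calibration for a gradient bank
#'
#' Correlates each first-derivative kernel with an ideal unit-slope ramp
#' along its own gradient direction under the same mirror-padded
#' convolution used for real inputs, and normalises by the interior
#' response. The result is ~1 in the interior and falls toward 0 where
#' reflection cancels the kernel; values are floored at 0.2 so the
#' correction never amplifies by more than 5x.
#'
#' @param dim_im image size `c(rows, cols)`.
#' @param bank a first-derivative `filter_bank`.
#' @param plan optional matching [conv_plan()].
#' @return named list of coverage matrices, one per `o<i>f<j>` kernel.
#' @export
gradient_coverage <- function(dim_im, bank, plan = NULL) {
  stopifnot(bank$kind == "first_derivative")
  spec <- bank$spec
  if (is.null(plan)) plan <- conv_plan(dim_im, bank_flat_kernels(bank))
  X <- matrix(seq_len(dim_im[2]), dim_im[1], dim_im[2], byrow = TRUE)
  Y <- matrix(seq_len(dim_im[1]), dim_im[1], dim_im[2])
  out <- list()
  ctr <- pmax(1L, dim_im %/% 2L)
  for (o in seq_len(spec$n_orientations)) {
    th <- spec$thetas[o]
    ramp <- -X * sin(th) + Y * cos(th)   # unit slope along theta + pi/2
    r <- conv_apply(plan, ramp,
                    which = paste0("o", o, "f", seq_len(spec$n_frequencies)))
    for (f in seq_len(spec$n_frequencies)) {
      cc <- r[[f]]
      interior <- cc[ctr[1], ctr[2]]
      out[[paste0("o", o, "f", f)]] <- pmax(cc / interior, 0.2)
    }
  }
  out
}

#' @keywords internal
border_window <- function(dim_im, taper) {
  if (taper <= 0) return(1)
  ramp <- function(n) {
    w <- rep(1, n)
    k <- min(taper, n %/% 2)
    edge <- 0.5 * (1 - cos(pi * (seq_len(k) - 0.5) / k))
    w[seq_len(k)] <- edge
    w[n + 1 - seq_len(k)] <- edge
    w
  }
  outer(ramp(dim_im[1]), ramp(dim_im[2]))
}

#' @keywords internal
it_lobe_weights <- function(thetas, direction = NULL, low_weight = 0.1) {
  # per-orientation weights for the two integration paths. With no
  # preferred direction every path gets 1. With a direction, the weight
  # favours the integration *axis* aligned with it: both paths of the
  # aligned channel keep full weight while transverse channels fall
  # toward low_weight (the assumed direction resolves which fields carry
  # the integration, not which way along them it runs).
  n <- length(thetas)
  if (is.null(direction)) {
    return(list(pos = rep(1, n), neg = rep(1, n)))
  }
  w <- low_weight + (1 - low_weight) * abs(cos(direction - (thetas + pi / 2)))
  list(pos = w, neg = w)
}

#' Directed integration of gradient responses
#'
#' Per (orientation, frequency) channel the rectified positive gradient
#' part is correlated with the matching-orientation positive IT lobe and
#' the rectified negative part with (the absolute value of) the negative
#' lobe. The two integration paths are combined by a rule favoring the
#' maximum: `max(a, b) - opponent * min(a, b)`, which is nonnegative
#' (the plain hard maximum at the default `opponent = 0`). The IT bank
#' carries one kernel pair per orientation (its extent is an object-scale
#' property) and is shared across the gradient's frequency bands.
#'
#' @param grad signed `feature_stack` from [energy_gradient()].
#' @param it_bank a `filter_bank` of kind `"it_signed_lobes"` whose
#'   orientation grid matches `grad`'s.
#' @param direction optional integration axis (radians): channels whose
#'   integration axis aligns with it keep weight 1, transverse channels
#'   are reduced toward `low_weight` (used for contour textures where the
#'   carrying direction must be assumed).
#' @param low_weight weight floor for misaligned lobes.
#' @param opponent weight of the opposing path's subtraction in `[0, 1]`
#'   (0 recovers the plain hard maximum).
#' @param drive_gain scalar gain on the integrated responses before they
#'   enter the cascade; it sets the operating point of module IV's
#'   saturating normalization (the lobes themselves are unit mass).
#' @param plan optional precomputed [conv_plan()].
#' @return a nonnegative `feature_stack` on `grad`'s grid.
#' @export
directed_integration <- function(grad, it_bank, direction = NULL,
                                 low_weight = 0.1, opponent = 0,
                                 drive_gain = 1, plan = NULL) {
  stopifnot(opponent >= 0, opponent <= 1, drive_gain > 0)
  stopifnot(inherits(grad, "feature_stack"),
            inherits(it_bank, "filter_bank"),
            it_bank$kind == "it_signed_lobes")
  thetas <- attr(grad, "thetas")
  if (!isTRUE(all.equal(thetas, it_bank$spec$thetas))) {
    stop("directed_integration: orientation grids do not match")
  }
  w <- it_lobe_weights(thetas, direction, low_weight)
  if (is.null(plan)) {
    kers <- list()
    for (o in seq_along(thetas)) {
      kers[[paste0("o", o, ".pos")]] <- it_bank$kernels[[o]][[1]]$pos
      kers[[paste0("o", o, ".neg")]] <- abs(it_bank$kernels[[o]][[1]]$neg)
    }
    plan <- conv_plan(dim(grad)[1:2], kers)
  }
  d <- dim(grad)
  vals <- array(0, d)
  for (o in seq_len(d[3])) {
    for (f in seq_len(d[4])) {
      g <- grad[, , o, f]
      r <- conv_apply_pair(plan, pmax(g, 0), pmax(-g, 0),
                           which = paste0("o", o, c(".pos", ".neg")))
      rpos <- w$pos[o] * r[[1]]$r1   # positive part, positive lobe
      rneg <- w$neg[o] * r[[2]]$r2   # negative part, mirrored lobe
      vals[, , o, f] <- drive_gain *
        (pmax(rpos, rneg) - opponent * pmin(rpos, rneg))
    }
  }
  feature_stack(vals, thetas, attr(grad, "omegas"))
}

#' Sum integrated channels into the raw depth activity field
#'
#' @param per_channel nonnegative `feature_stack` (module IV output).
#' @return numeric matrix; higher values mean farther from the viewer.
#' @export
depth_combine <- function(per_channel) {
  stopifnot(inherits(per_channel, "feature_stack"))
  fs_sum_all(per_channel)
}

#' Normalise a depth-like field to relative units
#'
#' Divides by the maximum (idempotent); with `invert = TRUE` the values
#' are first subtracted from their maximum, turning a
#' "higher-is-farther" activity field (or a camera-distance map) into a
#' relative nearness map on `[0, 1]` with 1 nearest.
#'
#' @param x numeric vector/matrix (NAs ignored and preserved).
#' @param invert subtract from the maximum first.
#' @export
normalize_relative_depth <- function(x, invert = FALSE) {
  m <- max(x, na.rm = TRUE)
  if (!is.finite(m)) stop("normalize_relative_depth: no finite values")
  if (invert) x <- m - x
  mx <- max(x, na.rm = TRUE)
  if (mx <= 0) return(x * 0)
  x / mx
}

#' Finalize a raw depth activity field
#'
#' Masks, smooths, inverts (activity is higher-is-farther) and rescales to
#' `[0, 1]` so that 1 is nearest. Values outside the mask are NA.
#'
#' @param raw numeric matrix of nonnegative integrated activity.
#' @param mask logical/0-1 matrix of the object support (NULL = all).
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @return an object of class `depth_map`: list with `depth` (finalized),
#'   `raw` (masked, smoothed activity) and `mask`.
#' @export
depth_finalize <- function(raw, mask = NULL, smooth_sigma = 3) {
  stopifnot(is.matrix(raw))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(raw), ncol(raw))
  mask <- matrix(as.logical(mask), nrow(raw), ncol(raw))
  if (!any(mask)) stop("depth_finalize: empty mask")
  sm <- gauss_smooth(raw, smooth_sigma)
  mraw <- matrix(NA_real_, nrow(raw), ncol(raw))
  mraw[mask] <- sm[mask]
  mx <- max(mraw, na.rm = TRUE)
  if (mx <= 0) stop("depth_finalize: all-zero raw activity inside the mask")
  # invert (higher activity = farther) and divide by the activity maximum;
  # activity has a natural zero, so values lie in [0, 1] with 1 nearest
  depth <- (mx - mraw) / mx
  structure(list(depth = depth, raw = mraw, mask = mask),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %dx%d, %d masked px, finalized range [%.3f, %.3f]\n",
              nrow(x$depth), ncol(x$depth), sum(x$mask),
              min(x$depth, na.rm = TRUE), max(x$depth, na.rm = TRUE)))
  invisible(x)
}
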