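# Local surface orientation from the distribution of grouped orientation
# responses. The orientation domain is axial (theta == theta + pi), so
# angles are doubled before vector summation: the activity-weighted
# resultant of exp(2i * theta_o) encodes the axis of anisotropy (its
# argument, halved) and a slant-proportional magnitude (its modulus).

#' Activity-weighted orientation resultant
#'
#' `R = sum_o d_o exp(2i theta_o) / sum_o d_o` over the orientation bins.
#' Doubling the angles makes antipodal orientations reinforce rather than
#' cancel, as required for an axial quantity.
#'
#' @param d nonnegative numeric vector of per-orientation activity (summed
#'   over frequency bands).
#' @param thetas orientation bin centers in radians; defaults to a uniform
#'   grid on `[0, pi)`.
#' @return a complex scalar; `NA_complex_` (flagged isotropic/empty) when
#'   all activity is zero.
#' @export
orientation_resultant <- function(d, thetas = NULL) {
  if (is.null(thetas)) thetas <- seq(0, pi, length.out = length(d) + 1L)[seq_along(d)]
  stopifnot(length(d) == length(thetas), all(d >= 0))
  s <- sum(d)
  if (s <= 0) return(NA_complex_)
  sum(d * exp(2i * thetas)) / s
}

#' Slant axis from the resultant
#'
#' Half the two-argument arctangent of the resultant, mapped into
#' `[0, pi)`. This is the axis of anisotropy, i.e. the image orientation
#' along which the texture is least compressed; the slant (tilt) direction
#' is perpendicular to it, ambiguous by pi.
#'
#' @param R complex resultant from [orientation_resultant()].
#' @return angle in radians in `[0, pi)`; NA for an empty resultant.
#' @export
slant_axis <- function(R) {
  if (is.na(R)) return(NA_real_)
  th <- atan2(Im(R), Re(R)) / 2
  th %% pi
}

#' Slant-proportional resultant magnitude
#'
#' `sqrt(Re(R)^2 + Im(R)^2)`, in `[0, 1]` because the resultant is
#' normalised by the total activity: 1 for a single active orientation,
#' 0 for a uniform distribution.
#'
#' @inheritParams slant_axis
#' @export
slant_magnitude <- function(R) {
  if (is.na(R)) return(NA_real_)
  sqrt(Re(R)^2 + Im(R)^2)
}

#' Anisotropy of an orientation distribution
#'
#' `A = 1 - min(d)/max(d)`, in `[0, 1]`: 0 for a flat distribution
#' (frontoparallel-looking texture), 1 when some orientation is silent.
#'
#' @param d nonnegative numeric vector of per-orientation activity.
#' @return scalar in `[0, 1]`; NA (flagged undefined) when `max(d) == 0`.
#' @export
anisotropy <- function(d) {
  stopifnot(all(d >= 0))
  m <- max(d)
  if (m <= 0) return(NA_real_)
  1 - min(d) / m
}

#' Per-pixel surface orientation map
#'
#' Pools the per-orientation (frequency-summed) module II activity with a
#' Gaussian window, then applies the resultant/magnitude/anisotropy
#' estimators at every pixel. Pointwise orientation histograms are noise
#' dominated, hence the patch pooling.
#'
#' @param v2 a `feature_stack` (module II output).
#' @param patch_sigma Gaussian pooling sigma in pixels.
#' @return an object of class `surface_orientation_map`: list of matrices
#'   `slant_axis` (radians, `[0, pi)`), `magnitude` (`[0, 1]`),
#'   `anisotropy` (`[0, 1]`), plus the pooled per-orientation array
#'   `pooled` and the orientation grid `thetas`.
#' @export
orientation_map <- function(v2, patch_sigma = 8) {
  stopifnot(inherits(v2, "feature_stack"))
  per_or <- fs_sum_freq(v2)
  thetas <- attr(per_or, "thetas")
  nth <- dim(per_or)[3]
  pooled <- array(0, dim(per_or))
  for (o in seq_len(nth)) {
    pooled[, , o] <- gauss_smooth(per_or[, , o], patch_sigma)
  }
  tot <- apply(pooled, c(1, 2), sum)
  mx <- apply(pooled, c(1, 2), max)
  mn <- apply(pooled, c(1, 2), min)
  re <- matrix(0, nrow(tot), ncol(tot)); im <- re
  for (o in seq_len(nth)) {
    re <- re + pooled[, , o] * cos(2 * thetas[o])
    im <- im + pooled[, , o] * sin(2 * thetas[o])
  }
  ok <- tot > 0
  mag <- axis_th <- an <- matrix(NA_real_, nrow(tot), ncol(tot))
  mag[ok] <- sqrt(re[ok]^2 + im[ok]^2) / tot[ok]
  axis_th[ok] <- (atan2(im[ok], re[ok]) / 2) %% pi
  okm <- mx > 0
  an[okm] <- 1 - mn[okm] / mx[okm]
  structure(list(slant_axis = axis_th, magnitude = mag, anisotropy = an,
                 pooled = pooled, thetas = thetas),
            class = "surface_orientation_map")
}

#' @export
print.surface_orientation_map <- function(x, ...) {
  cat(sprintf("<surface_orientation_map> %dx%d, mean |R| = %.3f, mean A = %.3f\n",
              nrow(x$magnitude), ncol(x$magnitude),
              mean(x$magnitude, na.rm = TRUE),
              mean(x$anisotropy, na.rm = TRUE)))
  invisible(x)
}

#' Export per-patch orientation estimates as CSV
#'
#' Samples the orientation map on a regular grid and writes
#' `(row, col, slant_axis, magnitude, anisotropy)` rows.
#'
#' @param om a `surface_orientation_map`.
#' @param path output CSV path.
#' @param step grid step in pixels.
#' @export
export_orientation_csv <- function(om, path, step = 10L) {
  rows <- seq(1L, nrow(om$magnitude), by = step)
  cols <- seq(1L, ncol(om$magnitude), by = step)
  grid <- expand.grid(row = rows, col = cols)
  grid$slant_axis <- om$slant_axis[as.matrix(grid[, c("row", "col")])]
  grid$magnitude <- om$magnitude[as.matrix(grid[, c("row", "col")])]
  grid$anisotropy <- om$anisotropy[as.matrix(grid[, c("row", "col")])]
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}
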