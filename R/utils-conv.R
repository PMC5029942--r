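# Spatial filtering backbone: FFT cross-correlation with reflect padding.
#
# All filter "responses" in the package are cross-correlations,
#   r[i] = sum_o w[o] * x[i + o],
# with o running over kernel offsets from the kernel center. Output has the
# size of the input ("same"); borders are handled by mirror reflection so
# that kernel energy never leaks to zero outside the image (a hard zero
# border would create spurious texture-energy gradients).

#' @keywords internal
next_fft_size <- function(n) {
  # smallest highly composite (2,3,5-smooth) size >= n
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' @keywords internal
pad_reflect <- function(x, h) {
  if (h == 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (h >= nr || h >= nc) stop("reflect padding wider than the image")
  ri <- c(rev(seq_len(h) + 1L), seq_len(nr), nr - seq_len(h))
  ci <- c(rev(seq_len(h) + 1L), seq_len(nc), nc - seq_len(h))
  x[ri, ci, drop = FALSE]
}

# Embed a (2h+1)^2 kernel into a P x P grid with its center wrapped to
# (1,1), so circular correlation realises offset semantics directly.
#' @keywords internal
embed_kernel <- function(k, P) {
  h <- (nrow(k) - 1L) %/% 2L
  if (2L * h + 1L != nrow(k) || nrow(k) != ncol(k)) {
    stop("kernels must be square with odd side length")
  }
  out <- matrix(0, P, P)
  idx <- function(o) ((o %% P) + P) %% P + 1L
  out[idx(-h:h), idx(-h:h)] <- k
  out
}

#' Precompute a correlation plan for a set of kernels
#'
#' Builds the padded FFT workspace shared by all kernels in `kernels` for
#' inputs of size `dim_in`. The plan caches the conjugate kernel spectra so
#' that repeated filtering of different inputs (e.g. across feedback cycles)
#' costs one forward FFT per input plus one inverse FFT per kernel.
#'
#' @param dim_in integer vector `c(nrow, ncol)` of the input maps.
#' @param kernels named list of square, odd-sided numeric matrices.
#' @return an object of class `conv_plan`.
#' @keywords internal
conv_plan <- function(dim_in, kernels) {
  stopifnot(length(dim_in) == 2L, length(kernels) >= 1L)
  hs <- vapply(kernels, function(k) (nrow(k) - 1L) %/% 2L, integer(1))
  hmax <- max(hs)
  hmax <- min(hmax, min(dim_in) - 1L)  # reflection cannot exceed image size
  M <- max(dim_in) + 2L * hmax
  P <- next_fft_size(M)
  kfft <- lapply(kernels, function(k) {
    h <- (nrow(k) - 1L) %/% 2L
    if (2L * h + 1L > P) stop("kernel larger than FFT plan size")
    Conj(stats::fft(embed_kernel(k, P)))
  })
  structure(list(dim_in = as.integer(dim_in), h = as.integer(hmax),
                 P = as.integer(P), kfft = kfft),
            class = "conv_plan")
}

#' Apply plan kernels to one input map
#'
#' @param plan a `conv_plan`.
#' @param x numeric matrix matching the plan's input size.
#' @param which character or integer selection of kernels (default: all).
#' @return list of response matrices, same size as `x`.
#' @keywords internal
conv_apply <- function(plan, x, which = NULL) {
  stopifnot(inherits(plan, "conv_plan"),
            nrow(x) == plan$dim_in[1], ncol(x) == plan$dim_in[2])
  if (is.null(which)) which <- seq_along(plan$kfft)
  h <- plan$h; P <- plan$P
  xp <- matrix(0, P, P)
  xpad <- pad_reflect(x, h)
  xp[seq_len(nrow(xpad)), seq_len(ncol(xpad))] <- xpad
  X <- stats::fft(xp)
  rows <- h + seq_len(nrow(x)); cols <- h + seq_len(ncol(x))
  out <- vector("list", length(which))
  for (i in seq_along(which)) {
    y <- Re(stats::fft(X * plan$kfft[[which[i]]], inverse = TRUE)) / (P * P)
    out[[i]] <- y[rows, cols]
  }
  names(out) <- if (is.character(which)) which else names(plan$kfft)[which]
  out
}

#' Single-shot "same" cross-correlation with reflect padding
#' @keywords internal
conv_same <- function(x, k) {
  conv_apply(conv_plan(dim(x), list(k = k)), x)[[1]]
}

# ---- Gaussian building blocks -------------------------------------------

# Rotated coordinate grids for a square kernel of halfwidth h.  Column
# offsets play the x role, row offsets the y role; an angle theta has
# direction (cos theta, sin theta) in (col, row) steps, i.e. angles are
# measured from the +x (column) axis toward increasing row index.  The
# along-axis coordinate is u, the across-axis coordinate v; the direction
# of increasing v is theta + pi/2.
#' @keywords internal
rot_grid <- function(h, theta) {
  o <- -h:h
  X <- matrix(o, 2 * h + 1, 2 * h + 1, byrow = TRUE)  # column offsets
  Y <- matrix(o, 2 * h + 1, 2 * h + 1)                # row offsets
  list(u = X * cos(theta) + Y * sin(theta),
       v = -X * sin(theta) + Y * cos(theta))
}

# Unnormalised anisotropic Gaussian on rotated coordinates, center
# displaced to (u0, v0) in the rotated frame.
#' @keywords internal
aniso_gauss <- function(h, theta, sigma_u, sigma_v, u0 = 0, v0 = 0) {
  g <- rot_grid(h, theta)
  exp(-((g$u - u0)^2 / (2 * sigma_u^2) + (g$v - v0)^2 / (2 * sigma_v^2)))
}

#' Isotropic Gaussian kernel, unit sum
#' @keywords internal
gauss_kernel <- function(sigma, h = NULL) {
  if (is.null(h)) h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- aniso_gauss(h, 0, sigma, sigma)
  k / sum(k)
}

#' Gaussian smoothing of a matrix (reflect borders, separable)
#' @keywords internal
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  h <- min(h, nrow(x) - 1L, ncol(x) - 1L)  # tiny inputs: shrink support
  if (h < 1L) return(x)
  g <- exp(-(-h:h)^2 / (2 * sigma^2)); g <- g / sum(g)
  xp <- pad_reflect(x, h)
  y <- stats::filter(xp, g, sides = 2)               # along rows (columns of x)
  y <- t(stats::filter(t(y), g, sides = 2))          # along columns
  matrix(y[h + seq_len(nrow(x)), h + seq_len(ncol(x))], nrow(x), ncol(x))
}

#' Correlate two real inputs against plan kernels in one FFT pass
#'
#' Packs `x1 + 1i * x2` into a single forward transform; because the plan
#' kernels are real, the real/imaginary parts of each inverse transform are
#' the responses of `x1` and `x2` respectively.
#'
#' @return list of lists `list(r1, r2)` per selected kernel.
#' @keywords internal
conv_apply_pair <- function(plan, x1, x2, which = NULL) {
  stopifnot(inherits(plan, "conv_plan"))
  if (is.null(which)) which <- seq_along(plan$kfft)
  h <- plan$h; P <- plan$P
  xp <- matrix(0 + 0i, P, P)
  xpad <- pad_reflect(x1, h) + 1i * pad_reflect(x2, h)
  xp[seq_len(nrow(xpad)), seq_len(ncol(xpad))] <- xpad
  X <- stats::fft(xp)
  rows <- h + seq_len(nrow(x1)); cols <- h + seq_len(ncol(x1))
  out <- vector("list", length(which))
  for (i in seq_along(which)) {
    y <- stats::fft(X * plan$kfft[[which[i]]], inverse = TRUE) / (P * P)
    out[[i]] <- list(r1 = Re(y)[rows, cols], r2 = Im(y)[rows, cols])
  }
  names(out) <- if (is.character(which)) which else names(plan$kfft)[which]
  out
}

#' @keywords internal
odd_support <- function(extent) {
  # smallest odd integer side covering +/- extent
  2L * as.integer(ceiling(extent)) + 1L
}
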