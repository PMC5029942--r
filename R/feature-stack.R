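# FeatureStack: the common currency between modules. A 4D array of
# responses indexed (row, col, orientation, frequency) with the
# orientation/frequency grids attached as attributes. Post-rectification
# stacks are nonnegative; signed stacks (pre-rectification gradients) use
# the same layout.

#' Create a feature stack
#'
#' @param values 4D numeric array `(rows, cols, n_orientations,
#'   n_frequencies)`, or NULL to allocate zeros.
#' @param thetas,omegas orientation (radians) and frequency (cycles/pixel)
#'   grids.
#' @param dim_im image size `c(rows, cols)` (needed when `values` is NULL).
#' @param signed if FALSE (default), negative values are rejected.
#' @return an object of class `feature_stack` (a 4D array).
#' @export
feature_stack <- function(values = NULL, thetas, omegas, dim_im = NULL,
                          signed = FALSE) {
  if (is.null(values)) {
    stopifnot(!is.null(dim_im))
    values <- array(0, c(dim_im, length(thetas), length(omegas)))
  }
  stopifnot(length(dim(values)) == 4L,
            dim(values)[3] == length(thetas),
            dim(values)[4] == length(omegas))
  if (!all(is.finite(values))) stop("feature stack holds non-finite values")
  if (!signed && min(values) < 0) stop("unsigned feature stack has negative values")
  structure(values, thetas = thetas, omegas = omegas,
            signed = signed, class = "feature_stack")
}

#' @keywords internal
fs_like <- function(values, template, signed = FALSE) {
  feature_stack(values, attr(template, "thetas"), attr(template, "omegas"),
                signed = signed)
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<feature_stack> %dx%d pixels, %d orientations x %d bands, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], d[4], min(x), max(x)))
  invisible(x)
}

#' @keywords internal
fs_grids_match <- function(a, b) {
  isTRUE(all.equal(attr(a, "thetas"), attr(b, "thetas"))) &&
    isTRUE(all.equal(attr(a, "omegas"), attr(b, "omegas"))) &&
    all(dim(a)[1:2] == dim(b)[1:2])
}

#' Per-orientation sum over frequency bands
#'
#' Collapses a stack to one map per orientation channel (the summed
#' activity distribution the slant/tilt estimator works on).
#'
#' @param x a `feature_stack`.
#' @return 3D array `(rows, cols, n_orientations)` with `thetas` attribute.
#' @export
fs_sum_freq <- function(x) {
  d <- dim(x)
  out <- array(0, d[1:3])
  for (f in seq_len(d[4])) out <- out + x[, , , f, drop = FALSE][, , , 1]
  attr(out, "thetas") <- attr(x, "thetas")
  out
}

#' Total activity map (sum over all feature channels)
#' @param x a `feature_stack`.
#' @return numeric matrix.
#' @export
fs_sum_all <- function(x) {
  d <- dim(x)
  apply(array(x, c(d[1] * d[2], d[3] * d[4])), 1, sum) |>
    matrix(d[1], d[2])
}

#' Per-location maximum over all feature channels
#' @param x a `feature_stack`.
#' @return numeric matrix.
#' @export
fs_max_feat <- function(x) {
  d <- dim(x)
  apply(array(x, c(d[1] * d[2], d[3] * d[4])), 1, max) |>
    matrix(d[1], d[2])
}

#' Summaries of a grouped (module II) stack
#'
#' @param v2 a `feature_stack`.
#' @return list with `per_orientation` (sum over frequency, per
#'   orientation), `total` (sum over all channels) and `per_band` (the
#'   stack unchanged).
#' @export
summarize_stack <- function(v2) {
  list(per_orientation = fs_sum_freq(v2),
       total = fs_sum_all(v2),
       per_band = v2)
}
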