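# Quantitative comparison of inferred depth against ground truth:
# the relative error E = sum |o - m| / sum o over the masked region, and
# profile extraction/comparison utilities.

#' Relative depth error
#'
#' `E = sum_i |o_i - m_i| / sum_i o_i` over the masked pixels, where `o`
#' is the ground truth and `m` the model result, both on the common
#' relative `[0, 1]` scale. Reported as a percentage by default (e.g.
#' `7.66` for 7.66%).
#'
#' @param truth,model numeric matrices (or vectors) of equal shape.
#' @param mask optional logical matrix restricting the comparison; NAs in
#'   either input are dropped as well.
#' @param percent return a percentage (default) rather than a fraction.
#' @return nonnegative scalar.
#' @export
relative_error <- function(truth, model, mask = NULL, percent = TRUE) {
  if (!all(dim(truth) == dim(model))) {
    stop("relative_error: truth and model shapes differ")
  }
  keep <- !(is.na(truth) | is.na(model))
  if (!is.null(mask)) keep <- keep & as.logical(mask)
  o <- truth[keep]; m <- model[keep]
  so <- sum(o)
  if (!length(o) || so <= 0) stop("relative_error: ground truth sums to zero")
  e <- sum(abs(o - m)) / so
  if (percent) 100 * e else e
}

#' Extract a row or column profile
#'
#' @param map numeric matrix.
#' @param axis `"row"` (the profile runs along a row) or `"col"`.
#' @param index row/column index; defaults to the middle line.
#' @param mask optional logical matrix; profile values outside the mask
#'   are NA.
#' @return numeric vector.
#' @export
extract_profile <- function(map, axis = c("row", "col"), index = NULL,
                            mask = NULL) {
  axis <- match.arg(axis)
  if (is.null(index)) {
    index <- if (axis == "row") (nrow(map) + 1L) %/% 2L else (ncol(map) + 1L) %/% 2L
  }
  prof <- if (axis == "row") map[index, ] else map[, index]
  if (!is.null(mask)) {
    m <- if (axis == "row") mask[index, ] else mask[, index]
    prof[!as.logical(m)] <- NA_real_
  }
  prof
}

#' Compare a model profile with its ground truth
#'
#' Profiles are first normalised to a maximum of one (relative depth
#' carries no absolute scale, so the comparison is between profile
#' shapes); set `normalize = FALSE` to compare raw values.
#'
#' @param model,truth numeric vectors of equal length (NAs dropped
#'   pairwise).
#' @param normalize divide each profile by its own maximum first.
#' @return list with `spearman` (rank correlation), `mean_signed_error`
#'   (`mean(model - truth)`; negative means the model underestimates) and
#'   `relative_error` (the E statistic restricted to the profile, in
#'   percent).
#' @export
compare_profiles <- function(model, truth, normalize = TRUE) {
  stopifnot(length(model) == length(truth))
  keep <- !(is.na(model) | is.na(truth))
  m <- model[keep]; o <- truth[keep]
  if (length(m) < 3L) stop("compare_profiles: fewer than 3 shared samples")
  if (normalize) {
    if (max(m) > 0) m <- m / max(m)
    if (max(o) > 0) o <- o / max(o)
  }
  list(spearman = stats::cor(m, o, method = "spearman"),
       mean_signed_error = mean(m - o),
       relative_error = relative_error(o, m))
}
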