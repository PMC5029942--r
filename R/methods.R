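# S3 methods for the fitted model object.

#' @export
print.texdepth <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Texture-based depth inference (%dx%d px, %d orientations x %d bands, %d cycle(s), feedback %s)\n",
              d[1], d[2], x$config$n_orientations, x$config$n_frequencies,
              x$config$n_cycles, if (x$config$feedback) "on" else "off"))
  cat(sprintf("  depth: finalized range [%.3f, %.3f] over %d masked px (1 = nearest)\n",
              min(x$depth$depth, na.rm = TRUE),
              max(x$depth$depth, na.rm = TRUE), sum(x$depth$mask)))
  cat(sprintf("  sketch: max activity %.4f; IT integration reach %d px\n",
              max(x$sketch), as.integer(x$it_extent)))
  if (!is.null(x$truth)) {
    m <- normalize_relative_depth(x$depth$depth)   # shape comparison
    cat(sprintf("  relative error vs ground truth: %.2f%%\n",
                relative_error(x$truth, m, x$depth$mask)))
  }
  invisible(x)
}

#' Summarize a fitted depth inference
#'
#' @param object a `texdepth` fit.
#' @param ... unused.
#' @return an object of class `summary.texdepth` with per-module activity
#'   ranges, depth statistics, orientation-map statistics, convergence
#'   deltas and (when ground truth is attached) the relative error and
#'   mid-profile comparison.
#' @export
summary.texdepth <- function(object, ...) {
  stacks <- object$stacks
  act <- t(vapply(stacks, function(s) c(min = min(s), mean = mean(s),
                                        max = max(s)), numeric(3)))
  dstats <- c(p5 = unname(stats::quantile(object$depth$depth, 0.05, na.rm = TRUE)),
              p50 = unname(stats::quantile(object$depth$depth, 0.5, na.rm = TRUE)),
              p95 = unname(stats::quantile(object$depth$depth, 0.95, na.rm = TRUE)))
  out <- list(activity = act, depth_quantiles = dstats,
              cycle_delta = object$diagnostics$cycle_delta,
              mean_anisotropy = mean(object$orientation$anisotropy, na.rm = TRUE),
              mean_magnitude = mean(object$orientation$magnitude, na.rm = TRUE),
              config = object$config)
  if (!is.null(object$truth)) {
    out$relative_error <- relative_error(
      object$truth, normalize_relative_depth(object$depth$depth),
      object$depth$mask)
    out$mid_profile <- compare_profiles(
      extract_profile(object$depth$depth, "col", mask = object$depth$mask),
      extract_profile(object$truth, "col", mask = object$depth$mask))
  }
  class(out) <- "summary.texdepth"
  out
}

#' @export
print.summary.texdepth <- function(x, ...) {
  cat("Per-module activity (min/mean/max):\n")
  print(round(x$activity, 4))
  cat("Finalized depth quantiles (1 = nearest):\n")
  print(round(x$depth_quantiles, 3))
  cat(sprintf("Mean anisotropy %.3f, mean |R| %.3f\n",
              x$mean_anisotropy, x$mean_magnitude))
  if (length(x$cycle_delta) > 1) {
    cat("Max-abs change per feedback cycle:",
        paste(sprintf("%.4g", x$cycle_delta[-1]), collapse = ", "), "\n")
  }
  if (!is.null(x$relative_error)) {
    cat(sprintf("Relative error vs ground truth: %.2f%%; mid-column profile Spearman %.3f\n",
                x$relative_error, x$mid_profile$spearman))
  }
  invisible(x)
}

#' Extract the finalized depth map
#'
#' @param object a `texdepth` fit.
#' @param ... unused.
#' @return numeric matrix (`[0, 1]`, 1 = nearest, NA outside the mask).
#' @export
fitted.texdepth <- function(object, ...) object$depth$depth

#' Predict depth for the fitted image or a new one
#'
#' With `newdata` (a matrix, file path or `rendered_scene`) the model is
#' re-run under the fit's configuration; without it the fitted depth map
#' is returned.
#'
#' @param object a `texdepth` fit.
#' @param newdata optional new image.
#' @param mask optional mask for `newdata`.
#' @param ... unused.
#' @return numeric matrix.
#' @export
predict.texdepth <- function(object, newdata = NULL, mask = NULL, ...) {
  if (is.null(newdata)) return(object$depth$depth)
  refit <- texdepth(newdata, mask = mask, config = object$config)
  refit$depth$depth
}

#' Cascade parameters of a fit
#'
#' @param object a `texdepth` fit.
#' @param ... unused.
#' @return matrix of per-module cascade constants.
#' @export
coef.texdepth <- function(object, ...) {
  cfg <- object$config
  ps <- list(v1 = cfg$params_v1, v2 = cfg$params_v2,
             v3 = cfg$params_v3, v4 = cfg$params_v4)
  t(vapply(ps, function(p) unlist(p[c("beta", "xi", "eta", "alpha", "gamma",
                                      "delta", "eps", "lambda_fb",
                                      "pool_sigma")]), numeric(9)))
}

#' Depth residuals against ground truth
#'
#' @param object a `texdepth` fit with a `truth` component (e.g. fitted on
#'   a `rendered_scene`).
#' @param ... unused.
#' @return matrix of `model - truth` inside the mask (NA elsewhere).
#' @export
residuals.texdepth <- function(object, ...) {
  if (is.null(object$truth)) {
    stop("no ground truth attached to this fit (fit on a rendered_scene ",
         "or pass truth = to texdepth())")
  }
  r <- object$depth$depth - object$truth
  r[!object$depth$mask] <- NA_real_
  r
}

#' Plot a fitted depth inference
#'
#' Draws the input image, the finalized depth map, the sketch and the
#' anisotropy map in a 2x2 panel (base graphics).
#'
#' @param x a `texdepth` fit.
#' @param ... unused.
#' @export
plot.texdepth <- function(x, ...) {
  show <- function(m, main) {
    m[is.na(m)] <- 0
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256, 0, 1),
                    axes = FALSE, main = main, useRaster = TRUE)
  }
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show(x$image, "input")
  show(x$depth$depth, "relative depth (1 = near)")
  show(x$sketch, "2D sketch")
  show(x$orientation$anisotropy, "anisotropy")
  invisible(x)
}
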