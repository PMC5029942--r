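# The top-level estimator: orchestrates modules I -> II -> {III, IV} with
# synchronous feedback cycles and returns a classed fit object.

#' @keywords internal
build_banks <- function(dim_im, cfg, mask = NULL) {
  spec <- filter_bank_spec(cfg$n_orientations, cfg$n_frequencies,
                           cfg$freq_range[1], cfg$freq_range[2],
                           aspect_ratio = cfg$gabor_aspect)
  bip_spec <- filter_bank_spec(cfg$n_orientations, cfg$n_frequencies,
                               cfg$freq_range[1], cfg$freq_range[2],
                               aspect_ratio = cfg$bipole_aspect,
                               lobe_separation = cfg$bipole_separation)
  sk_spec <- if (cfg$sketch_input == "per_channel") spec else
    filter_bank_spec(cfg$n_orientations, 1L,
                     sqrt(prod(cfg$freq_range)), cfg$freq_range[2])
  it_extent <- cfg$it_extent
  if (is.null(it_extent)) {
    diam <- if (is.null(mask)) max(dim_im) else {
      rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
      max(diff(rr), diff(cc)) + 1L
    }
    it_extent <- max(16, round(diam / 3))
  }
  it_spec <- filter_bank_spec(cfg$n_orientations, 1L,
                              cfg$freq_range[1], cfg$freq_range[2],
                              sigmoid_sharpness = cfg$it_sharpness)
  list(
    gabor = make_gabor_bank(spec, band_gain = cfg$band_gain),
    bipole = make_bipole_lobes(bip_spec, length_factor = cfg$bipole_length),
    sd = make_second_derivative_bank(sk_spec, elongation = cfg$sd_elongation),
    dog = make_dog_kernel(cfg$dog_sigmas[1], cfg$dog_sigmas[2]),
    fd = make_first_derivative_bank(spec, elongation = cfg$fd_elongation,
                                    sigma_scale = cfg$fd_sigma_scale),
    it = make_it_integration_bank(it_spec, extent = it_extent,
                                  lateral_factor = cfg$it_lateral),
    it_extent = it_extent,
    spec = spec, sk_spec = sk_spec
  )
}

#' @keywords internal
build_plans <- function(dim_im, banks) {
  it_kers <- list()
  for (o in seq_len(banks$it$spec$n_orientations)) {
    it_kers[[paste0("o", o, ".pos")]] <- banks$it$kernels[[o]][[1]]$pos
    it_kers[[paste0("o", o, ".neg")]] <- abs(banks$it$kernels[[o]][[1]]$neg)
  }
  list(gabor = conv_plan(dim_im, bank_flat_kernels(banks$gabor)),
       bipole = conv_plan(dim_im, bank_flat_kernels(banks$bipole)),
       sd = conv_plan(dim_im, bank_flat_kernels(banks$sd)),
       fd = conv_plan(dim_im, bank_flat_kernels(banks$fd)),
       it = conv_plan(dim_im, it_kers))
}

#' @keywords internal
expand_freq <- function(stack, omegas) {
  # replicate a single-band stack across a target frequency grid (feedback
  # resampling to the receiving module's channels)
  d <- dim(stack)
  if (d[4] == length(omegas)) return(stack)
  stopifnot(d[4] == 1L)
  vals <- array(0, c(d[1:3], length(omegas)))
  for (f in seq_along(omegas)) vals[, , , f] <- stack[, , , 1]
  feature_stack(vals, attr(stack, "thetas"), omegas)
}

#' @keywords internal
combined_feedback <- function(sources, gains, p, r_own) {
  net <- NULL
  for (nm in names(sources)) {
    src <- sources[[nm]]
    if (is.null(src)) next
    g <- gains[[nm]]
    if (is.null(g) || g <= 0) next
    src <- expand_freq(src, attr(r_own, "omegas"))
    term <- g * unclass(feedback_signal(src, p))
    net <- if (is.null(net)) term else net + term
  }
  if (is.null(net)) return(NULL)
  fs_like(net, r_own)
}

#' @keywords internal
stage_update <- function(drive, p, r_prev = NULL, net = NULL) {
  r0 <- if (is.null(r_prev)) rect(drive) else r_prev
  if (is.null(net)) net <- fs_like(array(0, dim(drive)), drive)
  q <- inhibitory_pool(r0, p)
  steady_state(rect(drive), net, q, p)
}

#' Infer relative depth, sketch and surface orientation from texture
#'
#' Fits the hierarchical cascade model to a single grayscale image: V1
#' quadrature texture-energy decomposition, V2 bipole grouping with
#' divisive normalization, V4 orientation-contrast sketch extraction, and
#' V4/IT signed gradient computation with directed integration into a
#' globally ordered relative depth field. Descending gated feedback (depth
#' and sketch pathways back to the grouping stage and down to V1) runs for
#' `config$n_cycles` synchronous passes.
#'
#' @param image numeric matrix in `[0, 1]`, a file path readable by
#'   [read_gray()], or a `rendered_scene` (whose image, mask and
#'   ground-truth depth are used).
#' @param mask optional logical/0-1 matrix of the object support.
#' @param config a [texdepth_config()].
#' @param truth optional ground-truth relative depth (matrix, 1 = nearest)
#'   kept for residual/summary methods.
#' @return an object of class `texdepth`: list with components
#'   `depth` (a `depth_map`), `sketch` (matrix), `orientation`
#'   (a `surface_orientation_map`), `stacks` (final per-module feature
#'   stacks), `diagnostics` (per-cycle summed maps and convergence
#'   deltas), `config`, `image`, `mask`, `truth`.
#' @seealso [texdepth_config()], [render_scene()], [relative_error()]
#' @export
texdepth <- function(image, mask = NULL, config = texdepth_config(),
                     truth = NULL) {
  if (inherits(image, "rendered_scene")) {
    scene <- image
    image <- scene$image
    if (is.null(mask)) mask <- scene$mask
    if (is.null(truth)) truth <- scene$depth
  }
  if (is.character(image)) image <- read_gray(image)
  if (!is.matrix(image) || !all(is.finite(image))) {
    stop("image must be a finite numeric matrix (module I input)")
  }
  cfg <- config
  dim_im <- dim(image)
  if (!is.null(mask)) mask <- matrix(as.logical(mask), dim_im[1], dim_im[2])
  banks <- build_banks(dim_im, cfg, mask)
  plans <- build_plans(dim_im, banks)

  # constant across cycles: the V1 drive
  drive1 <- texture_energy(image, banks$gabor, plan = plans$gabor)
  drive1 <- fs_like(cfg$v1_transfer(unclass(drive1)), drive1)

  n_pass <- cfg$n_cycles  # same sweep count with or without feedback
  rho <- cfg$relax        # damped synchronous updates stabilise the loop
  blend <- function(new, old) {
    if (is.null(old)) new else fs_like(rho * unclass(new) + (1 - rho) * unclass(old), new)
  }
  r1 <- r2 <- r3 <- r4 <- NULL
  diagnostics <- list(cycle_delta = numeric(0), summed = list())
  sk_freq_summed <- cfg$sketch_input == "freq_summed"

  for (cyc in seq_len(n_pass)) {
    use_fb <- cfg$feedback && cyc > 1L
    net1 <- if (use_fb) combined_feedback(list(I_from_II = r2, I_from_IV = r4),
                                          cfg$fb_gains, cfg$params_v1, r1)
    r1_new <- blend(stage_update(drive1, cfg$params_v1, r_prev = r1, net = net1), r1)

    drive2 <- bipole_combine(r1_new, banks$bipole, cfg$transfer_s,
                             plan = plans$bipole)
    net2 <- if (use_fb) combined_feedback(list(II_from_III = r3, II_from_IV = r4),
                                          cfg$fb_gains, cfg$params_v2, r2)
    r2_new <- blend(stage_update(drive2, cfg$params_v2, r_prev = r2, net = net2), r2)

    sk_in <- if (sk_freq_summed) {
      po <- fs_sum_freq(r2_new)
      feature_stack(array(po, c(dim(po), 1L)), attr(r2_new, "thetas"),
                    banks$sk_spec$omegas)
    } else r2_new
    drive3 <- dog_enhance(rect(edge_line_responses(sk_in, banks$sd,
                                                   plan = plans$sd)),
                          banks$dog)
    r3_new <- blend(stage_update(drive3, cfg$params_v3, r_prev = r3), r3)

    total2 <- fs_sum_all(r2_new)
    grad <- energy_gradient(total2, banks$fd, plan = plans$fd,
                            taper = cfg$border_taper, coverage = FALSE,
                            gain_sigma = cfg$fd_gain_sigma)
    drive4 <- directed_integration(grad, banks$it,
                                   direction = cfg$contour_direction,
                                   low_weight = cfg$direction_low_weight,
                                   opponent = cfg$it_opponent,
                                   drive_gain = cfg$it_drive_gain,
                                   plan = plans$it)
    r4_new <- blend(stage_update(drive4, cfg$params_v4, r_prev = r4), r4)

    delta <- if (is.null(r4)) Inf else
      max(max(abs(r1_new - r1)), max(abs(r2_new - r2)),
          max(abs(r3_new - r3)), max(abs(r4_new - r4)))
    diagnostics$cycle_delta <- c(diagnostics$cycle_delta, delta)
    r1 <- r1_new; r2 <- r2_new; r3 <- r3_new; r4 <- r4_new
    if (cyc == 1L || cyc == n_pass) {
      diagnostics$summed[[if (cyc == 1L) "feedforward" else "final"]] <-
        list(I = fs_sum_all(r1), II = fs_sum_all(r2),
             III = fs_sum_all(r3), IV = fs_sum_all(r4))
    }
  }
  if (n_pass == 1L) diagnostics$summed$final <- diagnostics$summed$feedforward

  raw <- depth_combine(r4)
  msk <- if (is.null(mask)) matrix(TRUE, dim_im[1], dim_im[2]) else mask
  depth <- if (max(raw[msk]) <= 0) {
    # no texture-energy gradient survived normalization: the percept is a
    # frontoparallel surface (constant relative depth, no relief)
    flat <- matrix(NA_real_, dim_im[1], dim_im[2]); flat[msk] <- 1
    zero <- matrix(NA_real_, dim_im[1], dim_im[2]); zero[msk] <- 0
    structure(list(depth = flat, raw = zero, mask = msk), class = "depth_map")
  } else {
    depth_finalize(raw, mask, smooth_sigma = cfg$smooth_sigma)
  }
  sk <- sketch_map(r3)
  om <- orientation_map(r2, patch_sigma = cfg$patch_sigma)

  structure(list(depth = depth, sketch = sk, orientation = om,
                 stacks = list(v1 = r1, v2 = r2, v3 = r3, v4 = r4),
                 diagnostics = diagnostics,
                 config = cfg, image = image, mask = mask, truth = truth,
                 it_extent = banks$it_extent),
            class = "texdepth")
}

#' Depth inference for contour (planar-cut) textures
#'
#' Contour textures do not by themselves disambiguate the integration
#' direction, so it must be supplied: IT lobes aligned with it keep full
#' weight while the opposite and transverse paths are attenuated, and the
#' integration reach is enlarged to span the object. The direction is
#' never guessed.
#'
#' @inheritParams texdepth
#' @param integration_direction integration direction in radians
#'   (mandatory; e.g. `pi/2` for vertical).
#' @param extent_factor enlargement of the IT reach relative to the
#'   default third of the mask diameter.
#' @return a `texdepth` fit object.
#' @export
contour_mode <- function(image, mask = NULL, integration_direction,
                         config = texdepth_config(), extent_factor = 1.5) {
  if (missing(integration_direction) || is.null(integration_direction)) {
    stop("contour_mode: an integration direction must be supplied; ",
         "the model does not infer it from the image")
  }
  cfg <- config
  cfg$contour_direction <- integration_direction
  if (is.null(cfg$it_extent)) {
    dim_im <- if (inherits(image, "rendered_scene")) dim(image$image) else dim(image)
    msk <- if (!is.null(mask)) mask else if (inherits(image, "rendered_scene")) image$mask
    diam <- if (is.null(msk)) max(dim_im) else {
      rr <- range(which(rowSums(msk) > 0)); cc <- range(which(colSums(msk) > 0))
      max(diff(rr), diff(cc)) + 1L
    }
    cfg$it_extent <- max(16, round(extent_factor * diam / 3))
  } else {
    cfg$it_extent <- cfg$it_extent * extent_factor
  }
  texdepth(image, mask = mask, config = cfg)
}
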