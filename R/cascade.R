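# The generic three-stage steady-state dynamics shared by all model areas:
# stage-specific filtering, modulatory feedback, and subtractive/divisive
# normalization by a pooled inhibitory signal.
#
# For a drive d (the rectified, possibly nonlinear filter output), feedback
# net and inhibitory pool q, the steady-state response is
#
#   r = rect( (beta * d * (1 + net) - xi * q + eta)
#             / (alpha + gamma * d * (1 + net) + q) )
#
# so r saturates at beta/gamma for large drive, is depressed linearly and
# divisively by q, and is multiplicatively (never additively) enhanced by
# feedback. The pool is
#
#   q[i, feat] = delta * ( sum_feat r[i, feat]
#                          + eps * sum_j maxfeat(r[j]) * pool[i - j] )
#
# i.e. full feature-domain competition at the cell's own location plus a
# spatially weighted sum of the feature-maximum at neighbouring locations.
# The feedback signal from a higher module is
#
#   net[i, feat] = rect(lambda_fb - r_own[i, feat]) *
#                  sum_{z in neighbourhood} r_higher[z, feat]
#
# a saturating gate on the sending module's own activity: where the higher
# module already responds at lambda_fb or above, no further enhancement is
# delivered; where it is locally weak but its neighbourhood is active, the
# receiving unit is enhanced. This both interpolates across gaps and
# withholds enhancement from already-dominant structure (e.g. anisotropy
# ridges), which the rising divisive pool then actively suppresses.

#' Cascade stage parameters
#'
#' Constants of the steady-state normalization dynamics. Defaults keep the
#' saturation bound `beta/gamma` at 1 and make zero input map to zero
#' output (`eta = 0`).
#'
#' @param beta excitatory gain (numerator).
#' @param xi subtractive inhibition gain.
#' @param eta tonic baseline input (kept at 0 so that blank input yields
#'   blank output exactly).
#' @param alpha semi-saturation constant (> 0 guarantees a positive
#'   denominator; controls how linearly saturation is approached).
#' @param gamma divisive self-excitation gain (> 0; the response is bounded
#'   by `beta/gamma`).
#' @param delta scaling of the inhibitory pool.
#' @param eps weight of the spatial (neighbourhood) term in the pool
#'   relative to the feature-domain term.
#' @param lambda_fb feedback gate level: units already responding at this
#'   level receive no further feedback enhancement.
#' @param pool_sigma sigma (pixels) of the isotropic Gaussian spatial pool
#'   kernel (unit sum, truncated at 3 sigma).
#' @return an object of class `cascade_params`.
#' @export
cascade_params <- function(beta = 1, xi = 0.5, eta = 0, alpha = 0.25,
                           gamma = 1, delta = 0.04, eps = 1.5,
                           lambda_fb = 0.35, pool_sigma = 4) {
  stopifnot(gamma > 0, alpha >= 0, beta >= 0, xi >= 0, eta >= 0,
            delta >= 0, eps >= 0, lambda_fb >= 0, pool_sigma > 0)
  structure(list(beta = beta, xi = xi, eta = eta, alpha = alpha,
                 gamma = gamma, delta = delta, eps = eps,
                 lambda_fb = lambda_fb, pool_sigma = pool_sigma),
            class = "cascade_params")
}

#' Half-wave rectification
#'
#' @param x numeric array (a signed stack or any numeric).
#' @return `pmax(x, 0)`, preserving attributes of feature stacks.
#' @export
rect <- function(x) {
  if (!all(is.finite(x))) stop("rect: non-finite input")
  y <- pmax(unclass(x), 0)
  if (inherits(x, "feature_stack")) {
    y <- feature_stack(y, attr(x, "thetas"), attr(x, "omegas"))
  }
  y
}

#' Inhibitory pool signal
#'
#' Computes the subtractive/divisive inhibition `q` from a rectified stack:
#' the sum over all feature channels at each location plus `eps` times the
#' Gaussian-weighted spatial sum of the per-location feature maximum (only
#' the maximum across features enters the spatial term).
#'
#' @param r a nonnegative `feature_stack`.
#' @param p a [cascade_params()].
#' @return a `feature_stack` of pool values (identical across the feature
#'   dimension at each location).
#' @export
inhibitory_pool <- function(r, p) {
  stopifnot(inherits(r, "feature_stack"), inherits(p, "cascade_params"))
  featsum <- fs_sum_all(r)
  spatial <- gauss_smooth(fs_max_feat(r), p$pool_sigma)
  qmap <- p$delta * (featsum + p$eps * spatial)
  d <- dim(r)
  q <- array(qmap, d)  # recycle the map across (theta, omega)
  fs_like(q, r)
}

#' Modulatory feedback signal
#'
#' Eq-style gated feedback: `rect(lambda_fb - r_own) * S`, where `S` is the
#' spatial neighbourhood sum (Gaussian pool support, unweighted by feature)
#' of the matching-feature activity of the sending (higher) module.
#'
#' @param r_higher nonnegative `feature_stack` from the module above,
#'   already resampled to the receiving module's `(theta, omega)` grid.
#' @param p a [cascade_params()] (provides `lambda_fb` and the
#'   neighbourhood scale `pool_sigma`).
#' @param r_own optional override for the activity entering the saturating
#'   gate; by default (NULL) the sending module's own activity is gated,
#'   matching the closed-form feedback definition.
#' @return a nonnegative `feature_stack`.
#' @export
feedback_signal <- function(r_higher, p, r_own = NULL) {
  stopifnot(inherits(r_higher, "feature_stack"), inherits(p, "cascade_params"))
  gate_src <- if (is.null(r_own)) r_higher else r_own
  if (!fs_grids_match(r_higher, gate_src)) {
    stop("feedback grid mismatch between modules")
  }
  d <- dim(r_higher)
  # neighbourhood sum per matching feature channel: unit-sum Gaussian times
  # its support mass ~ unweighted local sum / kernel area; a plain unit-sum
  # Gaussian keeps the magnitude scale-independent.
  nb <- array(0, d)
  for (o in seq_len(d[3])) for (f in seq_len(d[4])) {
    nb[, , o, f] <- gauss_smooth(r_higher[, , o, f], p$pool_sigma)
  }
  net <- pmax(p$lambda_fb - unclass(gate_src), 0) * nb
  fs_like(net, r_higher)
}

#' Steady-state cascade response
#'
#' Elementwise evaluation of the normalization dynamics at steady state
#' (see the formula at the top of this file). Bounded above by
#' `beta/gamma` and below by `-xi` before rectification.
#'
#' @param drive rectified (nonnegative) filter output stack.
#' @param net feedback signal stack (0 for a pure feedforward pass).
#' @param q inhibitory pool stack.
#' @param p a [cascade_params()].
#' @return a nonnegative `feature_stack`.
#' @export
steady_state <- function(drive, net, q, p) {
  stopifnot(inherits(p, "cascade_params"))
  e <- p$beta * unclass(drive) * (1 + unclass(net))
  den <- p$alpha + p$gamma * unclass(drive) * (1 + unclass(net)) + unclass(q)
  if (any(den <= 0)) stop("steady_state: nonpositive denominator (alpha must be > 0)")
  r <- (e - p$xi * unclass(q) + p$eta) / den
  out <- pmax(r, 0)
  if (inherits(drive, "feature_stack")) out <- fs_like(out, drive) else out
}

#' Run one cascade stage
#'
#' Applies the module's filtering rule, then iterates feedback ->
#' inhibitory pool -> steady state for `n_cycles` fixed-point sweeps. With
#' no feedback source the feedback term is identically zero (a pure
#' feedforward pass). The pool on the first sweep is computed from the
#' rectified drive; later sweeps use the previous sweep's output.
#'
#' @param input the stage input (image or `feature_stack`), handed to
#'   `combine`.
#' @param bank the stage's `filter_bank`, handed to `combine`.
#' @param combine `function(input, bank)` returning the nonnegative drive
#'   stack (the stage-specific filtering rule).
#' @param feedback_source either NULL, a `feature_stack` from a higher
#'   module (fixed across sweeps), or a function of the current response
#'   returning such a stack.
#' @param p a [cascade_params()].
#' @param n_cycles number of fixed-point sweeps (>= 1).
#' @param tol optional early stop: sweep-to-sweep max absolute change below
#'   `tol` ends the iteration.
#' @return a nonnegative `feature_stack`.
#' @export
run_stage <- function(input, bank, combine, feedback_source = NULL,
                      p = cascade_params(), n_cycles = 1L, tol = 1e-4) {
  stopifnot(n_cycles >= 1L)
  drive <- combine(input, bank)
  if (!all(is.finite(drive))) stop("run_stage: non-finite drive after filtering")
  r <- rect(drive)
  for (cyc in seq_len(n_cycles)) {
    fb <- if (is.null(feedback_source)) NULL
          else if (is.function(feedback_source)) feedback_source(r)
          else feedback_source
    net <- if (is.null(fb)) fs_like(array(0, dim(r)), r)
           else feedback_signal(fb, p)
    q <- inhibitory_pool(r, p)
    r_new <- steady_state(rect(drive), net, q, p)
    if (!all(is.finite(r_new))) stop("run_stage: non-finite stage output")
    delta <- max(abs(r_new - r))
    r <- r_new
    if (cyc > 1L && delta < tol) break
  }
  r
}
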