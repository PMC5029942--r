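# Shared fixtures and independent oracles. The oracles are deliberately
# naive (nested loops, direct definitions) so they share no code path with
# the implementation they check.

# direct "same"-size cross-correlation with reflect padding, O(N^2 K^2)
brute_xcorr <- function(x, k) {
  h <- (nrow(k) - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  ri <- function(i) { i <- abs(i - 1L) + 1L; i <- ifelse(i > nr, 2L * nr - i, i); i }
  ci <- function(j) { j <- abs(j - 1L) + 1L; j <- ifelse(j > nc, 2L * nc - j, j); j }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (a in -h:h) for (b in -h:h) {
      s <- s + k[a + h + 1L, b + h + 1L] * x[ri(i + a), ci(j + b)]
    }
    out[i, j] <- s
  }
  out
}

# sinusoidal grating with stripes along orientation theta
grating <- function(n, theta, omega, phase = 0, amp = 0.4, offset = 0.5) {
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  Y <- matrix(seq_len(n), n, n)
  offset + amp * sin(2 * pi * omega * (-X * sin(theta) + Y * cos(theta)) + phase)
}

# random nonnegative stack on a small grid
random_stack <- function(seed, nr = 8, nc = 8, nth = 4, nom = 2) {
  set.seed(seed)
  thetas <- seq(0, pi, length.out = nth + 1L)[seq_len(nth)]
  omegas <- exp(seq(log(0.06), log(0.2), length.out = nom))
  feature_stack(array(runif(nr * nc * nth * nom), c(nr, nc, nth, nom)),
                thetas, omegas)
}

# brute-force pool: q[i,feat] = delta * (sum_feat r[i,] + eps * sum_j
# maxfeat(r[j]) * pool[i-j]), pool = truncated unit-sum Gaussian
brute_pool <- function(r, p) {
  d <- dim(r)
  h <- max(1L, as.integer(ceiling(3 * p$pool_sigma)))
  o <- -h:h
  g <- exp(-outer(o^2, o^2, "+") / (2 * p$pool_sigma^2))
  g <- g / sum(g)
  mx <- apply(array(r, c(d[1] * d[2], d[3] * d[4])), 1, max)
  mx <- matrix(mx, d[1], d[2])
  spat <- brute_xcorr(mx, g)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    fsum <- sum(r[i, j, , ])
    for (o1 in seq_len(d[3])) for (f1 in seq_len(d[4])) {
      out[i, j, o1, f1] <- p$delta * (fsum + p$eps * spat[i, j])
    }
  }
  out
}

# brute-force feedback: net = max(lambda - gate, 0) * (Gaussian-pooled
# matching-channel higher activity)
brute_feedback <- function(r_higher, p, r_own = NULL) {
  gate <- if (is.null(r_own)) r_higher else r_own
  d <- dim(r_higher)
  h <- max(1L, as.integer(ceiling(3 * p$pool_sigma)))
  o <- -h:h
  g <- exp(-outer(o^2, o^2, "+") / (2 * p$pool_sigma^2))
  g <- g / sum(g)
  out <- array(0, d)
  for (o1 in seq_len(d[3])) for (f1 in seq_len(d[4])) {
    nb <- brute_xcorr(matrix(r_higher[, , o1, f1], d[1], d[2]), g)
    out[, , o1, f1] <- pmax(p$lambda_fb - gate[, , o1, f1], 0) * nb
  }
  out
}

# scalar steady-state formula
brute_steady <- function(drive, net, q, p) {
  pmax((p$beta * drive * (1 + net) - p$xi * q + p$eta) /
         (p$alpha + p$gamma * drive * (1 + net) + q), 0)
}

# rebuild a stack with a template's grids
fs_like_test <- function(template, values, signed = FALSE) {
  feature_stack(values, attr(template, "thetas"), attr(template, "omegas"),
                signed = signed)
}

# small default scene/config helpers for pipeline-level tests
small_scene <- function(shape = "plane_plus_semisphere", n = 96, seed = 3,
                        texture = "polka", projection = "orthographic",
                        fov = 50, shape_args = list(),
                        texture_args = list(spacing = 8, dot_radius = 2)) {
  render_scene(scene_spec(shape, texture, projection, image_size = n,
                          seed = seed, fov = fov, shape_args = shape_args,
                          texture_args = texture_args))
}

fast_config <- function(..., n_cycles = 2L) {
  texdepth_config(n_orientations = 6L, n_frequencies = 3L,
                  freq_range = c(0.05, 0.25), n_cycles = n_cycles, ...)
}

# strip feature-stack attributes for value-only comparisons
bare <- function(x) array(unclass(x), dim(x))

# small standalone Gaussian blur (independent of the package's smoother)
gauss_smooth_test <- function(x, sigma) {
  h <- ceiling(3 * sigma); o <- -h:h
  g <- exp(-o^2 / (2 * sigma^2)); g <- g / sum(g)
  k <- outer(g, g)
  brute_xcorr(x, k)
}
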