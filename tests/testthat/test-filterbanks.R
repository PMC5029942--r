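# Kernel constructors: zero-sum contracts, symmetry, tuning and the
# orientation/sign conventions, checked against brute-force filtering of
# synthetic inputs.

spec44 <- filter_bank_spec(4, 2, 0.08, 0.2)

test_that("spec validation enforces grid and range contracts", {
  expect_error(filter_bank_spec(1), "n_orientations")
  expect_error(filter_bank_spec(4, 2, 0.2, 0.1), "freq_min")
  sp <- filter_bank_spec(6, 3, 0.05, 0.2)
  expect_equal(length(sp$thetas), 6L)
  expect_equal(sp$thetas[1], 0)
  expect_lt(max(sp$thetas), pi)
  expect_equal(diff(log(sp$omegas)), rep(diff(log(sp$omegas))[1], 2))
})

test_that("gabor kernels are zero-mean quadrature pairs with axial symmetry", {
  gb <- make_gabor_bank(spec44)
  for (o in 1:4) for (f in 1:2) {
    k <- bank_kernel(gb, o, f)
    expect_lt(abs(sum(k$even)), 1e-6)
    expect_lt(abs(sum(k$odd)), 1e-10)
    expect_equal(dim(k$even), dim(k$odd))
    expect_equal(nrow(k$even) %% 2, 1)
  }
  # orientation is axial: theta and theta + pi give the same even kernel
  sp2 <- filter_bank_spec(4, 1, 0.1, 0.2)
  g1 <- make_gabor_bank(sp2)
  sp_pi <- sp2; sp_pi$thetas <- sp2$thetas + pi
  g2 <- make_gabor_bank(sp_pi)
  expect_equal(bank_kernel(g1, 2, 1)$even, bank_kernel(g2, 2, 1)$even,
               tolerance = 1e-12)
  expect_error(make_gabor_bank(spec44, max_support = 2), "3\\*sigma")
})

test_that("quadrature amplitude prefers the matched grating orientation", {
  gb <- make_gabor_bank(filter_bank_spec(2, 1, 0.125, 0.2))
  img <- grating(64, 0, 0.125)
  k <- bank_kernel(gb, 1, 1)       # theta = 0 stripes (horizontal)
  k90 <- bank_kernel(gb, 2, 1)
  amp <- function(kk) {
    e <- brute_xcorr(img, kk$even); o <- brute_xcorr(img, kk$odd)
    mean(sqrt(e^2 + o^2)[20:45, 20:45])
  }
  expect_gt(amp(k) / amp(k90), 5)
})

test_that("bipole lobes are normalized mirror pairs on the orientation axis", {
  bp <- make_bipole_lobes(spec44)
  for (o in 1:4) for (f in 1:2) {
    l <- bank_kernel(bp, o, f)
    expect_equal(sum(l$lobe1), 1, tolerance = 1e-9)
    expect_equal(sum(l$lobe2), 1, tolerance = 1e-9)
    expect_true(min(l$lobe1) >= 0 && min(l$lobe2) >= 0)
    # mirror through the center
    m <- l$lobe1[rev(seq_len(nrow(l$lobe1))), rev(seq_len(ncol(l$lobe1)))]
    expect_equal(m, l$lobe2, tolerance = 1e-9)
  }
  # theta = 0: centers displaced only horizontally
  l <- bank_kernel(bp, 1, 1)
  c1 <- which(l$lobe1 == max(l$lobe1), arr.ind = TRUE)
  c2 <- which(l$lobe2 == max(l$lobe2), arr.ind = TRUE)
  ctr <- (nrow(l$lobe1) + 1) / 2
  expect_equal(unname(c1[1, "row"]), ctr)
  expect_equal(unname(c2[1, "row"]), ctr)
  expect_true(c1[1, "col"] > ctr && c2[1, "col"] < ctr)
  # too-small separation errors
  sp_bad <- filter_bank_spec(4, 2, 0.08, 0.2, lobe_separation = 0.1)
  expect_error(make_bipole_lobes(sp_bad), "overlap")
})

test_that("second-derivative kernels annihilate constants and prefer matched lines", {
  sdb <- make_second_derivative_bank(spec44)
  for (o in 1:4) for (f in 1:2) {
    k <- bank_kernel(sdb, o, f)
    expect_lt(abs(sum(k)), 1e-6)
  }
  # constant image -> zero response
  k <- bank_kernel(sdb, 1, 2)
  expect_lt(max(abs(brute_xcorr(matrix(0.7, 31, 31), k))), 1e-10)
  # a one-pixel line along theta drives the matched orientation harder
  n <- 41
  line_h <- matrix(0, n, n); line_h[21, ] <- 1   # along theta = 0
  k0 <- bank_kernel(sdb, 1, 2); k90 <- bank_kernel(sdb, 3, 2)
  expect_gt(max(abs(brute_xcorr(line_h, k0))),
            max(abs(brute_xcorr(line_h, k90))))
})

test_that("difference-of-Gaussians kernel is an isotropic zero-sum center-surround", {
  dog <- make_dog_kernel(1, 2)
  expect_lt(abs(sum(dog)), 1e-10)
  expect_equal(dog, t(dog), tolerance = 1e-12)               # 90 deg rotation
  expect_equal(dog, dog[rev(seq_len(nrow(dog))), ], tolerance = 1e-12)
  # response to a centered impulse equals the kernel's center weight:
  # (2*pi*sc^2)^-1 - (2*pi*ss^2)^-1 scaled by the truncated normalizers
  h <- (nrow(dog) - 1) / 2
  o <- -h:h
  gc <- exp(-outer(o^2, o^2, "+") / 2); gs <- exp(-outer(o^2, o^2, "+") / 8)
  expect_equal(dog[h + 1, h + 1], 1 / sum(gc) - 1 / sum(gs), tolerance = 1e-12)
  expect_error(make_dog_kernel(2, 1), "sigma_center")
})

test_that("first-derivative kernels are signed antisymmetric pairs", {
  fdb <- make_first_derivative_bank(spec44)
  for (o in 1:4) for (f in 1:2) {
    expect_lt(abs(sum(bank_kernel(fdb, o, f))), 1e-9)
  }
  k <- bank_kernel(fdb, 1, 2)   # theta = 0, gradient direction +y (rows)
  expect_lt(max(abs(brute_xcorr(matrix(1, 31, 31), k))), 1e-9)
  # a top-dark/bottom-bright step yields positive response at the step for
  # the +y polarity, and the response flips with the kernel's polarity
  n <- 41
  step <- matrix(0, n, n); step[21:n, ] <- 1
  r <- brute_xcorr(step, k)
  expect_gt(r[21, 21], 0)
  expect_equal(brute_xcorr(step, -k)[21, 21], -r[21, 21], tolerance = 1e-12)
})

test_that("IT lobes are one-sided, signed, and directionally selective", {
  sp <- filter_bank_spec(4, 1, 0.08, 0.2, sigmoid_sharpness = 1)
  itb <- make_it_integration_bank(sp, extent = 12)
  for (o in 1:4) {
    l <- bank_kernel(itb, o, 1)
    expect_gte(min(l$pos), 0)
    expect_lte(max(l$neg), 0)
    expect_equal(sum(l$pos), 1, tolerance = 1e-9)
    expect_equal(sum(l$neg), -1, tolerance = 1e-9)
  }
  # sigmoid_sharpness -> 0: lobe proportional to the untruncated Gaussian
  sp0 <- filter_bank_spec(4, 1, 0.08, 0.2, sigmoid_sharpness = 0)
  it0 <- make_it_integration_bank(sp0, extent = 12)
  l0 <- bank_kernel(it0, 1, 1)$pos
  h <- (nrow(l0) - 1) / 2; o <- -h:h
  su <- 0.35 * 12; sv <- 0.5 * 12; d <- 6
  U <- matrix(o, 2 * h + 1, 2 * h + 1, byrow = TRUE)
  V <- matrix(o, 2 * h + 1, 2 * h + 1)
  full <- exp(-(U^2 / (2 * su^2))) * exp(-((V + d)^2 / (2 * sv^2)))
  expect_equal(l0, full / sum(full), tolerance = 1e-9)
  # dipole test: +1 then -1 along the integration direction is preferred
  # over the reversed dipole by the signed pair
  # between a rising edge and a falling edge along the integration
  # direction, both one-sided paths are active; for the reversed dipole
  # neither is
  l <- bank_kernel(itb, 1, 1)   # theta = 0, integration direction +y
  n <- 61; x0 <- 28
  dip <- matrix(0, n, n); dip[x0, 31] <- 1; dip[x0 + 6, 31] <- -1
  resp_mid <- function(img) {
    rp <- brute_xcorr(pmax(img, 0), l$pos)
    rn <- brute_xcorr(pmax(-img, 0), abs(l$neg))
    pmax(rp, rn)[x0 + 3, 31]
  }
  expect_gt(resp_mid(dip), 2 * resp_mid(-dip))
})

test_that("banks are covariant with their orientation grid", {
  # rotating a grating by one orientation step shifts the preferred
  # channel by one bin
  sp <- filter_bank_spec(4, 1, 0.125, 0.2)
  gb <- make_gabor_bank(sp)
  pref <- function(theta0) {
    img <- grating(48, theta0, 0.125)
    e <- texture_energy(img, gb)
    which.max(apply(bare(e)[10:39, 10:39, , 1], 3, mean))
  }
  p0 <- pref(sp$thetas[1])
  p1 <- pref(sp$thetas[2])
  expect_equal((p1 - p0) %% 4, 1)
})

test_that("kernel support shrinks as frequency rises", {
  gb <- make_gabor_bank(filter_bank_spec(2, 3, 0.05, 0.2))
  sizes <- vapply(1:3, function(f) nrow(bank_kernel(gb, 1, f)$even), numeric(1))
  expect_true(all(diff(sizes) < 0))
  bp <- make_bipole_lobes(filter_bank_spec(2, 3, 0.05, 0.2))
  bsz <- vapply(1:3, function(f) nrow(bank_kernel(bp, 1, f)$lobe1), numeric(1))
  expect_true(all(diff(bsz) < 0))
})
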