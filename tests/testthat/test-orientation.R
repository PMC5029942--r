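# Slant/tilt estimation from orientation distributions: closed forms and
# end-to-end recovery on gratings.

test_that("resultant closed forms: concentration, uniformity, antipodal cancellation", {
  th <- seq(0, pi, length.out = 9)[1:8]
  d <- rep(0, 8); d[3] <- 1
  R <- orientation_resultant(d, th)
  expect_equal(R, exp(2i * th[3]), tolerance = 1e-12)
  expect_equal(slant_magnitude(R), 1, tolerance = 1e-12)
  # uniform distribution over an even grid cancels (roots of unity)
  expect_equal(abs(orientation_resultant(rep(1, 8), th)), 0, tolerance = 1e-12)
  # theta and theta + pi/2 cancel after angle doubling
  d2 <- rep(0, 8); d2[1] <- 1; d2[5] <- 1   # 0 and pi/2
  expect_equal(abs(orientation_resultant(d2, th)), 0, tolerance = 1e-12)
  # all-zero distribution is flagged
  expect_true(is.na(orientation_resultant(rep(0, 8), th)))
})

test_that("slant axis inverts the angle doubling into [0, pi)", {
  expect_equal(slant_axis(exp(2i * (pi / 3))), pi / 3, tolerance = 1e-12)
  expect_equal(slant_axis(complex(real = -1, imaginary = 0)), pi / 2,
               tolerance = 1e-12)
  expect_equal(slant_axis(exp(2i * 2.9)), 2.9 %% pi, tolerance = 1e-12)
  expect_true(is.na(slant_axis(NA_complex_)))
})

test_that("anisotropy index follows its min/max definition", {
  expect_equal(anisotropy(rep(0.4, 6)), 0)
  expect_equal(anisotropy(c(0, 1, 0.5)), 1)
  expect_equal(anisotropy(c(2, 1, 1.5, 1)), 0.5)
  expect_true(is.na(anisotropy(c(0, 0))))
})

test_that("A and the resultant magnitude are invariant to rescaling", {
  set.seed(11)
  d <- runif(8, 0.1, 2)
  th <- seq(0, pi, length.out = 9)[1:8]
  for (c in c(0.2, 5)) {
    expect_equal(anisotropy(c * d), anisotropy(d), tolerance = 1e-12)
    expect_equal(slant_magnitude(orientation_resultant(c * d, th)),
                 slant_magnitude(orientation_resultant(d, th)),
                 tolerance = 1e-12)
  }
})

test_that("a grating's orientation is recovered through modules I-II", {
  sp <- filter_bank_spec(8, 2, 0.08, 0.2)
  gb <- make_gabor_bank(sp)
  bp <- make_bipole_lobes(sp)
  recover <- function(theta0) {
    img <- grating(72, theta0, 0.125)
    v1 <- module_I(img, gb)
    v2 <- module_II(v1, bp)
    d <- vapply(1:8, function(o) mean(fs_sum_freq(v2)[25:48, 25:48, o]),
                numeric(1))
    slant_axis(orientation_resultant(d, sp$thetas))
  }
  bin <- pi / 8
  for (theta0 in c(pi / 6, pi / 2)) {
    est <- recover(theta0)
    err <- abs(((est - theta0 + pi / 2) %% pi) - pi / 2)
    expect_lt(err, bin + 1e-9)
  }
  # rotation covariance: rotating the grating by 45 deg shifts the axis
  e1 <- recover(pi / 6); e2 <- recover(pi / 6 + pi / 4)
  shift <- ((e2 - e1) %% pi)
  expect_lt(abs(shift - pi / 4), bin + 1e-9)
})

test_that("orientation maps are flat-flagged on untextured input and self-consistent", {
  sp <- filter_bank_spec(4, 2, 0.08, 0.2)
  v2 <- feature_stack(array(0, c(24, 24, 4, 2)), sp$thetas, sp$omegas)
  om <- orientation_map(v2, patch_sigma = 3)
  expect_true(all(is.na(om$magnitude)))
  expect_true(all(is.na(om$anisotropy)))
  # self-consistency: recomputing the scalar fields from the pooled
  # distributions reproduces the maps
  v2b <- random_stack(12, 16, 16, 4, 2)
  omb <- orientation_map(v2b, patch_sigma = 2)
  i <- 8; j <- 9
  d <- omb$pooled[i, j, ]
  expect_equal(omb$anisotropy[i, j], anisotropy(d), tolerance = 1e-12)
  expect_equal(omb$magnitude[i, j],
               slant_magnitude(orientation_resultant(d, omb$thetas)),
               tolerance = 1e-12)
  expect_equal(omb$slant_axis[i, j],
               slant_axis(orientation_resultant(d, omb$thetas)),
               tolerance = 1e-12)
})
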