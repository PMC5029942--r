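# Module IV: signed gradients, directed integration, depth finalization.

test_that("energy gradients vanish on constants and sign-track ramps", {
  sp <- filter_bank_spec(4, 2, 0.08, 0.2)
  fd <- make_first_derivative_bank(sp)
  n <- 64
  expect_lt(max(abs(energy_gradient(matrix(1.3, n, n), fd))), 1e-8)
  ramp <- matrix(seq(0, 1, length.out = n), n, n)         # rises along rows
  g <- energy_gradient(ramp, fd)
  # theta = 0 channel differentiates along +rows: constant positive sign
  # in the interior; the perpendicular channel is ~0
  inter <- bare(g)[20:44, 20:44, , 1]
  expect_gt(min(inter[, , 1]), 0)
  expect_lt(max(abs(inter[, , 3])), 1e-6 * max(inter[, , 1]))
  # reversing the ramp mirrors the response and flips its sign
  g2 <- energy_gradient(ramp[n:1, ], fd)
  expect_equal(bare(g2)[n:1, , 1, 1][20:44, 20:44],
               -bare(g)[20:44, 20:44, 1, 1], tolerance = 1e-9)
})

test_that("directed integration accumulates past a step like a smoothed cumsum", {
  sp <- filter_bank_spec(4, 1, 0.08, 0.2)
  fd <- make_first_derivative_bank(sp)
  itb <- make_it_integration_bank(sp, extent = 40)
  n <- 96
  step <- matrix(0.2, n, n); step[49:n, ] <- 1   # energy rises along rows
  g <- energy_gradient(step, fd, taper = 0)
  r <- directed_integration(g, itb)
  expect_gte(min(r), 0)
  # zero gradient -> zero activity
  z <- fs_like_test(g, array(0, dim(g)), signed = TRUE)
  expect_equal(max(directed_integration(z, itb)), 0)
  # the summed activity rises across the step and stays elevated behind
  # it, tracking the cumulative sum of the rectified gradient within the
  # integration reach
  prof <- rowMeans(depth_combine(r))[30:72]
  csum <- cumsum(rowMeans(pmax(bare(g)[, , 1, 1], 0)))[30:72]
  expect_gt(cor(prof, csum, method = "spearman"), 0.9)
})

test_that("mirroring the scene mirrors the integrated field", {
  sp <- filter_bank_spec(4, 1, 0.08, 0.2)
  fd <- make_first_derivative_bank(sp)
  itb <- make_it_integration_bank(sp, extent = 12)
  set.seed(8)
  base <- gauss_smooth_test(matrix(runif(64^2), 64), 3)
  g1 <- energy_gradient(base, fd, taper = 0)
  g2 <- energy_gradient(base[, 64:1], fd, taper = 0)
  r1 <- depth_combine(directed_integration(g1, itb))
  r2 <- depth_combine(directed_integration(g2, itb))
  expect_equal(r2[, 64:1], r1, tolerance = 1e-6)
})

test_that("depth channel summation matches a loop", {
  st <- random_stack(71, 6, 6, 4, 2)
  raw <- depth_combine(st)
  loop <- matrix(0, 6, 6)
  for (o in 1:4) for (f in 1:2) loop <- loop + unclass(st)[, , o, f]
  expect_equal(raw, loop, tolerance = 1e-12)
  one <- fs_like_test(st, array(0, dim(st)))
  one[2, 3, 1, 1] <- 5
  expect_equal(depth_combine(one)[2, 3], 5)
  expect_equal(max(depth_combine(one * 0)), 0)
})

test_that("finalization masks, inverts and rescales to [0, 1]", {
  raw <- matrix(0, 8, 8); raw[5:8, ] <- 2
  dm <- depth_finalize(raw, smooth_sigma = 0)
  expect_equal(sort(unique(as.vector(dm$depth))), c(0, 1))
  expect_equal(dm$depth[1, 1], 1)   # low activity = near
  expect_equal(dm$depth[6, 2], 0)
  # constant raw -> constant finalized
  cst <- depth_finalize(matrix(3, 8, 8), smooth_sigma = 0)
  expect_equal(diff(range(cst$depth)), 0)
  # range stays inside [0, 1], the far extreme pinned at 0
  set.seed(14)
  rnd <- depth_finalize(matrix(runif(64, 1, 2), 8), smooth_sigma = 0)
  expect_equal(min(rnd$depth), 0)
  expect_lte(max(rnd$depth), 1)
  # contract errors
  expect_error(depth_finalize(raw, mask = matrix(FALSE, 8, 8)), "empty mask")
  expect_error(depth_finalize(matrix(0, 8, 8)), "all-zero")
  msk <- matrix(FALSE, 8, 8); msk[1:4, ] <- TRUE
  dm2 <- depth_finalize(raw + 1, mask = msk, smooth_sigma = 0)
  expect_true(all(is.na(dm2$depth[5:8, ])))
})

test_that("contour mode demands an explicit integration direction", {
  img <- matrix(runif(32 * 32), 32)
  expect_error(contour_mode(img), "direction")
  expect_error(contour_mode(img, integration_direction = NULL), "direction")
})
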