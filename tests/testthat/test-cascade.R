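# The three-stage steady-state dynamics against independent loop oracles.

test_that("rectification follows its definition and rejects non-finite input", {
  expect_equal(rect(-3), 0)
  expect_equal(rect(0), 0)
  expect_equal(rect(2.5), 2.5)
  expect_equal(rect(c(-1, 0.5, 2)), c(0, 0.5, 2))
  expect_error(rect(c(1, NaN)), "non-finite")
})

test_that("inhibitory pool matches the brute-force loop evaluation", {
  r <- random_stack(41)
  p <- cascade_params(delta = 0.3, eps = 0.7, pool_sigma = 1.5)
  q <- inhibitory_pool(r, p)
  expect_equal(bare(q), brute_pool(unclass(r), p), tolerance = 1e-10)
})

test_that("pool reduces to the feature sum when the spatial term is off", {
  d <- dim(random_stack(1))
  vals <- array(0, d)
  vals[3, 4, 2, 1] <- 1
  r <- feature_stack(vals, attr(random_stack(1), "thetas"),
                     attr(random_stack(1), "omegas"))
  p <- cascade_params(delta = 0.6, eps = 0)
  q <- inhibitory_pool(r, p)
  expect_equal(unclass(q)[3, 4, , ], matrix(0.6, d[3], d[4]))
  expect_equal(sum(q) - sum(unclass(q)[3, 4, , ]), 0)
  expect_equal(bare(inhibitory_pool(rect(r * 0), p)), array(0, d))
})

test_that("feedback signal matches the brute-force loop and its gate closes", {
  rh <- random_stack(42)
  p <- cascade_params(lambda_fb = 0.5, pool_sigma = 1.2)
  net <- feedback_signal(rh, p)
  expect_equal(bare(net), brute_feedback(unclass(rh), p), tolerance = 1e-10)
  expect_true(min(net) >= 0)
  # zero higher activity -> zero feedback
  z <- rect(rh * 0)
  expect_equal(max(feedback_signal(z, p)), 0)
  # units at or above lambda_fb receive nothing
  hot <- fs_like_test(rh, pmin(unclass(rh) + p$lambda_fb, 1))
  expect_equal(max(feedback_signal(hot, p)), 0)
  # receiver-gated variant matches its oracle too
  own <- random_stack(43)
  net2 <- feedback_signal(rh, p, r_own = own)
  expect_equal(bare(net2), brute_feedback(unclass(rh), p, unclass(own)),
               tolerance = 1e-10)
})

test_that("steady state matches the scalar formula and its bounds", {
  set.seed(7)
  drive <- random_stack(44); net <- random_stack(45); q <- random_stack(46)
  p <- cascade_params(beta = 2, xi = 0.4, alpha = 0.3, gamma = 0.8,
                      eta = 0.05)
  r <- steady_state(drive, net, q, p)
  expect_equal(bare(r),
               brute_steady(bare(drive), bare(net), bare(q), p),
               tolerance = 1e-12)
  # saturation: large drive approaches beta/gamma within 1%
  big <- fs_like_test(drive, array(1e4 * max(p$alpha, max(q)), dim(drive)))
  rs <- steady_state(big, net * 0, q, p)
  expect_true(all(abs(rs - p$beta / p$gamma) < 0.01 * p$beta / p$gamma))
  # zero drive with eta = 0 rectifies to zero
  p0 <- cascade_params(eta = 0)
  expect_equal(max(steady_state(drive * 0, net * 0, q, p0)), 0)
  # responses never exceed beta/gamma + eta/alpha
  expect_true(max(r) <= p$beta / p$gamma + p$eta / p$alpha + 1e-12)
})

test_that("steady state is nondecreasing in drive at fixed pool/feedback", {
  p <- cascade_params()
  q <- 0.3; net <- 0.2
  d <- seq(0, 5, length.out = 101)
  r <- brute_steady(d, net, q, p)
  imp <- vapply(d, function(x) {
    s <- steady_state(feature_stack(array(x, c(1, 1, 2, 1)),
                                    c(0, pi / 2), 0.1),
                      feature_stack(array(net, c(1, 1, 2, 1)), c(0, pi / 2), 0.1),
                      feature_stack(array(q, c(1, 1, 2, 1)), c(0, pi / 2), 0.1),
                      p)[1, 1, 1, 1]
    s
  }, numeric(1))
  expect_equal(imp, r, tolerance = 1e-12)
  expect_true(all(diff(imp) >= -1e-12))
})

test_that("normalization enhances the stronger of two pooled units", {
  # two units sharing one pool: the response ratio after normalization is
  # at least the drive ratio
  # the pool must be strong enough that subtractive inhibition dominates
  # the divisive self-term; delta = 1 realises that regime
  p <- cascade_params(delta = 1, eps = 0)
  for (pair in list(c(1, 0.5), c(0.8, 0.1), c(2, 1.5))) {
    d <- feature_stack(array(pair, c(1, 1, 2, 1)), c(0, pi / 2), 0.1)
    q <- inhibitory_pool(d, p)
    r <- steady_state(d, d * 0, q, p)
    if (r[1, 1, 2, 1] > 0) {
      expect_gte(r[1, 1, 1, 1] / r[1, 1, 2, 1], pair[1] / pair[2] - 1e-9)
    } else {
      expect_gt(r[1, 1, 1, 1], 0)
    }
  }
})

test_that("run_stage honours its feedforward and invariance contracts", {
  bank <- NULL
  ident_combine <- function(input, bank) input
  d <- random_stack(47)
  p <- cascade_params()
  one <- run_stage(d, bank, ident_combine, NULL, p, n_cycles = 1L)
  q1 <- inhibitory_pool(rect(d), p)
  direct <- steady_state(rect(d), fs_like_test(d, array(0, dim(d))), q1, p)
  expect_equal(unclass(one), unclass(direct), tolerance = 1e-12)
  # zero input stays zero through any number of cycles (eta = 0)
  z <- run_stage(d * 0, bank, ident_combine, NULL, p, n_cycles = 3L)
  expect_equal(max(z), 0)
  # doubling beta and gamma together leaves the saturation bound unchanged
  p2 <- cascade_params(beta = 2 * p$beta, gamma = 2 * p$gamma)
  big <- fs_like_test(d, array(1e5, dim(d)))
  zero <- fs_like_test(d, array(0, dim(d)))
  r1 <- steady_state(big, zero, zero, p)
  r2 <- steady_state(big, zero, zero, p2)
  expect_equal(max(r1), max(r2), tolerance = 1e-3)
  expect_equal(max(r1), p$beta / p$gamma, tolerance = 1e-3)
  # outputs bounded for random input
  expect_true(max(one) <= p$beta / p$gamma + p$eta / max(p$alpha, 1e-9) + 1e-9)
})
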