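test_that("P2 attains its analytic extremes and isotropic null", {
  par <- p2_from_segments(matrix(rep(c(0, 0, 2), 10), ncol = 3, byrow = TRUE),
                          c(0, 0, 1))
  expect_equal(par$p2, 1)
  perp <- p2_from_segments(matrix(rep(c(1, 1, 0), 10), ncol = 3, byrow = TRUE),
                           c(0, 0, 1))
  expect_equal(perp$p2, -0.5)
  set.seed(4)
  iso <- p2_from_segments(matrix(rnorm(3 * 2e4), ncol = 3), c(0, 0, 1))
  expect_lt(abs(iso$p2), 3 / sqrt(2e4))
  expect_true(all(iso$angles >= 0 & iso$angles <= pi))
  expect_error(p2_from_segments(rbind(c(0, 0, 0)), c(0, 0, 1)), "zero-length")
})

test_that("system-level P2 uses next-nearest-neighbour segments", {
  # straight chain along z: segments all parallel to +z
  n <- 12
  pos <- cbind(2, 2, seq(1, by = 0.15, length.out = n))
  topo <- empty_topology(n)
  topo$chain <- rep(1L, n)
  sys <- particle_system(pos, rep("CH2", n), c(6, 6, 6), topology = topo)
  r <- order_parameter_p2(sys, 1, c(0, 0, 1))
  expect_equal(r$p2, 1, tolerance = 1e-12)
  expect_equal(r$n_segments, n - 2)
  expect_error(order_parameter_p2(
    particle_system(pos[1:2, ], rep("CH2", 2), c(6, 6, 6),
                    topology = within(empty_topology(2), chain <- c(1L, 1L))),
    1), "fewer than 3")
})

test_that("P2 stays within [-0.5, 1] for arbitrary segment sets", {
  set.seed(6)
  for (rep in 1:20) {
    v <- matrix(rnorm(3 * sample(3:50, 1)), ncol = 3)
    p <- p2_from_segments(v, rnorm(3))$p2
    expect_gte(p, -0.5); expect_lte(p, 1)
  }
})

test_that("layered fixtures recover the planted spacing", {
  lf <- make_layered_fixture(1.17, 6, 0.05, seed = 4)
  pr <- concentration_profile(lf$system, n_bins = 36)
  expect_equal(length(pr$peaks), 6)
  expect_equal(pr$spacing, 1.17, tolerance = lf$system$box[3] / 36)
  exact <- make_layered_fixture(1.0, 3, 0, seed = 4)
  expect_equal(concentration_profile(exact$system, n_bins = 24)$spacing, 1.0,
               tolerance = 1e-9)
})

test_that("uniform distributions and jitter-swamped layers raise the no-peak flag", {
  set.seed(5)
  un <- particle_system(matrix(runif(3 * 160) * 5, ncol = 3),
                        rep("AA", 160), c(5, 5, 5))
  pr <- concentration_profile(un, n_bins = 24)
  expect_true(pr$no_peaks)
  expect_true(is.na(pr$spacing))
  swamped <- make_layered_fixture(0.1, 50, 0.5, seed = 7, n_per_layer = 4)
  expect_true(concentration_profile(swamped$system, n_bins = 10)$no_peaks)
  expect_error(concentration_profile(un, n_bins = 3), "n_bins")
})
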