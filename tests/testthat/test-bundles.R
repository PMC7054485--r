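test_that("constructed bundle fixtures are detected as expected", {
  f <- make_bundle_fixture(3, 0, 1.0, 0, seed = 1)
  b <- detect_bundles(f$system)
  expect_length(b, 1)
  expect_equal(b[[1]]$members, 1:3)
  # misaligned chains form no organized structure
  expect_length(detect_bundles(make_bundle_fixture(3, 50, 1.0, 0, seed = 1)$system), 0)
  # fewer than three chains can never bundle
  expect_length(detect_bundles(make_bundle_fixture(2, 0, 1.0, 0, seed = 1)$system), 0)
  # short chains (re below 0.65) are excluded even when parallel
  expect_length(detect_bundles(make_bundle_fixture(3, 0, 0.5, 0, seed = 1)$system), 0)
})

test_that("bundle members always satisfy the membership predicates", {
  for (seed in 1:5) {
    sys <- random_sfc_system(12, 3, seed = seed)
    cl <- identify_clusters(sys)
    sf <- sfc_records(sys, cl)
    bs <- detect_bundles(sys, sf, cl)
    for (b in bs) {
      rows <- sf[match(b$members, sf$sfc), ]
      expect_true(all(rows$re > 0.65))
      expect_true(all(rows$connectivity == "two-cluster"))
      pair <- paste(pmin(rows$cluster_i, rows$cluster_j),
                    pmax(rows$cluster_i, rows$cluster_j), sep = "-")
      expect_length(unique(pair), 1)
      expect_gte(length(b$members), 3)
    }
  }
})

test_that("detection equals the exhaustive subset-enumeration oracle", {
  for (seed in 1:12) {
    n_sfc <- sample(6:16, 1)
    sys <- random_sfc_system(n_sfc, sample(2:4, 1), seed = seed + 100)
    cl <- identify_clusters(sys)
    sf <- sfc_records(sys, cl)
    mine <- lapply(detect_bundles(sys, sf, cl), `[[`, "members")
    ref <- oracle_bundles(sys, sf, cl)
    expect_equal(canon_bundles(mine), canon_bundles(ref),
                 label = paste("seed", seed))
  }
})

test_that("fiber_vector is the normalized sum and rejects degeneracy", {
  expect_equal(fiber_vector(matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE)),
               c(0, 0, 1))
  expect_error(fiber_vector(rbind(c(0, 0, 1), c(0, 0, -1))), "zero")
  set.seed(2)
  v <- matrix(rnorm(12), 4, 3)
  s <- colSums(v)
  expect_equal(fiber_vector(v), s / sqrt(sum(s^2)))
})

test_that("scripted rigid rotations and twists are recovered exactly", {
  f <- make_bundle_fixture(4, 5, 1.0, 0.01, seed = 3)
  b <- detect_bundles(f$system)[[1]]
  s0 <- f$system
  rot <- function(sys, groups, ang) {
    sys$positions[groups, ] <- rotate_about_axis(
      sys$positions[groups, , drop = FALSE], b$fiber, ang, b$M1)
    sys
  }
  # identity
  expect_equal(bundle_rotation(b, s0, s0), c(0, 0), tolerance = 1e-12)
  # synchronized rotation: equal ends, zero twist
  s1 <- rot(rot(s0, b$end1, 0.3), b$end2, 0.3)
  expect_equal(bundle_rotation(b, s0, s1), c(0.3, 0.3), tolerance = 1e-10)
  expect_equal(bundle_twist(b, s0, s1), 0, tolerance = 1e-10)
  # counter-rotation: twist is the difference of the end angles
  s2 <- rot(rot(s0, b$end1, 0.2), b$end2, -0.2)
  expect_equal(bundle_rotation(b, s0, s2), c(0.2, -0.2), tolerance = 1e-10)
  expect_equal(bundle_twist(b, s0, s2), 0.4, tolerance = 1e-10)
})

test_that("bundle matching tracks persistence by members and cluster pair", {
  f <- make_bundle_fixture(4, 5, 1.0, 0.01, seed = 3)
  b0 <- detect_bundles(f$system)
  expect_equal(match_bundles(b0, b0), 1L)
  expect_true(is.na(match_bundles(b0, structure(list(), class = "bundle_set"))))
})
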