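aa_system <- function(pos, box = c(5, 5, 5)) {
  wrap_positions(particle_system(pos, rep("AA", nrow(pos)), box))
}

test_that("pairs below and above the linkage cutoff split as expected", {
  two <- aa_system(rbind(c(1, 1, 1), c(1, 1, 1.3)))
  cl <- identify_clusters(two, 0.5)
  expect_equal(max(cl$membership), 1)
  apart <- aa_system(rbind(c(1, 1, 1), c(1, 1, 1.9)))
  cl2 <- identify_clusters(apart, 0.5)
  expect_equal(max(cl2$membership), 2)
  expect_error(identify_clusters(two, 0), "positive")
  # periodicity: points near opposite faces link through the boundary
  per <- aa_system(rbind(c(0.1, 1, 1), c(4.9, 1, 1)))
  expect_equal(max(identify_clusters(per, 0.5)$membership), 1)
})

test_that("single-linkage components match a brute-force union-find oracle", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    pts <- matrix(runif(3 * n, 0, 4), n, 3)
    cutoff <- runif(1, 0.4, 1.2)
    sys <- aa_system(pts, c(4, 4, 4))
    mine <- identify_clusters(sys, cutoff)$membership
    ref <- uf_components(sys$positions, c(4, 4, 4), cutoff)
    # same partition (labels may differ)
    expect_equal(outer(mine, mine, "=="), outer(ref, ref, "=="))
  }
})

test_that("cluster ids persist across frames by maximal overlap", {
  # blob {1,2,3} and blob {4,5}
  s1 <- aa_system(rbind(c(1, 1, 1), c(1, 1, 1.3), c(1, 1.3, 1),
                        c(3, 3, 3), c(3, 3, 3.3)))
  c1 <- identify_clusters(s1, 0.5)
  expect_equal(c1$membership, c(1L, 1L, 1L, 2L, 2L))
  # particle 3 hops to the second blob: raw labels change membership but the
  # matched labels keep each blob's identity
  s2 <- aa_system(rbind(c(1, 1, 1), c(1, 1, 1.3), c(3, 3.3, 3),
                        c(3, 3, 3), c(3, 3, 3.3)))
  c2 <- match_clusters(c1, identify_clusters(s2, 0.5))
  expect_equal(c2$membership, c(1L, 1L, 2L, 2L, 2L))
  # wholesale identity swap: matching follows the particles, not the sites
  s3 <- aa_system(rbind(c(3, 3, 3), c(3, 3, 3.3), c(3, 3.3, 3),
                        c(1, 1, 1), c(1, 1, 1.3)))
  c3 <- match_clusters(c1, identify_clusters(s3, 0.5))
  expect_equal(c3$membership, c(1L, 1L, 1L, 2L, 2L))
})

test_that("a single regular tetrahedron gives the closed-form fraction", {
  a <- 0.5 # edge length below the threshold
  v <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
             c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
  sys <- aa_system(sweep(v, 2, c(2, 2, 2), "+"))
  vf <- cluster_volume_fraction(sys, edge_threshold = 0.65)
  expect_equal(vf$fraction, (a^3 / (6 * sqrt(2))) / 125, tolerance = 1e-10)
  expect_equal(vf$damage, 1 / vf$fraction)
  # push one vertex out so an edge exceeds the threshold -> fraction 0
  v2 <- v; v2[4, 3] <- 0.9
  sys2 <- aa_system(sweep(v2, 2, c(2, 2, 2), "+"))
  vf2 <- cluster_volume_fraction(sys2, edge_threshold = 0.65)
  expect_equal(vf2$fraction, 0)
  expect_identical(vf2$damage, Inf)
})

test_that("volume fraction equals a Cayley-Menger simplex-enumeration oracle", {
  for (seed in c(3, 7, 21)) {
    sys <- make_clustered_points(5, 10, 0.15, 6, seed = seed)
    thr <- 0.65
    vf <- cluster_volume_fraction(sys, thr)
    pts <- wrap_positions(sys)$positions
    aug <- fibrilMD:::augment_periodic(pts, sys$box, thr)
    tets <- fibrilMD:::delaunay3d(aug)
    vol <- 0
    for (r in seq_len(nrow(tets))) {
      v <- aug[tets[r, ], ]
      if (max(dist(v)) > thr) next
      ctr <- colMeans(v)
      if (any(ctr < 0) || any(ctr >= sys$box)) next
      vol <- vol + cayley_menger_volume(v)
    }
    expect_equal(vf$fraction, vol / prod(sys$box), tolerance = 1e-9)
  }
})

test_that("volume fraction is bounded and monotone in the edge threshold", {
  sys <- make_clustered_points(4, 12, 0.2, 6, seed = 5)
  thrs <- c(0.4, 0.55, 0.65, 0.8, 1.0)
  fr <- vapply(thrs, function(t) cluster_volume_fraction(sys, t)$fraction, 1)
  expect_true(all(fr >= 0 & fr <= 1))
  expect_true(all(diff(fr) >= -1e-12))
})

test_that("degenerate point sets are rejected", {
  flat <- aa_system(cbind(matrix(runif(20, 1, 3), 10, 2), 2))
  expect_error(cluster_volume_fraction(flat, 0.65), "degenerate")
  few <- aa_system(rbind(c(1, 1, 1), c(2, 2, 2)))
  expect_error(cluster_volume_fraction(few, 0.65), "at least 4")
})
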