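test_that("a single 10-bead repeat gives the forced chain connectivity", {
  sys <- build_network(1, 10, 5, 0, seed = 3)
  expect_equal(n_particles(sys), 10)
  expect_equal(nrow(sys$topology$bonds), 9)
  expect_equal(nrow(sys$topology$angles), 8)
  expect_equal(as.vector(table(sys$species)[c("AA", "CH2", "O")]),
               c(1L, 6L, 3L))
  expect_equal(nrow(sys$topology$sfcs), 0) # one AA -> no SFC
})

test_that("network composition, SFC census and box match the declared recipe", {
  sys <- build_network(2, 100, 3, 40, seed = 5)
  tab <- table(sys$species)
  expect_equal(as.vector(tab[c("AA", "CH2", "O", "W")]),
               c(20L, 120L, 60L, 40L))
  expect_equal(n_particles(sys), 2 * 100 + 40)
  expect_equal(sys$box, c(3, 3, 3))
  # SFC count = n_chains * (AA per chain - 1); each SFC spans 11 beads
  expect_equal(nrow(sys$topology$sfcs), 2 * (10 - 1))
  span <- sys$topology$sfcs$aa_j - sys$topology$sfcs$aa_i
  expect_true(all(span == 10))
  # every non-terminal AA bounds exactly two SFCs
  aa_use <- table(c(sys$topology$sfcs$aa_i, sys$topology$sfcs$aa_j))
  interior <- setdiff(unlist(sys$topology$aa_by_chain),
                      unlist(lapply(sys$topology$aa_by_chain,
                                    function(a) a[c(1, length(a))])))
  expect_true(all(aa_use[as.character(interior)] == 2))
  # positions wrapped inside the box
  expect_true(all(sys$positions >= 0 & sys$positions < 3))
})

test_that("builds are bit-identical for a fixed seed and differ across seeds", {
  a <- build_network(2, 20, 4, 10, seed = 7)
  b <- build_network(2, 20, 4, 10, seed = 7)
  c <- build_network(2, 20, 4, 10, seed = 8)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  expect_false(identical(a$positions, c$positions))
})

test_that("freshly built systems respect the overlap tolerance", {
  sys <- build_network(2, 50, 3, 100, seed = 9, overlap_tol = 0.21)
  D <- fibrilMD:::min_image_dist_matrix(sys$positions, sys$box)
  diag(D) <- Inf
  b <- sys$topology$bonds
  for (r in seq_len(nrow(b))) D[b$i[r], b$j[r]] <- D[b$j[r], b$i[r]] <- Inf
  a <- sys$topology$angles
  for (r in seq_len(nrow(a))) D[a$i[r], a$k[r]] <- D[a$k[r], a$i[r]] <- Inf
  expect_gte(min(D), 0.21)
})

test_that("impossible packings and bad compositions are rejected", {
  expect_error(build_network(1, 15, 5, 0, seed = 1), "multiple of 10")
  expect_error(build_network(2, 100, 1.0, 4000, seed = 1, max_restarts = 2),
               "packing failure")
})

test_that("velocities follow Maxwell-Boltzmann with zero total momentum", {
  sys <- build_network(4, 100, 4, 500, seed = 11, temperature = 300)
  p <- colSums(sys$velocities * sys$masses)
  expect_lt(max(abs(p)), 1e-9)
  ke <- 0.5 * sum(sys$masses * rowSums(sys$velocities^2))
  Tkin <- 2 * ke / (3 * n_particles(sys) * 0.0083144621)
  expect_lt(abs(Tkin - 300) / 300, 0.1)
})

test_that("four-chains model hits the requested mutual angles and flags ends", {
  for (ang in c(0, 10, 50)) {
    fc <- build_four_chains(60, ang, 4.5, seed = 2)
    expect_true(all(abs(four_chain_angles(fc) - ang) < 0.5))
  }
  fc <- build_four_chains(60, 10, 4.5, seed = 2)
  meta <- fc$topology$four_chains
  expect_true(all(fc$restrained[c(meta$anchors, meta$ends)]))
  expect_equal(sum(fc$restrained), 8)
  # end-to-end distances equal the request
  re <- sqrt(rowSums((fc$positions[meta$ends, ] -
                      fc$positions[meta$anchors, ])^2))
  expect_equal(re, rep(4.5, 4), tolerance = 1e-9)
  # bonds start near rest length (bulged-arc construction)
  b <- fc$topology$bonds
  bl <- sqrt(rowSums((fc$positions[b$i, ] - fc$positions[b$j, ])^2))
  expect_lt(max(abs(bl - 0.15)), 0.03)
})

test_that("four-chains rejects end-to-end beyond the contour length", {
  expect_error(build_four_chains(60, 10, 9.5, seed = 1), "contour")
  expect_error(build_four_chains(60, 95, 4, seed = 1), "mutual_angle")
})

test_that("force-field assignment validates coverage totally", {
  sys <- build_network(1, 20, 4, 5, seed = 1)
  ff <- default_forcefield()
  ff$lj <- ff$lj[ff$lj$species != "W", ]
  expect_error(assign_forcefield(sys, ff), "species: W")
  ff2 <- default_forcefield()
  ff2$bonds <- ff2$bonds[ff2$bonds$type != "AA-CH2", ]
  expect_error(assign_forcefield(sys, ff2), "bond parameters")
  # empty system passes vacuously
  empty <- particle_system(matrix(numeric(0), 0, 3), character(0), c(1, 1, 1))
  expect_silent(assign_forcefield(empty, default_forcefield()))
  # cutoff must fit the box
  expect_error(assign_forcefield(sys, default_forcefield(cutoff = 2.5)),
               "half the smallest box edge")
})
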