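test_that("harmonic bond at rest length and LJ pair at its minimum", {
  d <- harmonic_dimer(sep = 0.15)
  e <- potential_energy(d)
  expect_equal(e$bond, 0, tolerance = 1e-12)
  # neutral pair at 2^(1/6) sigma: LJ term = -eps (+ small cutoff shift)
  sys <- particle_system(rbind(c(1, 1, 1), c(1, 1, 1 + 2^(1/6) * 0.3166)),
                         c("W", "W"), c(8, 8, 8))
  sys <- assign_forcefield(sys, default_forcefield(cutoff = 3.9))
  expect_equal(potential_energy(sys)$lj, -0.65, tolerance = 1e-4)
})

test_that("engine energy equals an independent hand-summed evaluation", {
  # 5-particle fixed configuration with bonds, an angle, LJ and charges
  pos <- rbind(c(1.0, 1.0, 1.0), c(1.15, 1.02, 1.01),
               c(1.25, 1.14, 1.05), c(2.1, 1.9, 1.4), c(0.4, 2.6, 2.2))
  sp <- c("AA", "CH2", "O", "AA", "W")
  topo <- empty_topology(5)
  topo$bonds <- data.frame(i = c(1L, 2L), j = c(2L, 3L),
                           type = c("AA-CH2", "CH2-O"))
  topo$angles <- data.frame(i = 1L, j = 2L, k = 3L, type = "AA-CH2-O")
  sys <- particle_system(pos, sp, c(3, 3, 3), topology = topo)
  sys <- assign_forcefield(sys, full_ff(cutoff = 1.4,
                                        charges = c(AA = -0.2, CH2 = 0,
                                                    O = 0.1, W = 0.05)))
  ours <- potential_energy(sys)
  ref <- brute_energy(sys)
  for (term in c("bond", "angle", "lj", "coulomb", "total"))
    expect_equal(ours[[term]], ref[[term]], tolerance = 1e-10, label = term)
  expect_equal(ours$total, ours$bond + ours$angle + ours$lj + ours$coulomb)
})

test_that("analytic forces match central-difference energy gradients", {
  set.seed(5)
  for (rep in 1:3) {
    n <- 10
    pos <- matrix(runif(3 * n, 1, 2.6), n, 3)
    sp <- sample(c("AA", "CH2", "O", "W"), n, TRUE)
    topo <- empty_topology(n)
    topo$bonds <- data.frame(i = 1:3, j = 2:4,
                             type = paste(sp[1:3], sp[2:4], sep = "-"))
    topo$angles <- data.frame(i = 1:2, j = 2:3, k = 3:4,
                              type = paste(sp[1:2], sp[2:3], sp[3:4], sep = "-"))
    sys <- particle_system(pos, sp, c(4, 4, 4), topology = topo)
    sys <- assign_forcefield(sys, full_ff(cutoff = 1.9,
                                          charges = c(AA = -0.2, CH2 = 0,
                                                      O = 0.1, W = 0.05)))
    f <- compute_forces(sys)
    h <- 1e-6
    num <- matrix(0, n, 3)
    for (i in seq_len(n)) for (d in 1:3) {
      s1 <- sys; s1$positions[i, d] <- s1$positions[i, d] + h
      s2 <- sys; s2$positions[i, d] <- s2$positions[i, d] - h
      num[i, d] <- -(potential_energy(s1)$total -
                     potential_energy(s2)$total) / (2 * h)
    }
    expect_lt(max(abs(f - num)) / max(abs(f)), 1e-6)
  }
})

test_that("a free particle moves in a straight line", {
  sys <- particle_system(matrix(c(1, 1, 1), 1), "W", c(10, 10, 10))
  sys <- assign_forcefield(sys, default_forcefield())
  sys$velocities <- matrix(c(0.1, 0.05, -0.02), 1)
  out <- fibrilMD:::run_md(sys, 1000, 0.01, 300, 0, stride = 1e6)
  expect_equal(as.vector(out$system$positions),
               c(1, 1, 1) + 10 * c(0.1, 0.05, -0.02), tolerance = 1e-10)
})

test_that("NVE energy drift on the harmonic dimer is below 1e-4", {
  d <- harmonic_dimer()
  out <- fibrilMD:::run_md(d, 10000, 0.002, 300, 0, stride = 1e6,
                           log_stride = 10)
  E <- out$trajectory$log$potential + out$trajectory$log$kinetic
  k <- max(2, floor(length(E) * 0.05))
  drift <- abs(mean(tail(E, k)) - mean(head(E, k))) / abs(mean(E))
  expect_lt(drift, 1e-4)
})

test_that("deformation increments conserve volume to machine precision", {
  sys <- build_network(1, 20, 4, 0, seed = 1)
  v0 <- prod(sys$box)
  set.seed(2)
  for (rate in runif(25, -0.5, 2)) sys <- apply_deformation_increment(sys, rate, 5)
  expect_lt(abs(prod(sys$box) - v0) / v0, 1e-12)
  # identity at rate 0 and the 100% closed form
  s2 <- apply_deformation_increment(sys, 0, 5)
  expect_identical(s2$box, sys$box)
  cube <- particle_system(matrix(c(1, 1, 1), 1), "W", c(5, 5, 5))
  cube <- apply_deformation_increment(cube, 1, 1000) # 100% in one increment
  expect_equal(cube$box, c(5 / sqrt(2), 5 / sqrt(2), 10), tolerance = 1e-12)
  expect_equal(prod(cube$box), 125, tolerance = 1e-10)
})

test_that("thermostatted kinetic temperature holds the set point within 3%", {
  sys <- build_network(1, 30, 2.6, 120, seed = 4,
                       ff = default_forcefield(cutoff = 1.0))
  sys <- minimize_system(sys, 300)
  out <- fibrilMD:::run_md(sys, 24000, 0.005, 300, 1, stride = 1e6,
                           log_stride = 40, seed = 9)
  Tkin <- out$trajectory$log$temperature
  Tkin <- Tkin[-(1:100)] # discard the initial transient
  expect_lt(abs(mean(Tkin) - 300) / 300, 0.03)
})

test_that("runs are reproducible for a fixed seed", {
  sys <- build_network(1, 20, 3, 30, seed = 6,
                       ff = default_forcefield(cutoff = 1.0))
  sys <- minimize_system(sys, 200)
  a <- fibrilMD:::run_md(sys, 500, 0.005, 300, 1, stride = 100, seed = 42)
  b <- fibrilMD:::run_md(sys, 500, 0.005, 300, 1, stride = 100, seed = 42)
  expect_identical(a$system$positions, b$system$positions)
  expect_identical(a$trajectory$log, b$trajectory$log)
})

test_that("run_protocol ramps linearly, holds, and reverses at the same rate", {
  # free particles make long ramps cheap; rate 100/ns to 50% in 5 ps
  sys <- particle_system(rbind(c(1, 1, 1), c(2, 2, 2)), c("W", "W"),
                         c(5, 5, 5))
  sys <- assign_forcefield(sys, default_forcefield())
  prot <- deformation_protocol(100, 0.5, hold = 0.002, reverse = TRUE,
                               dt = 0.01, stride = 50)
  out <- run_protocol(sys, prot, seed = 1)
  lg <- out$trajectory$log
  # ramp duration = ratio / rate = 5 ps; strain grows linearly in time
  ramp <- lg[lg$time <= 5, ]
  expect_equal(ramp$Lz, 5 * (1 + 100e-3 * ramp$time), tolerance = 1e-9)
  expect_equal(max(lg$Lz), 7.5, tolerance = 1e-9)
  # volume constant throughout all phases
  expect_lt(max(abs(lg$Lx * lg$Ly * lg$Lz - 125)) / 125, 1e-12)
  # reverse brings the box back to its original shape
  expect_equal(out$system$box, c(5, 5, 5), tolerance = 1e-9)
  expect_setequal(unique(out$trajectory$phase), c("ramp", "hold", "reverse"))
})

test_that("null protocols and error paths behave", {
  sys <- particle_system(matrix(c(1, 1, 1), 1), "W", c(5, 5, 5))
  sys <- assign_forcefield(sys, default_forcefield())
  prot <- deformation_protocol(1, 0, hold = 0.001, dt = 0.01)
  out <- run_protocol(sys, prot, seed = 1)
  expect_true(all(out$trajectory$boxes == 5))
  expect_error(deformation_protocol(0, 0.5), "rate must be positive")
  expect_error(deformation_protocol(1, -0.1), "target_ratio")
  # zero-distance pair is a singular configuration
  bad <- particle_system(rbind(c(1, 1, 1), c(1, 1, 1)), c("W", "W"),
                         c(5, 5, 5))
  bad <- assign_forcefield(bad, default_forcefield())
  expect_error(potential_energy(bad), "zero distance")
})
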