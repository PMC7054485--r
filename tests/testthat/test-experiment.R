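test_that("the experiment driver is deterministic and writes its report", {
  outdir <- withr::local_tempdir()
  cfg <- default_run_config(
    "reduced",
    system = list(n_chains = 1, groups_per_chain = 50, box_edge = 2.6,
                  n_water = 60, temperature = 300, cutoff = 1.0),
    protocol = list(rate = 20, target_ratio = 0.3, hold = 0.05,
                    reverse = FALSE, dt = 0.008, friction = 1, stride = 500),
    equilibration_ps = 10, minimize_steps = 200,
    seed = 3, outdir = outdir)
  rep1 <- run_experiment(cfg)
  rep2 <- run_experiment(cfg)
  expect_equal(rep1$aggregate, rep2$aggregate)
  expect_identical(rep1$hash, rep2$hash)
  # tables and provenance on disk
  expect_true(file.exists(file.path(outdir, "structure_seed3.tsv")))
  expect_true(file.exists(file.path(outdir, "structure_aggregate.tsv")))
  expect_true(file.exists(file.path(outdir, "provenance.txt")))
  tab <- read_analysis_table(file.path(outdir, "structure_seed3.tsv"))
  expect_equal(nrow(tab), nrow(rep1$per_seed[[1]]))
  expect_match(readLines(file.path(outdir, "structure_seed3.tsv"))[2],
               rep1$hash)
  # strain reaches the target during the ramp
  expect_equal(max(tab$strain), 0.3, tolerance = 0.01)
})

test_that("multi-seed experiments aggregate mean and sd across replicates", {
  cfg <- default_run_config(
    "reduced",
    system = list(n_chains = 1, groups_per_chain = 50, box_edge = 2.6,
                  n_water = 60, temperature = 300, cutoff = 1.0),
    protocol = list(rate = 30, target_ratio = 0.3, hold = 0.02,
                    reverse = FALSE, dt = 0.008, friction = 1, stride = 400),
    equilibration_ps = 5, minimize_steps = 150,
    seed = 11, n_replicates = 2)
  rep <- run_experiment(cfg)
  expect_length(rep$per_seed, 2)
  expect_equal(rep$seeds, c(11, 12))
  expect_true(all(c("damage_mean", "damage_sd", "n_bundles_mean",
                    "n_bundles_sd") %in% names(rep$aggregate)))
  expect_true(any(is.finite(rep$aggregate$strain_sd)))
})

test_that("equilibration-only configurations leave the box untouched", {
  cfg <- default_run_config(
    "reduced",
    system = list(n_chains = 1, groups_per_chain = 50, box_edge = 2.6,
                  n_water = 60, temperature = 300, cutoff = 1.0),
    protocol = list(rate = 1, target_ratio = 0, hold = 0.05,
                    reverse = FALSE, dt = 0.008, friction = 1, stride = 500),
    equilibration_ps = 5, minimize_steps = 150, seed = 2)
  rep <- run_experiment(cfg)
  tab <- rep$per_seed[[1]]
  expect_true(all(abs(tab$strain) < 1e-12))
  expect_true(all(tab$Lz == tab$Lz[1]))
})
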