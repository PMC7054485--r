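test_that("the four class thresholds assign the canonical cases", {
  expect_equal(as.character(classify_sfc(0.35, "same-cluster")), "loop1")
  expect_equal(as.character(classify_sfc(0.5, "same-cluster")), "loop2")
  expect_equal(as.character(classify_sfc(0.70, "two-cluster")), "unstretched")
  expect_equal(as.character(classify_sfc(0.90, "two-cluster")), "stretched")
  # half-open boundaries fall to the lower class
  expect_equal(as.character(classify_sfc(c(0.42, 0.65, 0.85), "same-cluster")),
               c("loop1", "loop2", "unstretched"))
  expect_error(classify_sfc(-0.1, "same-cluster"), "non-negative")
})

test_that("conflicting connectivity is labelled by distance and flagged", {
  cls <- classify_sfc(c(0.9, 0.3), c("same-cluster", "two-cluster"))
  expect_equal(as.character(cls), c("stretched", "loop1"))
  expect_equal(attr(cls, "inconsistent"), c(TRUE, TRUE))
  ok <- classify_sfc(c(0.3, 0.9), c("same-cluster", "two-cluster"))
  expect_equal(attr(ok, "inconsistent"), c(FALSE, FALSE))
})

test_that("every SFC gets exactly one class and counts sum to the total", {
  sys <- build_network(2, 100, 3, 100, seed = 31,
                       ff = default_forcefield(cutoff = 1.0))
  sys <- minimize_system(sys, 200)
  sf <- sfc_records(sys)
  expect_equal(nrow(sf), 2 * 9)
  expect_true(all(sf$class %in% c("loop1", "loop2", "unstretched",
                                  "stretched")))
  expect_equal(sum(table(sf$class)), nrow(sf))
  # random re values partition too
  set.seed(1)
  re <- runif(500, 0, 1.6)
  cls <- classify_sfc(re, sample(c("same-cluster", "two-cluster"), 500, TRUE))
  expect_equal(length(cls), 500)
  expect_false(any(is.na(cls)))
})

test_that("transition matrices count scripted class paths", {
  # static: all mass on the diagonal
  m <- transition_matrix(cbind(c("loop1", "stretched"), c("loop1", "stretched")))
  expect_equal(sum(diag(m)), 2)
  expect_equal(sum(m) - sum(diag(m)), 0)
  # scripted loop1 -> loop2 -> unstretched over 3 frames
  script <- rbind(c("loop1", "loop2", "unstretched"))
  m2 <- transition_matrix(script)
  expect_equal(m2["loop1", "loop2"], 1)
  expect_equal(m2["loop2", "unstretched"], 1)
  expect_equal(sum(m2), 2)
  expect_equal(attr(m2, "neighbor_fraction"), 1)
  expect_equal(attr(m2, "n_skip"), 0)
  # a skip transition is counted as such
  m3 <- transition_matrix(rbind(c("loop1", "stretched")))
  expect_equal(attr(m3, "n_skip"), 1)
  expect_error(transition_matrix(rbind("loop1")), "at least 2 frames")
})
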