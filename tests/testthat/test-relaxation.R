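test_that("autocorrelation limits: frozen vectors and memoryless refresh", {
  frozen <- matrix(rep(c(0, 0, 1), 50), ncol = 3, byrow = TRUE)
  ac <- autocorrelation(frozen, max_lag = 20, dt = 1)
  expect_equal(ac$f, rep(1, 21))
  set.seed(8)
  iid <- matrix(rnorm(3 * 4000), ncol = 3)
  iid <- iid / sqrt(rowSums(iid^2))
  ac2 <- autocorrelation(iid, max_lag = 5, dt = 1, unit = TRUE)
  expect_equal(ac2$f[1], 1)
  expect_lt(max(abs(ac2$f[-1])), 0.08)
  expect_error(autocorrelation(frozen[1, , drop = FALSE]), "at least 2")
  expect_error(autocorrelation(rbind(c(0, 0, 0), c(0, 0, 1)), unit = TRUE),
               "zero-norm")
})

test_that("rotational-diffusion series decay with the planted time constant", {
  x <- make_planted_correlation(20, 15000, 0.1, seed = 6, n_vectors = 6)
  ac <- autocorrelation(x, max_lag = 600, dt = 0.1, origin_stride = 7)
  expect_equal(ac$f[1], 1)
  # curve matches exp(-t/tau*) pointwise within sampling error
  expect_lt(max(abs(ac$f[ac$lag <= 30] - exp(-ac$lag[ac$lag <= 30] / 20))),
            0.08)
  ft <- fit_exponential(ac)
  expect_true(ft$usable)
  expect_equal(ft$tau, 20, tolerance = 0.1 * 20)
  expect_equal(ft$half_time, ft$tau * log(2))
  # determinism of the generator
  y <- make_planted_correlation(20, 100, 0.1, seed = 6, n_vectors = 2)
  z <- make_planted_correlation(20, 100, 0.1, seed = 6, n_vectors = 2)
  expect_identical(y, z)
})

test_that("exponential fits recover noiseless signals and flag pathologies", {
  t <- 0:100
  corr <- structure(list(lag = t, f = exp(-t / 20), dt = 1, label = "x",
                         n_entities = 1), class = "correlation_series")
  ft <- fit_exponential(corr)
  expect_true(ft$usable)
  expect_equal(ft$tau, 20, tolerance = 1e-6)
  # the same pure exponential sampled at another stride gives the same tau
  t2 <- seq(0, 100, by = 0.25)
  corr2 <- structure(list(lag = t2, f = exp(-t2 / 20), dt = 0.25, label = "x",
                          n_entities = 1), class = "correlation_series")
  expect_equal(fit_exponential(corr2)$tau, ft$tau, tolerance = 1e-6)
  # noisy recovery within 10%
  set.seed(9)
  corr3 <- structure(list(lag = t, f = exp(-t / 15) + rnorm(101, sd = 0.02),
                          dt = 1, label = "x", n_entities = 1),
                     class = "correlation_series")
  expect_equal(fit_exponential(corr3)$tau, 15, tolerance = 1.5)
  # constant series: no decay -> unusable, not an error
  flat <- structure(list(lag = t, f = rep(1, 101), dt = 1, label = "x",
                         n_entities = 1), class = "correlation_series")
  expect_false(fit_exponential(flat)$usable)
  # all-negative series -> unusable
  neg <- structure(list(lag = t, f = rep(-0.2, 101), dt = 1, label = "x",
                        n_entities = 1), class = "correlation_series")
  expect_false(fit_exponential(neg)$usable)
  # tau far beyond the window -> unusable
  slow <- structure(list(lag = 0:20, f = exp(-(0:20) / 1e5), dt = 1,
                         label = "x", n_entities = 1),
                    class = "correlation_series")
  expect_false(fit_exponential(slow)$usable)
})

test_that("Weissenberg numbers are exactly multiplicative with sane regimes", {
  w <- weissenberg(1e-4, 20300)
  expect_equal(w$wi, 2.03)
  expect_equal(w$regime, "ve")
  expect_equal(weissenberg(0, 100)$regime, "v")
  expect_equal(weissenberg(0, 100)$wi, 0)
  expect_error(weissenberg(1e-4, 0), "tau must be positive")
  # multiplicativity and monotonicity
  set.seed(3)
  r <- runif(20, 0, 1e-2); tau <- runif(20, 1, 1e5); a <- runif(20, 0.1, 10)
  expect_equal(weissenberg(a * r, tau)$wi, a * weissenberg(r, tau)$wi)
  expect_true(all(diff(weissenberg(sort(r), 100)$wi) >= 0))
})

test_that("the relaxation suite recovers planted taus per observable window", {
  # three planted windows with very different time constants
  mk_corr <- function(tau, dt, n, seed, nv = 6) {
    x <- make_planted_correlation(tau, n, dt, seed = seed, n_vectors = nv)
    fit_exponential(autocorrelation(x, max_lag = round(3 * tau / dt),
                                    dt = dt, origin_stride = 5))
  }
  f1 <- mk_corr(0.05, 0.001, 4000, 11)   # velocity-like window
  f2 <- mk_corr(5, 0.1, 4000, 12)        # bond/conformation-like window
  f3 <- mk_corr(300, 10, 4000, 13)       # cluster/bundle-like window
  expect_equal(f1$tau, 0.05, tolerance = 0.1)
  expect_equal(f2$tau, 5, tolerance = 0.1)
  expect_equal(f3$tau, 300, tolerance = 0.1)
})
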