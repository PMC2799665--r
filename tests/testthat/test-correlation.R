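test_that("G(tau) trivial identities hold", {
  # constant signal: no fluctuation, G = 1 everywhere
  s <- state_series(rep(1L, 100), dt = 0.1)
  g <- fluorescence_autocorrelation(s, lags = c(0, 0.1, 0.5, 1))
  expect_equal(g$values, rep(1, 4))

  # alternating signal: G(0) = 2, G(dt) = 0
  s2 <- state_series(rep(c(1L, 0L), 50), dt = 0.1)
  g2 <- fluorescence_autocorrelation(s2, lags = c(0, 0.1))
  expect_equal(g2$values, c(2, 0))

  # G(0) = 1/mean for any binary signal
  set.seed(3)
  s3 <- state_series(rbinom(400, 1, 0.3), dt = 0.2)
  g3 <- fluorescence_autocorrelation(s3, lags = 0)
  expect_equal(g3$values[1L], 1 / mean(s3$states), tolerance = 1e-12)

  expect_error(fluorescence_autocorrelation(state_series(rep(0L, 10), dt = 1)),
               class = "looplab_degenerate_signal_error")
  expect_error(fluorescence_autocorrelation(s2, lags = 1e5),
               class = "looplab_lag_error")
})

test_that("fast G(tau) equals the brute-force double loop", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(50:400, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(x) == 0) x[1] <- 1
    s <- state_series(x, dt = 0.1)
    ks <- sort(sample(0:(n %/% 3), 6))
    g <- fluorescence_autocorrelation(s, lags = ks * 0.1)
    expect_equal(g$values, brute_force_G(x, ks), tolerance = 1e-12)
    expect_true(all(diff(g$n_pairs) <= 0))
  }
})

test_that("symmetric telegraph matches the analytic 1 + exp(-2 k tau)", {
  k <- 1 / 10
  s <- gen_telegraph(k, k, dt = 0.1, n_steps = 2e6, seed = 21)
  lags <- seq(0, 40, by = 2)
  g <- fluorescence_autocorrelation(s, lags = lags)
  expect_lt(max(abs(g$values - markov_G(lags, k, k))), 0.05)
  # long-lag decay to 1
  gtail <- fluorescence_autocorrelation(s, lags = c(100, 150, 200))
  expect_lt(max(abs(gtail$values - 1)), 0.05)
})

test_that("mean-subtracted convention shifts G by one", {
  set.seed(4)
  s <- state_series(rbinom(300, 1, 0.5), dt = 0.1)
  a <- fluorescence_autocorrelation(s, lags = c(0, 0.5, 1))
  b <- fluorescence_autocorrelation(s, lags = c(0, 0.5, 1),
                                    mean_subtract = TRUE)
  expect_equal(a$values - 1, b$values, tolerance = 1e-12)
})

test_that("C(t) trivial identities and modes", {
  h <- hbond_matrix(matrix(1L, 50, 2), dt = 0.1)
  cv <- hbond_existence_autocorrelation(h, lags = c(0, 0.5, 2))
  expect_equal(cv$values, rep(1, 3))

  set.seed(5)
  h2 <- gen_hbond_series(1 / 4, 1 / 6, n_bonds = 4, dt = 0.1, n_steps = 400,
                         seed = 5)
  ci <- hbond_existence_autocorrelation(h2, lags = 0)
  cc <- hbond_existence_autocorrelation(h2, lags = 0, mode = "continuous")
  expect_equal(ci$values[1L], 1)
  expect_equal(cc$values[1L], 1)

  ccur <- hbond_existence_autocorrelation(h2, max_lag = 10,
                                          mode = "continuous")
  expect_true(all(diff(ccur$values) <= 1e-12))

  expect_error(hbond_existence_autocorrelation(
    hbond_matrix(matrix(0L, 10, 1), dt = 0.1)),
    class = "looplab_input_error")
})

test_that("fast C(t) equals the brute-force double loop in both modes", {
  set.seed(15)
  for (rep in 1:6) {
    h <- matrix(rbinom(60 * 3, 1, 0.6), 60, 3)
    if (!any(h == 1)) h[1, 1] <- 1L
    hm <- hbond_matrix(h, dt = 0.1)
    ks <- c(0L, 1L, 3L, 7L, 15L)
    ci <- hbond_existence_autocorrelation(hm, lags = ks * 0.1)
    cc <- hbond_existence_autocorrelation(hm, lags = ks * 0.1,
                                          mode = "continuous")
    expect_equal(ci$values, brute_force_C(h, ks, FALSE), tolerance = 1e-12)
    expect_equal(cc$values, brute_force_C(h, ks, TRUE), tolerance = 1e-12)
  }
})

test_that("Markov bonds relax as p + (1-p) exp(-(kb+kr) t)", {
  kb <- 1 / 5; kr <- 1 / 10
  h <- gen_hbond_series(kb, kr, n_bonds = 30, dt = 0.05, n_steps = 4e4,
                        seed = 16)
  lags <- seq(0, 20, by = 1)
  cv <- hbond_existence_autocorrelation(h, lags = lags)
  p <- kr / (kb + kr)
  expect_lt(max(abs(cv$values - (p + (1 - p) * exp(-(kb + kr) * lags)))), 0.03)
})

test_that("off-grid lags snap down with a warning", {
  s <- state_series(rep(c(1L, 0L, 1L, 1L), 25), dt = 0.1)
  expect_warning(g <- fluorescence_autocorrelation(s, lags = c(0, 0.15, 0.25)),
                 "snapped")
  expect_equal(g$lags, c(0, 0.1, 0.2), tolerance = 1e-9)
})
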