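make_curve <- function(K, tau_r, lags = c(0, lag_grid(0.5, 400,
                                                      include_zero = FALSE))) {
  corr_curve(lags, 1 + (1 / K) * exp(-lags / tau_r), kind = "fluorescence_G")
}

test_that("two-state fit recovers parameters from their own formula", {
  f <- fit_two_state(make_curve(K = 2, tau_r = 30), window = c(6, 300))
  expect_equal(f$K, 2, tolerance = 1e-6)
  expect_equal(f$tau_r, 30, tolerance = 1e-6)
  expect_equal(f$tau_c, 90, tolerance = 1e-5)   # tau_r (1 + K)
  expect_equal(f$tau_o, 45, tolerance = 1e-5)   # tau_c / K
  expect_gt(f$r_correlation, 0.999)
})

test_that("flat curves raise a no-relaxation error", {
  lags <- c(0, lag_grid(0.5, 400, include_zero = FALSE))
  flat <- corr_curve(lags, rep(1, length(lags)), kind = "fluorescence_G")
  expect_error(fit_two_state(flat, window = c(6, 300)),
               class = "looplab_no_relaxation_error")
})

test_that("reciprocal K convention is the documented switch", {
  f <- fit_two_state(make_curve(K = 2, tau_r = 30), window = c(6, 300),
                     k_convention = "closed_over_open")
  expect_equal(f$K, 0.5, tolerance = 1e-6)
})

test_that("derive_times implements the two-state algebra", {
  d <- derive_times(K = 1, tau_r = 10)
  expect_equal(d$tau_c, 20)
  expect_equal(d$tau_o, 20)
  expect_equal(d$fraction_open, 0.5)

  # inverting the printed nGS = 5 experimental row
  d2 <- derive_times(K = 0.4226804, tau_r = 14.40942)
  expect_equal(d2$tau_c, 20.5, tolerance = 1e-4)
  expect_equal(d2$tau_o, 48.5, tolerance = 1e-4)

  # algebraic round trip to 1e-12 and the 1/tau_r sum rule
  set.seed(31)
  for (i in 1:20) {
    K <- runif(1, 0.05, 20); tr <- runif(1, 0.5, 200)
    d3 <- derive_times(K, tr)
    back <- equilibrium_from_times(d3$tau_c, d3$tau_o)
    expect_equal(back$K, K, tolerance = 1e-12)
    expect_equal(back$tau_r, tr, tolerance = 1e-12)
    expect_equal(1 / d3$tau_c + 1 / d3$tau_o, 1 / tr, tolerance = 1e-9)
    expect_equal(d3$fraction_open, d3$tau_c / (d3$tau_c + d3$tau_o),
                 tolerance = 1e-12)
  }
  expect_error(derive_times(-1, 10), class = "looplab_parameter_error")
})

test_that("telegraph records round-trip through correlation and fit", {
  s <- gen_telegraph(1 / 50, 1 / 80, dt = 0.1, n_steps = 2e6, seed = 41)
  cv <- fluorescence_autocorrelation(s, max_lag = 300)
  f <- fit_two_state(cv, window = c(6, 300), series = s)
  expect_lt(abs(f$tau_c - 50) / 50, 0.1)
  expect_lt(abs(f$tau_o - 80) / 80, 0.1)
  expect_true(all(c("K", "tau_r", "tau_c", "tau_o") %in%
                    names(f$errors$split_half)))
})

test_that("multi-exponential fits recover a synthetic three-component sum", {
  t <- c(0, lag_grid(0.001, 200, points_per_decade = 40,
                     include_zero = FALSE))
  y <- 1 + 0.3 * exp(-(t / 0.05)^0.5) + 0.4 * exp(-t / 3) +
    0.4 * exp(-t / 40)
  cv <- corr_curve(t, y, kind = "fluorescence_G")
  f <- fit_multiexp(cv, n_exp = 2)
  expect_equal(f$stretched$tau_ps, 50, tolerance = 0.02)
  expect_equal(f$stretched$beta, 0.5, tolerance = 0.02)
  expect_equal(f$stretched$amplitude, 0.3, tolerance = 0.02)
  expect_equal(sort(f$exponentials$tau_ns), c(3, 40), tolerance = 0.02)
  expect_equal(f$exponentials$amplitude, c(0.4, 0.4), tolerance = 0.02)
  expect_false(f$quality_flag)
  # relative amplitudes in percent of G(0) - 1
  expect_equal(sum(unlist(f$amplitudes_relative)), 100, tolerance = 0.5)
})

test_that("a pure single exponential degrades gracefully (nested model)", {
  t <- c(0, lag_grid(0.001, 100, points_per_decade = 30,
                     include_zero = FALSE))
  y <- 1 + 0.5 * exp(-t / 8)
  cv <- corr_curve(t, y, kind = "fluorescence_G")
  f <- suppressMessages(fit_multiexp(cv, n_exp = 1))
  expect_equal(f$exponentials$tau_ns[1L], 8, tolerance = 0.05)
  # the stretched family collapses: either dropped or degenerate (beta ~ 1
  # duplicating the exponential, or negligible amplitude)
  if (!is.null(f$stretched))
    expect_true(f$stretched$amplitude < 0.05 * 0.5 ||
                  f$stretched$beta > 0.9)
})

test_that("auto model selection separates well-spaced ns relaxations", {
  t <- c(0, lag_grid(0.01, 400, points_per_decade = 30,
                     include_zero = FALSE))
  y2 <- 1 + 0.4 * exp(-t / 4) + 0.4 * exp(-t / 60)
  f2 <- suppressMessages(fit_multiexp(
    corr_curve(t, y2, kind = "fluorescence_G"), n_exp = "auto",
    stretched = FALSE))
  expect_equal(f2$n_exp, 2L)
  expect_equal(sort(f2$exponentials$tau_ns), c(4, 60), tolerance = 0.05)
})

test_that("hydrogen-bond lifetimes come from the nanosecond exponential", {
  # Markov bond fixture: relaxation time 1/(k_break + k_reform) = 10 ns
  h <- gen_hbond_series(1 / 20, 1 / 20, n_bonds = 20, dt = 0.05,
                        n_steps = 2e5, seed = 3)
  cv <- hbond_existence_autocorrelation(h, max_lag = 60)
  f <- fit_hbond_lifetime(cv)
  expect_lt(abs(f$lifetime_ns - 10) / 10, 0.1)

  # an always-intact bond has no relaxation
  expect_error(fit_hbond_lifetime(hbond_existence_autocorrelation(
    hbond_matrix(matrix(1L, 200, 2), dt = 0.1), max_lag = 5)),
    class = "looplab_no_relaxation_error")
})

test_that("two-population bonds: the slow ns process sets the lifetime", {
  fast <- gen_hbond_series(1 / 0.02, 1 / 0.02, n_bonds = 10, dt = 0.005,
                           n_steps = 6e5, seed = 9)
  slow <- gen_hbond_series(1 / 30, 1 / 30, n_bonds = 10, dt = 0.005,
                           n_steps = 6e5, seed = 10)
  hh <- hbond_matrix(cbind(unclass(fast), unclass(slow)), dt = 0.005)
  f <- fit_hbond_lifetime(hbond_existence_autocorrelation(hh, max_lag = 80))
  expect_lt(abs(f$lifetime_ns - 15) / 15, 0.15)
})

test_that("power-law fits match the generating law and closed-form OLS", {
  n <- c(8, 12, 16, 24, 30)
  # noiseless input: silence lm's "essentially perfect fit" notice
  f <- suppressWarnings(fit_powerlaw(n, n^-2))
  expect_equal(f$gamma, -2, tolerance = 1e-9)

  # three arbitrary points vs hand-computed normal equations
  n3 <- c(5, 11, 23); k3 <- c(2.1, 0.7, 0.31)
  x <- log(n3); y <- log(k3)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  f3 <- fit_powerlaw(n3, k3)
  expect_equal(f3$gamma, slope, tolerance = 1e-12)

  # scale equivariance: rescaling rates changes only the prefactor
  f4 <- fit_powerlaw(n3, 7.3 * k3)
  expect_equal(f4$gamma, f3$gamma, tolerance = 1e-12)
  expect_equal(f4$prefactor, 7.3 * f3$prefactor, tolerance = 1e-9)

  expect_error(fit_powerlaw(c(4, 6), c(1, 2)), class = "looplab_input_error")
  expect_error(fit_powerlaw(n3, k3, n_min = 20), class = "looplab_input_error")
})

test_that("weighted power-law fits honour the supplied rate errors", {
  n <- c(10, 14, 18, 24, 30)
  k <- n^-1.4 * exp(c(0.02, -0.01, 0.03, 0, -0.02))
  err <- 0.1 * k
  fw <- fit_powerlaw(n, k, errors = err, weighted = TRUE)
  fu <- fit_powerlaw(n, k)
  expect_true(is.finite(fw$gamma))
  expect_lt(abs(fw$gamma - fu$gamma), 0.2)
  expect_true(fw$weighted)
})

test_that("split-half errors follow the two-point standard deviation", {
  x <- c(rep(10, 50), rep(12, 50))
  sh <- split_half_errors(x, mean)
  expect_equal(as.numeric(sh), sqrt(2), tolerance = 1e-12)
  # identical halves: zero
  sh0 <- split_half_errors(rep(3.5, 40), mean)
  expect_equal(as.numeric(sh0), 0)
  # telegraph: the split-half scale agrees with the spread of independent
  # half-length replicas within a factor 2 (averaging several split-half
  # draws to tame the chi_1 noise of a single |a - b|)
  reps <- vapply(1:20, function(i)
    mean(gen_telegraph(1 / 20, 1 / 20, dt = 0.1, n_steps = 5e4,
                       seed = 500 + i)$states), numeric(1L))
  sh2 <- vapply(1:10, function(i) {
    s <- gen_telegraph(1 / 20, 1 / 20, dt = 0.1, n_steps = 1e5,
                       seed = 600 + i)
    unname(split_half_errors(s, function(h) mean(h$states)))
  }, numeric(1L))
  ratio <- sqrt(mean(sh2^2)) / sd(reps)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("fits flag (not reject) low correlation coefficients", {
  set.seed(77)
  t <- c(0, lag_grid(0.01, 50, include_zero = FALSE))
  y <- 1 + 0.2 * exp(-t / 5) + rnorm(length(t), sd = 0.25)
  cv <- corr_curve(t, pmax(y, 0.01), kind = "fluorescence_G")
  f <- tryCatch(suppressMessages(suppressWarnings(
    fit_multiexp(cv, n_exp = 1, stretched = FALSE))),
    looplab_error = function(e) NULL)
  if (!is.null(f)) expect_true(f$quality_flag)
})
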