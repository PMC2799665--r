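test_that("uniform samples give a flat profile within the noise envelope", {
  set.seed(50)
  u <- runif(2e5)
  p <- fe_profile(u, bin_width = 0.02)
  keep <- p$counts > 0 & p$bin_centers > 0.02 & p$bin_centers < 0.98
  F <- p$F[keep]
  sig <- kB_kJ_mol_K * p$temperature / sqrt(p$counts[keep])
  expect_true(all(abs(F - mean(F)) <= 3.5 * sig))
})

test_that("the Gaussian-chain mode is recovered", {
  set.seed(51)
  N <- 10; b <- 0.38
  r <- sqrt(rowSums(matrix(rnorm(3 * 3e5, sd = sqrt(N * b^2 / 3)),
                           ncol = 3)^2))
  p <- fe_profile(r)
  expect_lt(abs(profile_minimum(p) / sqrt(2 * N * b^2 / 3) - 1), 0.05)
})

test_that("free energy scales linearly with temperature", {
  set.seed(52)
  x <- rnorm(5e4, 1, 0.2)
  p1 <- fe_profile(x, temperature = 293)
  p2 <- fe_profile(x, temperature = 586)
  ok <- !is.na(p1$F)
  expect_equal(p2$F[ok], 2 * p1$F[ok], tolerance = 1e-9)
})

test_that("degenerate and near-empty inputs are rejected", {
  expect_error(fe_profile(rep(0.4, 100)),
               class = "looplab_degenerate_profile_error")
  expect_warning(fe_profile(runif(50)), "noisy")
})

test_that("barriers of an analytic double well are located exactly", {
  x <- seq(-1.6, 1.6, by = 0.02)
  F <- (x^2 - 1)^2
  prof <- structure(list(bin_centers = x, F = F - min(F),
                         counts = rep(1000L, length(x)), temperature = 293,
                         bin_width = 0.02, n_samples = 1e5, jacobian = FALSE),
                    class = "fe_profile")
  b <- find_barrier(prof, smooth_bins = 1L)
  expect_equal(b$r_min_closed, -1, tolerance = 0.03)
  expect_equal(b$r_barrier, 0, tolerance = 0.03)
  expect_equal(b$r_min_open, 1, tolerance = 0.03)
  expect_equal(b$dF_opening, 1, tolerance = 0.05)
  expect_equal(select_cutoff(prof, smooth_bins = 1L), b$r_barrier)
})

test_that("single-well profiles raise a no-barrier error", {
  set.seed(53)
  p <- fe_profile(rnorm(2e4, 1, 0.1))
  expect_error(find_barrier(p), class = "looplab_no_barrier_error")
})

test_that("the selected cutoff is robust to 10% resampling", {
  set.seed(54)
  x <- c(rnorm(3e4, 0.4, 0.08), rnorm(6e4, 0.95, 0.18))
  p <- fe_profile(x)
  cut0 <- select_cutoff(p)
  for (i in 1:5) {
    idx <- sample(length(x), round(0.1 * length(x)))
    x2 <- x
    x2[idx] <- sample(x, length(idx), replace = TRUE)
    expect_lt(abs(select_cutoff(fe_profile(x2)) - cut0), 0.02 + 1e-9)
  }
})

test_that("labelled/unlabelled default cutoffs are the documented constants", {
  expect_equal(unname(gs_cutoffs["labelled"]), 0.45)
  expect_equal(unname(gs_cutoffs["unlabelled"]), 0.58)
})

test_that("attraction lowers the free-energy cost of reaching contact", {
  kBT <- kB_kJ_mol_K * 293
  cost <- function(eps, seed) {
    run <- gen_chain_trajectory(n_beads = 12, n_steps = 1e6, seed = seed,
                                attraction_eps = eps)
    p <- fe_profile(run$distances)
    near <- which(p$bin_centers <= 0.45 & !is.na(p$F))
    expect_gt(length(near), 0)
    min(p$F[near])  # height of the contact region above the global minimum
  }
  for (seed in c(60, 61, 62)) {
    expect_lt(cost(2 * kBT, seed), cost(0, seed))
  }
  # the phantom chain's entropic profile has no interior barrier
  run0 <- gen_chain_trajectory(n_beads = 12, n_steps = 1e6, seed = 63)
  expect_error(find_barrier(fe_profile(run0$distances)),
               class = "looplab_no_barrier_error")
})

test_that("Jacobian correction shifts the minimum inward", {
  set.seed(55)
  N <- 10; b <- 0.38
  r <- sqrt(rowSums(matrix(rnorm(3 * 2e5, sd = sqrt(N * b^2 / 3)),
                           ncol = 3)^2))
  p_raw <- fe_profile(r)
  p_jac <- fe_profile(r, jacobian = TRUE)
  expect_lt(profile_minimum(p_jac), profile_minimum(p_raw))
})
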