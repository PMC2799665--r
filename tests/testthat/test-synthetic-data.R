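test_that("telegraph stationary occupancy matches the two-state Markov law", {
  # symmetric rates: time-average ~ 1/2
  s <- gen_telegraph(k_close = 0.2, k_open = 0.2, dt = 0.1, n_steps = 2e5,
                     seed = 1)
  expect_lt(abs(mean(s$states) - 0.5), 0.02)

  # rates from the labelled nGS = 5 peptide (tau_c = 20.5, tau_o = 48.5 ns)
  s2 <- gen_telegraph(k_close = 1 / 20.5, k_open = 1 / 48.5, dt = 0.1,
                      n_steps = 1e6, seed = 2)
  expect_lt(abs(mean(s2$states) - 20.5 / (20.5 + 48.5)), 0.02)
})

test_that("telegraph absorbing states and degenerate inputs behave", {
  s <- gen_telegraph(k_close = 0.5, k_open = 0, dt = 0.1, n_steps = 1000,
                     seed = 1, initial_state = "closed")
  expect_true(all(s$states == 0L))
  s2 <- gen_telegraph(k_close = 0, k_open = 0.5, dt = 0.1, n_steps = 1000,
                      seed = 1, initial_state = "open")
  expect_true(all(s2$states == 1L))
  expect_error(gen_telegraph(0, 0, 0.1, 100), class = "looplab_parameter_error")
  expect_error(gen_telegraph(1, 1, -1, 100), class = "looplab_parameter_error")
  expect_error(gen_telegraph(1, 1, 0.1, 1), class = "looplab_parameter_error")
})

test_that("fixed seed reproduces the telegraph bit for bit", {
  a <- gen_telegraph(1 / 50, 1 / 80, dt = 0.1, n_steps = 5e4, seed = 99)
  b <- gen_telegraph(1 / 50, 1 / 80, dt = 0.1, n_steps = 5e4, seed = 99)
  expect_identical(a$states, b$states)
})

test_that("telegraph dwell times are exponential (KS at alpha = 0.01)", {
  s <- gen_telegraph(k_close = 0.1, k_open = 0.1, dt = 0.1, n_steps = 1e6,
                     seed = 7)
  dw <- dwell_times(s)
  set.seed(8)
  for (d in list(dw$open, dw$closed)) {
    expect_gt(length(d), 1000)
    # dequantize the dt-gridded durations so the KS null is continuous
    d <- d + runif(length(d), -0.05, 0.05)
    p <- ks.test(d, "pexp", rate = 1 / mean(d))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("hydrogen-bond series follow the prescribed on/off statistics", {
  h <- gen_hbond_series(k_break = 0, k_reform = 0.5, n_bonds = 3, dt = 0.1,
                        n_steps = 500, seed = 1, initial_state = "open")
  expect_true(all(unclass(h) == 1L))

  h2 <- gen_hbond_series(k_break = 1 / 5, k_reform = 1 / 10, n_bonds = 10,
                         dt = 0.05, n_steps = 1e5, seed = 3)
  # stationary intact fraction: k_reform / (k_break + k_reform)
  expect_lt(abs(mean(h2) - (1 / 10) / (1 / 5 + 1 / 10)), 0.02)
  # intact dwell mean ~ 1/k_break
  d <- dwell_times(state_series(unclass(h2)[, 1L], dt = 0.05))
  expect_lt(abs(d$mean_open - 5) / 5, 0.15)
})

test_that("zero-temperature chains with equilibrium bonds do not move", {
  run <- gen_chain_trajectory(n_beads = 5, temperature = 0, n_steps = 2000,
                              seed = 4, distance_stride = 10,
                              equilibration_steps = 0)
  expect_lt(diff(range(run$distances$values)), 1e-9)
})

test_that("chain connectivity is conserved", {
  run <- gen_chain_trajectory(n_beads = 8, n_steps = 5e4, seed = 5,
                              frame_stride = 1000)
  for (m in seq_len(dim(run$trajectory$coords)[1L])) {
    xyz <- run$trajectory$coords[m, , ]
    bl <- sqrt(rowSums((xyz[-1L, ] - xyz[-nrow(xyz), ])^2))
    expect_lt(max(bl), 1.5 * 0.38)
  }
})

test_that("phantom chain reproduces freely-jointed end-to-end statistics", {
  run <- gen_chain_trajectory(n_beads = 10, n_steps = 5e6, seed = 6,
                              distance_stride = 100)
  r2 <- mean(run$distances$values^2)
  expect_lt(abs(r2 / (9 * 0.38^2) - 1), 0.05)
  set.seed(11)
  r2_mc <- random_walk_r2(10, 0.38, 2e4)
  expect_lt(abs(r2 / r2_mc - 1), 0.06)
})

test_that("chain runs are reproducible under a fixed seed", {
  a <- gen_chain_trajectory(n_beads = 6, n_steps = 1e4, seed = 12)
  b <- gen_chain_trajectory(n_beads = 6, n_steps = 1e4, seed = 12)
  expect_identical(a$distances$values, b$distances$values)
})

test_that("generator parameters echo into a JSON sidecar", {
  run <- gen_chain_trajectory(n_beads = 5, n_steps = 1000, seed = 1)
  f <- tempfile(fileext = ".json")
  write_params_json(run$params, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$n_beads, 5)
  expect_equal(back$temperature, 293)
})
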