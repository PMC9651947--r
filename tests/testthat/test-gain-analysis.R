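test_that("surround speed tuning normalizes to the static-background mean", {
  amps <- matrix(rep(2, 40), 40, 2)
  speeds <- rep(c(0, 40, 80, 160), each = 10)
  tc <- surround_speed_tuning(amps, speeds)
  expect_true(all(tc$y == 1))
  expect_identical(tc$x, c(0, 40, 80, 160))
  expect_error(surround_speed_tuning(amps, rep(c(20, 40), each = 20)),
               "speed-0")
  expect_error(surround_speed_tuning(matrix(0, 20, 1), rep(c(0, 40), 10)),
               "zero reference")
})

test_that("surround speed tuning recovers an injected suppression profile", {
  s_true <- c(1, 0.8, 0.5, 0.3)
  speeds_grid <- c(0, 40, 160, 320)
  set.seed(1)
  n_per <- 40
  speeds <- rep(speeds_grid, each = n_per)
  mu <- rep(s_true, each = n_per)
  amps <- cbind(mu * stats::rlnorm(length(mu), -0.02, 0.2))
  tc <- surround_speed_tuning(amps, speeds)
  expect_true(all(abs(tc$y[, 1] - s_true) <= 2 * pmax(tc$sem[, 1], 0.02) + 0.05))
  # monotone injected suppression comes out monotone
  expect_true(all(diff(tc$y[, 1]) < 0))
})

test_that("gain versus walking is flat for a behavior-independent generator", {
  tun <- generate_tuning(8, 4, 2, seed = 2)
  gen <- generate_trials(tun, 60, gain_sd = 0.2, noise_sd = 0.02,
                         behavior_coupling = 0, seed = 3)
  amps <- peak_amplitudes(gen$tensor)
  tc <- suppressMessages(gain_vs_walking(amps, gen$tensor$behavior_amplitude))
  expect_true(all(abs(tc$y - 1) < 0.15))
})

test_that("gain versus walking decreases under negative coupling", {
  tun <- generate_tuning(8, 1, 1, seed = 4)
  gen <- generate_trials(tun, 200, gain_sd = 0.2, noise_sd = 0.02,
                         behavior_coupling = -1, modulated = 1:8, seed = 5)
  amps <- peak_amplitudes(gen$tensor)
  tc <- suppressMessages(gain_vs_walking(amps, gen$tensor$behavior_amplitude))
  expect_lt(stats::cor(tc$x, tc$y, method = "spearman"), 0)
  # single occupied bin degenerates gracefully
  tc1 <- suppressMessages(gain_vs_walking(amps, rep(1, 200),
                                          bin_edges = c(0, 2)))
  expect_identical(length(tc1$y), 1L)
})

test_that("saccade-timing gain recovers a planted suppression dip", {
  sim <- simulate_saccade_timing(n_trials_per_offset = 60, depth = 0.5,
                                 seed = 6)
  tc <- saccade_timing_gain(sim$amplitude, sim$offset)
  at0 <- which(tc$x == 0)
  expect_equal(tc$y[at0, 1], 0.5, tolerance = 2 * tc$sem[at0, 1] + 0.03)
  far <- abs(tc$x) > 0.5
  expect_true(all(abs(tc$y[far, 1] - 1) < 0.15))
  # offset-independent data sit flat at 1
  flat <- simulate_saccade_timing(depth = 0, seed = 7)
  tcf <- saccade_timing_gain(flat$amplitude, flat$offset)
  expect_true(all(abs(tcf$y - 1) < 0.15))
  expect_error(saccade_timing_gain(sim$amplitude, sim$offset * 0), "reference")
})

test_that("independence test covers zero under multiplicative gains", {
  sim <- simulate_gain_experiment(8, 50, interaction = 0, seed = 8)
  res <- independence_test(sim$data, seed = 9)
  expect_true(all(res$predicted == res$g_visual * res$g_behavior))
  expect_gte(mean(res$ci_lo <= 0 & res$ci_hi >= 0), 0.75)
  # trivial case: unit marginal gains predict 1
  d <- data.frame(
    glomerulus = "g", visual = rep(c(FALSE, TRUE, FALSE, TRUE), each = 5),
    walking = rep(c(FALSE, FALSE, TRUE, TRUE), each = 5),
    amplitude = rep(1, 20))
  r1 <- independence_test(d, n_boot = 50, seed = 1)
  expect_equal(r1$predicted, 1)
  expect_equal(r1$deviation, 0)
})

test_that("independence test detects an injected interaction", {
  sim <- simulate_gain_experiment(8, 50, interaction = 0.3, seed = 10)
  res <- independence_test(sim$data, seed = 11)
  expect_gte(mean(res$ci_lo > 0 | res$ci_hi < 0), 0.8)
})

test_that("independence deviations shrink with trial count", {
  mean_abs_dev <- vapply(c(20, 100, 500), function(n) {
    sim <- simulate_gain_experiment(6, n, interaction = 0, seed = 12)
    res <- independence_test(sim$data, n_boot = 100, seed = 13)
    mean(abs(res$deviation))
  }, numeric(1))
  expect_true(mean_abs_dev[3] < mean_abs_dev[1])
})

test_that("gain quantities are invariant to global amplitude scaling", {
  sim <- simulate_gain_experiment(4, 30, seed = 14)
  r1 <- independence_test(sim$data, n_boot = 100, seed = 15)
  scaled <- sim$data; scaled$amplitude <- scaled$amplitude * 7.3
  r2 <- independence_test(scaled, n_boot = 100, seed = 15)
  expect_equal(r1$deviation, r2$deviation, tolerance = 1e-12)
  amps <- matrix(stats::runif(40, 1, 2), 40, 1)
  speeds <- rep(c(0, 40), each = 20)
  expect_equal(surround_speed_tuning(amps, speeds)$y,
               surround_speed_tuning(amps * 5, speeds)$y, tolerance = 1e-12)
})

test_that("independence test names missing condition cells", {
  d <- data.frame(glomerulus = "g", visual = c(FALSE, TRUE),
                  walking = c(FALSE, FALSE), amplitude = c(1, 1))
  expect_error(independence_test(d), "beh, both")
})
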