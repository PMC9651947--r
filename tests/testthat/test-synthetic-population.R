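test_that("tuning generator produces recoverable group structure", {
  skip_if_not_installed("mclust")
  tun <- generate_tuning(13, 12, 4, seed = 1)
  cl <- cluster_tuning(tun, 4)
  expect_gt(mclust::adjustedRandIndex(cl$labels, tun$group_labels), 0.9)
})

test_that("tuning generator is deterministic and validates inputs", {
  a <- generate_tuning(8, 6, 2, seed = 3)
  b <- generate_tuning(8, 6, 2, seed = 3)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0))
  expect_identical(anyDuplicated(a$glomerulus_names), 0L)
  expect_error(generate_tuning(4, 2, 5), "n_groups")
  expect_error(generate_tuning(6, 2, 4), "n_stimuli")
  one <- generate_tuning(5, 4, 1, seed = 2)
  expect_true(all(one$group_labels == 1))
})

test_that("noiseless unit-gain trials peak exactly at their tuning entry", {
  tun <- generate_tuning(6, 4, 2, seed = 5)
  gen <- generate_trials(tun, 5, gain_sd = 0, noise_sd = 0, seed = 6)
  amps <- peak_amplitudes(gen$tensor)
  idx <- match(gen$tensor$labels, tun$stimulus_names)
  expect_equal(t(amps$values), tun$values[, idx], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("shared gain induces strong positive trial correlations", {
  tun <- generate_tuning(13, 10, 4, seed = 1)
  gen <- generate_trials(tun, 30, gain_sd = 0.4, noise_sd = 0.01, seed = 2)
  cm <- trial_correlations(peak_amplitudes(gen$tensor))
  expect_gt(mean(cm$values[upper.tri(cm$values)]), 0.5)
})

test_that("negative behavior coupling yields negative amplitude-behavior rho", {
  mean_rho <- vapply(1:10, function(s) {
    tun <- generate_tuning(6, 1, 1, seed = s)
    gen <- generate_trials(tun, 60, gain_sd = 0.3, noise_sd = 0.05,
                           behavior_coupling = -1, modulated = 1:3,
                           seed = 500 + s)
    amps <- peak_amplitudes(gen$tensor)
    rho <- behavior_correlation(amps, gen$tensor$behavior_amplitude)
    mean(rho[1:3])
  }, numeric(1))
  expect_true(all(mean_rho < 0))
})

test_that("with zero coupling, behavior and amplitudes are independent", {
  mean_rho <- vapply(1:20, function(s) {
    tun <- generate_tuning(6, 4, 2, seed = s)
    gen <- generate_trials(tun, 25, gain_sd = 0.4, noise_sd = 0.02,
                           behavior_coupling = 0, seed = 900 + s)
    amps <- peak_amplitudes(gen$tensor)
    mean(behavior_correlation(amps, gen$tensor$behavior_amplitude))
  }, numeric(1))
  expect_gte(mean(abs(mean_rho) < 0.15), 0.95)
})

test_that("noise-free zero-coupling amplitudes are rank one per stimulus", {
  tun <- generate_tuning(8, 4, 2, seed = 4)
  gen <- generate_trials(tun, 10, gain_sd = 0.4, noise_sd = 0, seed = 5)
  amps <- peak_amplitudes(gen$tensor)
  for (s in unique(amps$labels)) {
    m <- amps$values[amps$labels == s, , drop = FALSE]
    sv <- svd(m)$d
    expect_lt(sv[2] / sv[1], 1e-10)
  }
})

test_that("walking generator honors refractoriness and saccade timing stats", {
  w <- generate_walking(300, saccade_rate_hz = 0.8, refractory_s = 0.5,
                        seed = 1)
  iti <- diff(w$saccade_times)
  expect_true(all(iti >= 0.5))
  h <- graphics::hist(iti, breaks = seq(0, ceiling(max(iti)), 0.25),
                      plot = FALSE)
  mode_at <- h$mids[which.max(h$counts)]
  expect_gte(mode_at, 0.5)
  expect_lte(mode_at, 2)
  expect_true(all(w$saccade_peaks > 160))
  # amplitude is the pointwise norm of the three axes
  expect_equal(w$trace$amplitude,
               sqrt(w$trace$rot_x^2 + w$trace$rot_y^2 + w$trace$rot_z^2))
})

test_that("near-zero saccade rate produces a quiescent angular trace", {
  w <- generate_walking(60, saccade_rate_hz = 0.02, refractory_s = 0.5,
                        seed = 2)
  ev <- detect_saccades(w$trace$rot_z, dt = 0.02)
  expect_lte(length(ev$onset_times), length(w$saccade_times))
  expect_lte(length(w$saccade_times), 3)
})

test_that("infeasible renewal parameters are rejected", {
  expect_error(generate_walking(60, saccade_rate_hz = 3, refractory_s = 0.5),
               "infeasible")
  expect_error(generate_walking(60, saccade_rate_hz = 0), "rate")
  expect_error(generate_trials(generate_tuning(4, 4, 2), noise_sd = -1),
               "noise_sd")
})

test_that("heading integrates angular velocity in the trajectory", {
  w <- generate_walking(30, seed = 3)
  expect_equal(w$trajectory$heading,
               cumsum(w$trajectory$angular_velocity * 0.02))
})
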