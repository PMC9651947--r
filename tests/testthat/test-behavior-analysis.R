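test_that("walking amplitude is the pointwise rotation-vector norm", {
  expect_identical(walking_amplitude(0, 0, 0), 0)
  expect_identical(walking_amplitude(3, 4, 0), 5)
  set.seed(1)
  x <- stats::rnorm(50); y <- stats::rnorm(50); z <- stats::rnorm(50)
  a <- walking_amplitude(x, y, z)
  expect_equal(a, vapply(1:50, function(i) sqrt(sum(c(x[i], y[i], z[i])^2)),
                         numeric(1)))
  # invariant to axis sign flips and permutations
  expect_equal(walking_amplitude(-x, y, -z), a)
  expect_equal(walking_amplitude(z, x, y), a)
  expect_error(walking_amplitude(1:3, 1:2, 1:3), "equal lengths")
})

test_that("Li threshold equals the exhaustive-scan minimizer", {
  set.seed(2)
  for (i in 1:50) {
    v <- c(stats::rlnorm(sample(20:60, 1), log(2), 0.5),
           stats::rlnorm(sample(20:60, 1), log(30), 0.5))
    expect_identical(li_threshold(v), oracle_li_threshold(v))
  }
})

test_that("Li threshold separates bimodal data and scales with its input", {
  v <- c(rep(0.1, 100), rep(10, 100))
  thr <- li_threshold(v)
  expect_gt(thr, 0.1)
  expect_lt(thr, 10)
  set.seed(3)
  v2 <- stats::rlnorm(200, log(5), 1)
  for (c_scale in c(0.5, 3.7)) {
    expect_equal(li_threshold(c_scale * v2), c_scale * li_threshold(v2),
                 tolerance = 1e-12)
  }
  expect_error(li_threshold(rep(2, 10)), "identical")
  expect_error(li_threshold(c(-1, 2)), ">= 0")
})

test_that("behaving classification applies the 25% rule inclusively", {
  amp <- c(rep(0.1, 60), rep(10, 20), rep(0.1, 20))
  windows <- list(c(1, 40), c(61, 80), c(41, 60))
  bc <- classify_behaving(amp, windows)
  expect_identical(bc$behaving, c(FALSE, TRUE, FALSE))
  # exactly 25% above threshold is flagged (>= rule)
  amp2 <- c(rep(0.1, 30), rep(10, 10), rep(0.1, 120), rep(10, 40))
  bc2 <- classify_behaving(amp2, list(c(1, 40)))
  expect_equal(bc2$fraction_above, 0.25)
  expect_true(bc2$behaving)
  expect_error(classify_behaving(amp, list(c(90, 200))), "window")
})

test_that("behaving trials match generated walking bouts", {
  # ball-measured saccade amplitudes (attenuated relative to free walking)
  w <- generate_walking(300, seed = 4, saccade_amp_range = c(60, 120))
  n <- length(w$trace$amplitude)
  starts <- seq(1, n - 100, by = 100)
  windows <- lapply(starts, function(s) c(s, s + 99))
  bc <- classify_behaving(w$trace$amplitude, windows)
  frac <- vapply(starts, function(s) {
    mean(w$walking_bout[s:(s + 99)])
  }, numeric(1))
  # evaluate away from the 25% decision boundary, where the label is
  # genuinely ambiguous
  clear <- abs(frac - 0.25) > 0.1
  expect_gte(mean((bc$behaving == (frac >= 0.25))[clear]), 0.95)
})

test_that("saccade detection finds clean pulses at their onsets", {
  dt <- 0.01
  v <- numeric(1000)
  onsets_idx <- c(100, 400, 800)
  for (o in onsets_idx) v[o:(o + 20)] <- 300 * sin(pi * (0:20) / 20)
  ev <- detect_saccades(v, dt)
  expect_identical(length(ev$onset_times), 3L)
  expect_true(all(abs(ev$onset_times - (onsets_idx - 1) * dt) <= dt + 1e-9))
  expect_true(all(ev$peak_speeds >= 290))
  # all sub-threshold: empty
  expect_identical(length(detect_saccades(v * 0.1, dt)$onset_times), 0L)
  expect_error(detect_saccades(v, dt, speed_threshold = -1), "threshold")
})

test_that("saccade detection is robust to sub-threshold noise", {
  dt <- 0.01
  v <- numeric(1000)
  for (o in c(100, 400, 800)) v[o:(o + 20)] <- 300 * sin(pi * (0:20) / 20)
  clean <- detect_saccades(v, dt)
  set.seed(5)
  noisy <- v + stats::runif(1000, -40, 40) # < threshold / 4
  got <- detect_saccades(noisy, dt)
  expect_identical(length(got$onset_times), length(clean$onset_times))
  expect_true(all(abs(got$onset_times - clean$onset_times) <= 0.1))
})

test_that("generator saccades are recovered accurately", {
  w <- generate_walking(300, seed = 6)
  ev <- detect_saccades(w$trace$rot_z, dt = 0.02)
  recall <- mean(vapply(w$saccade_times, function(on) {
    any(abs(ev$onset_times - on) <= 0.05)
  }, logical(1)))
  false_frac <- mean(vapply(ev$onset_times, function(on) {
    !any(abs(w$saccade_times - on) <= 0.05)
  }, logical(1)))
  expect_gte(recall, 0.95)
  expect_lte(false_frac, 0.05)
  expect_lt(mean(ev$inter_turn_intervals < 0.5), 0.02)
})

test_that("saccade-cycle statistics partition the locomotor cycle", {
  dt <- 0.02
  v <- numeric(500)
  onsets_idx <- seq(51, 451, by = 50) # every 1 s
  for (o in onsets_idx) v[o:(o + 9)] <- 250
  ev <- detect_saccades(v, dt)
  st <- saccade_cycle_stats(ev, v, rep(5, 500), dt)
  expect_true(all(abs(st$iti - 1) < 1e-9))
  expect_gt(mean(st$peri$angular_speed), mean(st$inter$angular_speed))
  # fewer than two events: empty, flagged
  st0 <- saccade_cycle_stats(detect_saccades(v * 0, dt), v * 0,
                             rep(5, 500), dt)
  expect_true(st0$iti_empty)
})

test_that("forward velocity is independent of the saccade cycle", {
  pvals <- vapply(1:10, function(s) {
    w <- generate_walking(300, seed = s)
    ev <- detect_saccades(w$trace$rot_z, dt = 0.02)
    fv <- w$trajectory$forward_velocity
    tt <- w$trace$time
    # subsample at event resolution to break sample autocorrelation
    peri_v <- fv[findInterval(ev$onset_times, tt)]
    mids <- utils::head(ev$onset_times, -1) + ev$inter_turn_intervals / 2
    inter_v <- fv[findInterval(mids, tt)]
    suppressWarnings(stats::ks.test(peri_v, inter_v)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("FicTrac-style CSV import reconstructs a walking trace", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(rot_x = c(1, 2), rot_y = c(2, 3), rot_z = c(2, 6))
  utils::write.csv(df, tmp, row.names = FALSE)
  tr <- read_fictrac_csv(tmp)
  expect_equal(tr$amplitude, c(3, 7))
  expect_error(read_fictrac_csv({
    utils::write.csv(data.frame(a = 1), tmp, row.names = FALSE); tmp
  }), "rot_x")
})
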