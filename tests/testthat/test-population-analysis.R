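make_amps <- function(values, labels) amplitude_matrix(values, labels)

test_that("dF/F conversion matches the direct formula", {
  set.seed(1)
  raw <- array(stats::runif(3 * 4 * 20, 0.5, 2), c(3, 4, 20))
  time <- seq(-1.5, 4, length.out = 20)
  dff <- compute_dff(raw, time, c(-1.5, 0))
  pre <- which(time >= -1.5 & time <= 0)
  for (g in 1:3) for (tr in 1:4) {
    f0 <- mean(raw[g, tr, pre])
    expect_equal(dff[g, tr, ], (raw[g, tr, ] - f0) / f0, tolerance = 1e-12)
  }
  # constant F = F0 gives identically zero; doubling gives 1
  const <- array(2, c(1, 1, 20))
  expect_true(all(compute_dff(const, time) == 0))
  dbl <- const; dbl[1, 1, 15] <- 4
  expect_equal(compute_dff(dbl, time)[1, 1, 15], 1)
  bad <- const; bad[1, 1, 1:5] <- -3
  expect_error(compute_dff(bad, time), "glomerulus 1, trial 1")
})

test_that("peak amplitudes take the window maximum", {
  time <- seq(-1, 3, by = 0.25)
  dff <- array(0, c(2, 3, length(time)))
  dff[1, 1, ] <- seq_along(time) # monotone: peak at window end
  tens <- trial_tensor(dff, time, labels = c("a", "b", "a"),
                       epoch = c(1, 3, 0))
  am <- peak_amplitudes(tens, c(0, 3))
  expect_equal(unname(am$values[1, 1]), max(dff[1, 1, time >= 0]))
  expect_true(all(am$values[, 2] == 0))
  expect_error(peak_amplitudes(tens, c(10, 12)), "window")
})

test_that("trial correlations are symmetric, unit-diagonal, and exact for duplicates", {
  set.seed(2)
  x <- matrix(stats::rnorm(60), 20, 3)
  x[, 3] <- x[, 1] # duplicated glomerulus
  cm <- trial_correlations(make_amps(x, rep("s1", 20)))
  expect_equal(cm$values, t(cm$values))
  expect_true(all(diag(cm$values) == 1))
  expect_equal(cm$values[1, 3], 1)
  # independent columns at 30 trials mostly stay below |r| = 0.35
  set.seed(3)
  xs <- matrix(stats::rnorm(30 * 8), 30, 8)
  cm2 <- trial_correlations(make_amps(xs, rep("s1", 30)))
  off <- abs(cm2$values[upper.tri(cm2$values)])
  expect_gt(mean(off < 0.35), 0.85)
  expect_error(trial_correlations(make_amps(x[1:2, ], rep("s1", 2))), "3 trials")
})

test_that("zero-variance glomeruli are excluded from correlation averages", {
  x <- cbind(stats::rnorm(10), rep(1, 10), stats::rnorm(10))
  expect_warning(cm <- trial_correlations(make_amps(x, rep("s", 10))),
                 "zero-variance")
  # the degenerate glomerulus's correlations stay undefined; the rest are
  # intact
  expect_true(all(is.na(cm$values[2, -2])))
  expect_true(all(is.finite(cm$values[-2, -2])))
  expect_true(all(diag(cm$values) == 1))
})

test_that("complete-linkage clustering recovers separated templates", {
  t1 <- c(1, 1, 0, 0); t2 <- c(0, 0, 1, 1)
  rows <- rbind(t1 + 0.01, t1 - 0.01, t1, t2 + 0.01, t2 - 0.01)
  cl <- cluster_tuning(rows, 2)
  expect_identical(length(unique(cl$labels[1:3])), 1L)
  expect_identical(length(unique(cl$labels[4:5])), 1L)
  expect_false(cl$labels[1] == cl$labels[4])
  # n_clusters = n rows: singletons; permutation invariance of the partition
  expect_identical(sort(unname(cluster_tuning(rows, 5)$labels)), 1:5)
  perm <- c(3, 5, 1, 2, 4)
  cl_p <- cluster_tuning(rows[perm, ], 2)
  expect_identical(cl_p$labels[order(perm)] == cl_p$labels[order(perm)][1],
                   cl$labels == cl$labels[1])
  expect_error(cluster_tuning(rbind(c(1, NA))), "NA")
})

test_that("shared gain recovers a planted rank-one gain factor", {
  set.seed(4)
  g_t <- stats::rlnorm(90, 0, 0.4)
  tuningvec <- stats::runif(7, 0.5, 1.5)
  labels <- rep(c("a", "b", "c"), each = 30)
  stim_scale <- c(a = 1, b = 2, c = 0.5)[labels]
  x <- (g_t * stim_scale) %o% tuningvec
  sg <- shared_gain(make_amps(x, labels))
  expect_gt(sg$var_explained, 0.99)
  expect_gt(stats::cor(sg$score, g_t * stim_scale -
                         stats::ave(g_t * stim_scale, labels)), 0.99)
  # orientation convention: loadings have positive mean even if all
  # responses are negated
  sg_neg <- shared_gain(make_amps(-x, labels))
  expect_gt(mean(sg_neg$loadings), 0)
})

test_that("shared gain on isotropic noise explains about 1/G variance", {
  ve <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(stats::rnorm(200 * 10), 200, 10)
    shared_gain(make_amps(x, rep("s", 200)))$var_explained
  }, numeric(1))
  # the leading sample eigenvalue of a 200 x 10 noise matrix sits between
  # the naive 1/G and the Marchenko-Pastur bulk edge (1 + sqrt(G/T))^2 / G
  expect_gt(mean(ve), 1 / 10)
  expect_lt(mean(ve), (1 + sqrt(10 / 200))^2 / 10)
  expect_error(shared_gain(make_amps(matrix(1:4, 2, 2), c("a", "b"))), "3 trials")
})

test_that("behavior correlation hits -1 for perfectly anticorrelated traces", {
  amp <- matrix(seq(1, 2, length.out = 30), 30, 1)
  rho <- behavior_correlation(make_amps(amp, rep("s", 30)), -amp[, 1])
  expect_equal(unname(rho), -1)
  expect_error(behavior_correlation(make_amps(amp, rep("s", 30)),
                                    rep(1, 30)), "constant")
})

test_that("Holm correction matches the hand-stepped procedure", {
  # the canonical worked example: only the smallest p survives
  expect_identical(oracle_holm_reject(c(0.01, 0.03, 0.04)),
                   c(TRUE, FALSE, FALSE))
  set.seed(5)
  for (i in 1:50) {
    p <- stats::runif(sample(3:10, 1))
    expect_identical(unname(stats::p.adjust(p, "holm") < 0.05),
                     oracle_holm_reject(p))
  }
})

test_that("across-fly aggregation flags planted negative couplings", {
  set.seed(6)
  rho <- cbind(matrix(stats::rnorm(8 * 2, -0.5, 0.1), 8, 2),
               matrix(stats::rnorm(8 * 2, 0, 0.1), 8, 2))
  colnames(rho) <- paste0("g", 1:4)
  agg <- aggregate_behavior_correlation(rho)
  expect_identical(agg$significant, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("decoder is perfect on one-hot noiseless tuning", {
  labels <- rep(letters[1:4], each = 10)
  x <- diag(4)[match(labels, letters[1:4]), ]
  dr <- decode_stimulus(make_amps(x, labels), n_iterations = 5, seed = 1)
  expect_equal(dr$overall_accuracy, 1)
  expect_equal(unname(rowSums(dr$confusion)), rep(1, 4))
})

test_that("decoder agrees with an unpenalized multinomial fit on clean data", {
  skip_if_not_installed("nnet")
  tun <- generate_tuning(8, 5, 4, seed = 9)
  gen <- generate_trials(tun, 20, gain_sd = 0.1, noise_sd = 0.02, seed = 10)
  amps <- peak_amplitudes(gen$tensor)
  dr <- decode_stimulus(amps, n_iterations = 10, seed = 2)
  # independent route: nnet::multinom with a fixed 90/10 split
  set.seed(3)
  y <- factor(amps$labels)
  test_idx <- unlist(lapply(levels(y), function(cl) {
    sample(which(y == cl), 2)
  }))
  df <- data.frame(y = y, amps$values)
  fit <- nnet::multinom(y ~ ., df[-test_idx, ], trace = FALSE, maxit = 300)
  acc_ref <- mean(predict(fit, df[test_idx, ]) == y[test_idx])
  expect_equal(dr$overall_accuracy, acc_ref, tolerance = 0.15)
})

test_that("decoding permuted labels sits at chance", {
  tun <- generate_tuning(8, 5, 4, seed = 11)
  gen <- generate_trials(tun, 20, gain_sd = 0.3, noise_sd = 0.05, seed = 12)
  amps <- peak_amplitudes(gen$tensor)
  set.seed(13)
  perm <- amplitude_matrix(amps$values, sample(amps$labels))
  dr <- decode_stimulus(perm, n_iterations = 20, seed = 14)
  expect_lt(abs(dr$overall_accuracy - 0.2), 0.12)
})

test_that("a glomerulus subset never beats the full population", {
  tun <- generate_tuning(10, 6, 3, seed = 15)
  gen <- generate_trials(tun, 25, gain_sd = 0.3, noise_sd = 0.05, seed = 16)
  amps <- peak_amplitudes(gen$tensor)
  full <- decode_stimulus(amps, n_iterations = 30, seed = 17)
  sub <- amplitude_matrix(amps$values[, 1:3], amps$labels)
  part <- decode_stimulus(sub, n_iterations = 30, seed = 17)
  se <- stats::sd(full$accuracy_by_iteration - part$accuracy_by_iteration) /
    sqrt(30)
  expect_lte(part$overall_accuracy,
             full$overall_accuracy + 2 * se + 0.02)
  expect_error(decode_stimulus(make_amps(matrix(1:4, 4, 1),
                                         c("a", "a", "a", "b"))), "fewer than 2")
})

test_that("trial shuffling preserves within-stimulus moments exactly", {
  tun <- generate_tuning(8, 4, 2, seed = 18)
  gen <- generate_trials(tun, 30, gain_sd = 0.4, noise_sd = 0.02, seed = 19)
  amps <- peak_amplitudes(gen$tensor)
  sh <- shuffle_trials(amps, seed = 20)
  for (s in unique(amps$labels)) {
    r <- amps$labels == s
    for (g in seq_len(ncol(amps$values))) {
      expect_identical(sort(amps$values[r, g]), sort(sh$values[r, g]))
    }
    expect_identical(colMeans(amps$values[r, ]), colMeans(sh$values[r, ]))
  }
  # two perfectly correlated columns decorrelate under shuffling
  set.seed(21)
  v <- stats::rnorm(30)
  dup <- make_amps(cbind(v, v), rep("s", 30))
  rs <- vapply(1:20, function(s) {
    sh2 <- shuffle_trials(dup, seed = s)
    stats::cor(sh2$values[, 1], sh2$values[, 2])
  }, numeric(1))
  expect_gt(mean(abs(rs) < 0.35), 0.85)
})
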