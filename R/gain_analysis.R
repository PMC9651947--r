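#' Surround speed tuning from probe amplitudes
#'
#' Mean probe response per background-image speed, normalized per
#' glomerulus by the mean response with a static background (speed 0).
#'
#' @param amps Numeric matrix (trials x glomeruli) or an
#'   [amplitude_matrix] of probe responses.
#' @param condition_speed Background speed per trial (deg/s); a speed-0
#'   condition must be present.
#' @return Object of class `tuning_curve`: list with `x` (sorted speeds),
#'   `y` (speeds x glomeruli normalized means), `sem`, `normalization`.
#' @export
surround_speed_tuning <- function(amps, condition_speed) {
  x <- if (inherits(amps, "amplitude_matrix")) amps$values else as.matrix(amps)
  if (length(condition_speed) != nrow(x)) {
    stop("`condition_speed` must be aligned per trial", call. = FALSE)
  }
  if (!any(condition_speed == 0)) {
    stop("speed-0 reference condition missing", call. = FALSE)
  }
  speeds <- sort(unique(condition_speed))
  m <- do.call(rbind, lapply(speeds, function(s) {
    colMeans(x[condition_speed == s, , drop = FALSE])
  }))
  se <- do.call(rbind, lapply(speeds, function(s) {
    apply(x[condition_speed == s, , drop = FALSE], 2, sem)
  }))
  ref <- m[speeds == 0, ]
  if (any(ref == 0)) stop("zero reference (speed-0) mean response", call. = FALSE)
  y <- sweep(m, 2, ref, `/`)
  se <- sweep(se, 2, ref, `/`)
  dimnames(y) <- list(NULL, colnames(x))
  structure(list(x = speeds, y = y, sem = se,
                 normalization = "probe response with static background"),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %d points, normalized to %s\n",
              length(x$x), x$normalization))
  invisible(x)
}

#' Population response gain versus walking amplitude
#'
#' Normalizes each trial's amplitudes by the per-stimulus, per-glomerulus
#' mean, averages across glomeruli to obtain one population gain value per
#' trial, then bins trials by walking amplitude. Bins with fewer than
#' `min_trials` trials are dropped with a message.
#'
#' @param amps An [amplitude_matrix].
#' @param walking_amplitude Walking amplitude per trial (deg/s).
#' @param bin_edges Walking-amplitude bin edges.
#' @param min_trials Minimum trials per used bin (default 5).
#' @return A `tuning_curve` (x = bin centers, y = mean gain per bin, sem).
#' @export
gain_vs_walking <- function(amps, walking_amplitude,
                            bin_edges = c(0, 2.5, 5, 10, 20, 40, 80),
                            min_trials = 5) {
  stopifnot(inherits(amps, "amplitude_matrix"))
  x <- amps$values
  if (length(walking_amplitude) != nrow(x)) {
    stop("`walking_amplitude` must be aligned per trial", call. = FALSE)
  }
  norm <- x
  for (s in unique(amps$labels)) {
    rows <- amps$labels == s
    mu <- colMeans(x[rows, , drop = FALSE])
    mu[mu == 0] <- NA
    norm[rows, ] <- sweep(x[rows, , drop = FALSE], 2, mu, `/`)
  }
  gain <- rowMeans(norm, na.rm = TRUE)
  bin <- cut(walking_amplitude, breaks = bin_edges, include.lowest = TRUE)
  counts <- table(bin)
  keep <- names(counts)[counts >= min_trials]
  dropped <- setdiff(levels(bin), keep)
  if (length(dropped) > 0) {
    message(sprintf("dropping %d walking-amplitude bin(s) with < %d trials: %s",
                    length(dropped), min_trials,
                    paste(dropped, collapse = ", ")))
  }
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  sel <- levels(bin) %in% keep
  y <- vapply(levels(bin)[sel], function(b) mean(gain[bin == b]), numeric(1))
  se <- vapply(levels(bin)[sel], function(b) sem(gain[bin == b]), numeric(1))
  structure(list(x = centers[sel], y = unname(y), sem = unname(se),
                 n = as.integer(counts[sel]),
                 normalization = "per-stimulus mean response"),
            class = "tuning_curve")
}

#' Response gain versus saccade timing
#'
#' Mean probe amplitude per saccade-probe offset, normalized by the mean
#' amplitude over reference trials where the saccade occurred far from the
#' probe response (`|offset| >= reference_min_abs`).
#'
#' @param amps Numeric vector (one glomerulus) or matrix
#'   (trials x glomeruli) of probe amplitudes.
#' @param saccade_offset Saccade onset time relative to probe response
#'   onset, per trial (s).
#' @param reference_min_abs Minimum `|offset|` defining reference trials
#'   (default 2 s).
#' @return A `tuning_curve` (x = sorted offsets, y = normalized gain,
#'   columns = glomeruli).
#' @export
saccade_timing_gain <- function(amps, saccade_offset, reference_min_abs = 2) {
  x <- as.matrix(amps)
  if (length(saccade_offset) != nrow(x)) {
    stop("`saccade_offset` must be aligned per trial", call. = FALSE)
  }
  ref_rows <- abs(saccade_offset) >= reference_min_abs
  if (!any(ref_rows)) stop("no reference trials (|offset| >= reference)", call. = FALSE)
  ref <- colMeans(x[ref_rows, , drop = FALSE])
  if (any(ref == 0)) stop("zero reference mean response", call. = FALSE)
  offs <- sort(unique(saccade_offset))
  y <- do.call(rbind, lapply(offs, function(o) {
    colMeans(x[saccade_offset == o, , drop = FALSE]) / ref
  }))
  se <- do.call(rbind, lapply(offs, function(o) {
    apply(x[saccade_offset == o, , drop = FALSE], 2, sem) / ref
  }))
  structure(list(x = offs, y = y, sem = se,
                 normalization = sprintf("trials with |offset| >= %g s",
                                         reference_min_abs)),
            class = "tuning_curve")
}

#' Visual x motor gain-independence test
#'
#' For each glomerulus, estimates the visual-saccade gain and the walking
#' gain from single-factor condition cells (each as the ratio of that
#' cell's mean probe amplitude to the reference cell's mean), predicts the
#' joint gain as their product, and compares it with the observed
#' both-factors gain. The deviation `observed - predicted` gets a
#' trial-bootstrap percentile confidence interval: under multiplicative
#' (independent) gain control the interval covers zero.
#'
#' @param data Data frame with columns `glomerulus`, `visual` (logical:
#'   saccadic visual input), `walking` (logical), `amplitude` (probe
#'   response). All four condition cells must be populated per glomerulus.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `independence_test`: data frame with one row per
#'   glomerulus (`g_visual`, `g_behavior`, `predicted`, `observed`,
#'   `deviation`, `ci_lo`, `ci_hi`, `n_*` per cell).
#' @export
independence_test <- function(data, n_boot = 1000, conf = 0.95, seed = 1) {
  need <- c("glomerulus", "visual", "walking", "amplitude")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns glomerulus, visual, walking, amplitude",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  alpha <- (1 - conf) / 2
  gloms <- unique(data$glomerulus)
  rows <- lapply(gloms, function(g) {
    d <- data[data$glomerulus == g, ]
    cells <- list(
      ref  = d$amplitude[!d$visual & !d$walking],
      vis  = d$amplitude[d$visual & !d$walking],
      beh  = d$amplitude[!d$visual & d$walking],
      both = d$amplitude[d$visual & d$walking]
    )
    empty <- names(cells)[vapply(cells, length, integer(1)) == 0]
    if (length(empty) > 0) {
      stop(sprintf("glomerulus '%s': empty condition cell(s): %s",
                   g, paste(empty, collapse = ", ")), call. = FALSE)
    }
    gains <- function(cl) {
      m <- vapply(cl, mean, numeric(1))
      c(g_vis = m[["vis"]] / m[["ref"]],
        g_beh = m[["beh"]] / m[["ref"]],
        obs = m[["both"]] / m[["ref"]])
    }
    g0 <- gains(cells)
    dev_boot <- replicate(n_boot, {
      bs <- lapply(cells, function(v) v[sample.int(length(v), replace = TRUE)])
      gb <- gains(bs)
      gb[["obs"]] - gb[["g_vis"]] * gb[["g_beh"]]
    })
    ci <- stats::quantile(dev_boot, c(alpha, 1 - alpha), names = FALSE)
    data.frame(
      glomerulus = g,
      g_visual = g0[["g_vis"]], g_behavior = g0[["g_beh"]],
      predicted = g0[["g_vis"]] * g0[["g_beh"]], observed = g0[["obs"]],
      deviation = g0[["obs"]] - g0[["g_vis"]] * g0[["g_beh"]],
      ci_lo = ci[1], ci_hi = ci[2],
      n_ref = length(cells$ref), n_visual = length(cells$vis),
      n_walking = length(cells$beh), n_both = length(cells$both)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("independence_test", "data.frame")
  out
}

#' Simulate a two-factor gain experiment
#'
#' Ground-truth generator for the independence test: per glomerulus, probe
#' amplitudes in the four {visual saccade} x {walking} condition cells
#' follow `base * g_vis^visual * g_beh^walking * (1 + interaction)^(visual
#' * walking) * noise`, with multiplicative log-normal noise of
#' coefficient of variation `noise_cv`. With `interaction = 0` the two
#' gains combine exactly multiplicatively.
#'
#' @param n_glomeruli Number of glomeruli.
#' @param n_trials_per_cell Trials in each of the four condition cells.
#' @param g_vis_range,g_beh_range Ranges for per-glomerulus marginal gains.
#' @param interaction Multiplicative interaction applied in the
#'   both-factors cell (0 = independent gains).
#' @param noise_cv Trial-noise coefficient of variation.
#' @param seed Integer seed.
#' @return List with `data` (data frame for [independence_test()]) and
#'   `truth` (per-glomerulus `g_vis`, `g_beh`, `interaction`).
#' @export
simulate_gain_experiment <- function(n_glomeruli = 8, n_trials_per_cell = 50,
                                     g_vis_range = c(0.4, 0.9),
                                     g_beh_range = c(0.5, 0.95),
                                     interaction = 0, noise_cv = 0.25,
                                     seed = 1) {
  set.seed(as.integer(seed))
  g_vis <- stats::runif(n_glomeruli, g_vis_range[1], g_vis_range[2])
  g_beh <- stats::runif(n_glomeruli, g_beh_range[1], g_beh_range[2])
  base <- stats::rlnorm(n_glomeruli, log(1), 0.3)
  sdlog <- sqrt(log(1 + noise_cv^2))
  grid <- expand.grid(visual = c(FALSE, TRUE), walking = c(FALSE, TRUE))
  out <- list()
  for (g in seq_len(n_glomeruli)) {
    for (i in seq_len(nrow(grid))) {
      v <- grid$visual[i]; w <- grid$walking[i]
      mu <- base[g] * g_vis[g]^v * g_beh[g]^w *
        (1 + interaction)^(v && w)
      amp <- mu * stats::rlnorm(n_trials_per_cell, -sdlog^2 / 2, sdlog)
      out[[length(out) + 1L]] <- data.frame(
        glomerulus = sprintf("g%02d", g), visual = v, walking = w,
        amplitude = amp)
    }
  }
  list(data = do.call(rbind, out),
       truth = list(g_vis = g_vis, g_beh = g_beh, base = base,
                    interaction = interaction))
}

#' Simulate probe trials with saccade-timing-dependent suppression
#'
#' Generator for [saccade_timing_gain()]: trials at each saccade-probe
#' offset have mean amplitude `base * s(offset)` where the suppression
#' profile `s` dips to `1 - depth` within `half_width` of offset 0 and is
#' 1 far from it (Gaussian profile), with multiplicative log-normal noise.
#'
#' @param offsets Offset grid (s); should span negative and positive lags
#'   and include |offset| >= 2 s reference points.
#' @param n_trials_per_offset Trials per offset.
#' @param depth Maximal fractional suppression at offset 0.
#' @param half_width Suppression half-width (s).
#' @param noise_cv Trial-noise coefficient of variation.
#' @param base Mean unsuppressed amplitude.
#' @param seed Integer seed.
#' @return List with `amplitude` (vector), `offset` (per trial), and
#'   `truth_profile` (suppression at each unique offset).
#' @export
simulate_saccade_timing <- function(offsets = seq(-3, 3, by = 0.5),
                                    n_trials_per_offset = 30, depth = 0.5,
                                    half_width = 0.25, noise_cv = 0.2,
                                    base = 1, seed = 1) {
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + noise_cv^2))
  profile <- 1 - depth * exp(-offsets^2 / (2 * half_width^2))
  off <- rep(offsets, each = n_trials_per_offset)
  mu <- rep(base * profile, each = n_trials_per_offset)
  amp <- mu * stats::rlnorm(length(off), -sdlog^2 / 2, sdlog)
  list(amplitude = amp, offset = off,
       truth_profile = stats::setNames(profile, offsets))
}
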