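#' Group-structured glomerulus tuning matrix
#'
#' Generates a glomeruli x stimuli matrix of mean response amplitudes (dF/F
#' units) with a functional-group structure: glomeruli are assigned to
#' groups, each group shares a response template with strong responses to a
#' dedicated block of stimuli and weak responses elsewhere, and individual
#' glomeruli scale and jitter their group template. Within-group tuning
#' correlation therefore exceeds across-group correlation, so agglomerative
#' clustering of the rows recovers the group labels.
#'
#' @param n_glomeruli Number of glomeruli (rows).
#' @param n_stimuli Number of stimuli (columns); must be >= `n_groups`.
#' @param n_groups Number of functional groups.
#' @param seed Integer seed; the matrix is deterministic given the seed.
#' @param peak Mean response to preferred stimuli (dF/F).
#' @param baseline Mean response to non-preferred stimuli (dF/F).
#'
#' @return Object of class `tuning_matrix`: list with `values`
#'   (glomeruli x stimuli, >= 0), `glomerulus_names`, `stimulus_names`,
#'   `group_labels`.
#' @export
generate_tuning <- function(n_glomeruli = 13, n_stimuli = 12, n_groups = 4,
                            seed = 1, peak = 1, baseline = 0.1) {
  if (n_groups > n_glomeruli) {
    stop("`n_groups` must be <= `n_glomeruli`", call. = FALSE)
  }
  if (n_stimuli < n_groups) {
    stop("`n_stimuli` must be >= `n_groups`", call. = FALSE)
  }
  set.seed(as.integer(seed))
  blocks <- split(seq_len(n_stimuli),
                  rep(seq_len(n_groups), length.out = n_stimuli))
  templates <- matrix(0, n_groups, n_stimuli)
  for (g in seq_len(n_groups)) {
    templates[g, ] <- baseline * stats::runif(n_stimuli, 0.3, 1.7)
    templates[g, blocks[[g]]] <- peak * stats::runif(length(blocks[[g]]), 0.7, 1.3)
  }
  group_labels <- rep(seq_len(n_groups), length.out = n_glomeruli)
  group_labels <- sort(group_labels)
  scales <- exp(stats::rnorm(n_glomeruli, 0, 0.25))
  values <- templates[group_labels, , drop = FALSE] * scales +
    matrix(stats::rnorm(n_glomeruli * n_stimuli, 0, 0.02),
           n_glomeruli, n_stimuli)
  values <- pmax(values, 0)
  gn <- sprintf("g%02d", seq_len(n_glomeruli))
  sn <- sprintf("stim%02d", seq_len(n_stimuli))
  dimnames(values) <- list(gn, sn)
  structure(
    list(values = values, glomerulus_names = gn, stimulus_names = sn,
         group_labels = group_labels),
    class = "tuning_matrix"
  )
}

#' @export
print.tuning_matrix <- function(x, ...) {
  cat(sprintf("<tuning_matrix> %d glomeruli x %d stimuli, %d groups\n",
              nrow(x$values), ncol(x$values), length(unique(x$group_labels))))
  invisible(x)
}

# Monophasic calcium-response kernel: difference of exponentials, peak
# normalized to 1. Rise ~0.1 s, decay ~0.5 s spans several hundred ms.
doe_kernel <- function(t, tau_rise = 0.1, tau_decay = 0.5) {
  k <- ifelse(t > 0, exp(-t / tau_decay) - exp(-t / tau_rise), 0)
  pk <- max(k)
  if (pk > 0) k / pk else k
}

#' Trial tensor container
#'
#' @param dff 3D array, glomeruli x trials x timepoints.
#' @param time Timepoints (s) relative to stimulus onset, uniform.
#' @param labels Stimulus identity per trial.
#' @param epoch `c(pre, stim, tail)` durations (s).
#' @param behavior_amplitude Optional walking amplitude per trial (deg/s).
#' @param glomerulus_names Optional row names.
#' @param raw_f Optional raw-fluorescence array of the same shape.
#' @return Object of class `trial_tensor`.
#' @export
trial_tensor <- function(dff, time, labels, epoch,
                         behavior_amplitude = NULL, glomerulus_names = NULL,
                         raw_f = NULL) {
  stopifnot(length(dim(dff)) == 3L)
  if (length(labels) != dim(dff)[2]) {
    stop("`labels` length must equal the number of trials", call. = FALSE)
  }
  if (length(time) != dim(dff)[3]) {
    stop("`time` length must equal the number of timepoints", call. = FALSE)
  }
  if (!any(time < 0)) stop("pre-stimulus window is empty", call. = FALSE)
  structure(
    list(dff = dff, raw_f = raw_f, time = time, labels = labels,
         epoch = epoch, behavior_amplitude = behavior_amplitude,
         glomerulus_names = glomerulus_names %||%
           sprintf("g%02d", seq_len(dim(dff)[1]))),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$dff)
  cat(sprintf("<trial_tensor> %d glomeruli x %d trials x %d timepoints, %d stimuli\n",
              d[1], d[2], d[3], length(unique(x$labels))))
  invisible(x)
}

#' Simulate glomerulus population trial responses with a shared gain
#'
#' Generates single-trial responses under the generative model
#' `amplitude[g, t] = gain[t] * tuning[g, s(t)] * exp(beta[g] * b[t]) +
#' noise`, where `gain[t]` is a log-normal per-trial scalar shared by all
#' glomeruli (mean 1), `b[t]` is the standardized walking amplitude on
#' trial `t`, `beta[g] < 0` only for the designated behavior-modulated
#' subset, and the noise is independent Gaussian. Each trial is rendered as
#' a monophasic difference-of-exponentials time course peaking at the
#' trial's amplitude, embedded in a pre/stim/tail epoch structure. Stimulus
#' order is randomly interleaved.
#'
#' @param tuning A [generate_tuning()] object.
#' @param n_trials_per_stim Trials per stimulus.
#' @param gain_sd Log-domain SD of the shared gain.
#' @param noise_sd SD of additive amplitude noise (dF/F; >= 0).
#' @param behavior_coupling Coupling coefficient applied to modulated
#'   glomeruli (typically <= 0).
#' @param modulated Indices of behavior-modulated glomeruli (may be empty).
#' @param p_move Probability a trial falls in a walking bout.
#' @param seed Integer seed.
#' @param dt Imaging sample interval (s); default the 7.22 Hz volume rate.
#' @param epoch `c(pre, stim, tail)` durations (s).
#' @param f0 Baseline fluorescence per glomerulus used to synthesize the
#'   optional raw-fluorescence channel (`raw_f = f0 * (1 + dff)`).
#'
#' @return List with elements `tensor` (a [trial_tensor]) and `truth`
#'   (list: `gain`, `behavior_coupling` per glomerulus, `trial_behavior`
#'   raw walking amplitude per trial, `b` its standardized version,
#'   `amplitude` the noiseless-rendered trial amplitudes (glomeruli x
#'   trials), `noise_sd`).
#' @export
generate_trials <- function(tuning, n_trials_per_stim = 30, gain_sd = 0.4,
                            noise_sd = 0.05, behavior_coupling = -1,
                            modulated = integer(0), p_move = 0.4, seed = 1,
                            dt = 1 / 7.22, epoch = c(1.5, 3, 1.5), f0 = 1) {
  stopifnot(inherits(tuning, "tuning_matrix"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (sum(epoch) <= 0) stop("trial epochs must have positive duration", call. = FALSE)
  seeds <- expand_seeds(seed, 2)
  labels <- interleave_trials(tuning$stimulus_names, n_trials_per_stim,
                              seed = seeds[1])
  set.seed(seeds[2])
  n_g <- nrow(tuning$values)
  n_t <- length(labels)

  # Trial behavior: walking bouts (log-normal amplitudes around ~20 deg/s)
  # interspersed with near-stationary trials.
  moving <- stats::runif(n_t) < p_move
  w <- ifelse(moving, stats::rlnorm(n_t, log(20), 0.4),
              stats::rlnorm(n_t, log(2), 0.3))
  b <- if (stats::sd(w) > 0) (w - mean(w)) / stats::sd(w) else w * 0

  g_t <- if (gain_sd > 0) {
    stats::rlnorm(n_t, meanlog = -gain_sd^2 / 2, sdlog = gain_sd)
  } else rep(1, n_t)

  beta <- numeric(n_g)
  beta[modulated] <- behavior_coupling

  stim_idx <- match(labels, tuning$stimulus_names)
  amp_clean <- tuning$values[, stim_idx, drop = FALSE] *
    matrix(g_t, n_g, n_t, byrow = TRUE) *
    exp(outer(beta, b))
  amp <- amp_clean +
    matrix(stats::rnorm(n_g * n_t, 0, noise_sd), n_g, n_t)

  time <- seq(-epoch[1], epoch[2] + epoch[3], by = dt)
  kernel <- doe_kernel(time)
  dff <- array(0, c(n_g, n_t, length(time)))
  for (g in seq_len(n_g)) {
    dff[g, , ] <- outer(amp[g, ], kernel)
  }
  f0 <- rep_len(f0, n_g)
  raw_f <- array(0, dim(dff))
  for (g in seq_len(n_g)) raw_f[g, , ] <- f0[g] * (1 + dff[g, , ])

  tensor <- trial_tensor(dff, time, labels, epoch,
                         behavior_amplitude = w,
                         glomerulus_names = tuning$glomerulus_names,
                         raw_f = raw_f)
  truth <- list(gain = g_t, behavior_coupling = beta, trial_behavior = w,
                b = b, amplitude = amp, noise_sd = noise_sd,
                modulated = modulated)
  list(tensor = tensor, truth = truth)
}

#' Simulate fictive walking with saccadic turning
#'
#' Saccade onsets follow a renewal process with a hard refractory period:
#' inter-onset intervals are `refractory_s + Gamma(shape = 2)` with the
#' gamma scale set so the mean interval equals `1 / saccade_rate_hz`. Each
#' saccade is a 200 ms half-sine angular-velocity pulse about the z axis
#' with a random sign and a peak speed drawn from `saccade_amp_range`
#' (always above the conventional 160 deg/s saccade threshold). Forward
#' velocity follows smooth bouts generated independently of saccade timing;
#' rot_x/rot_y carry components proportional to forward velocity so forward
#' and rotational movement are correlated, as in fictive walking. Heading
#' integrates angular velocity and the trajectory integrates forward
#' velocity along the heading.
#'
#' @param duration_s Duration (s).
#' @param saccade_rate_hz Mean saccade rate (Hz, > 0); must satisfy
#'   `rate * refractory < 1`.
#' @param refractory_s Hard refractory period between onsets (s, >= 0).
#' @param saccade_amp_range Range of peak angular speeds (deg/s).
#' @param dt Sample interval (s; default 0.02, i.e. 50 Hz).
#' @param seed Integer seed.
#' @param noise_sd SD of additive angular-velocity noise (deg/s).
#'
#' @return List with `trace` (class `walking_trace`: `time`, `rot_x`,
#'   `rot_y`, `rot_z`, `amplitude` in deg/s), `trajectory` (class
#'   `trajectory_segment`: `time`, `x`, `y` in cm, `heading` deg,
#'   `angular_velocity` deg/s, `forward_velocity` cm/s), `saccade_times`
#'   (true onsets, s), `saccade_peaks` (true peak speeds, deg/s), and
#'   `walking_bout` (logical ground-truth walking indicator per sample).
#' @export
generate_walking <- function(duration_s = 300, saccade_rate_hz = 0.8,
                             refractory_s = 0.5,
                             saccade_amp_range = c(200, 500), dt = 0.02,
                             seed = 1, noise_sd = 5) {
  if (saccade_rate_hz <= 0) stop("`saccade_rate_hz` must be > 0", call. = FALSE)
  if (refractory_s < 0) stop("`refractory_s` must be >= 0", call. = FALSE)
  if (saccade_rate_hz * refractory_s >= 1) {
    stop("infeasible: saccade_rate_hz * refractory_s must be < 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  mean_iti <- 1 / saccade_rate_hz
  scale <- (mean_iti - refractory_s) / 2 # gamma shape 2
  onsets <- numeric(0)
  t <- stats::rgamma(1, 2, scale = scale) # first onset needs no refractory
  while (t < duration_s - 0.25) {
    onsets <- c(onsets, t)
    t <- t + refractory_s + stats::rgamma(1, shape = 2, scale = scale)
  }

  time <- seq(0, duration_s, by = dt)
  n <- length(time)
  rot_z <- stats::rnorm(n, 0, noise_sd)
  pulse_dur <- 0.2
  peaks <- stats::runif(length(onsets), saccade_amp_range[1], saccade_amp_range[2])
  signs <- sample(c(-1, 1), length(onsets), replace = TRUE)
  for (i in seq_along(onsets)) {
    idx <- which(time >= onsets[i] & time < onsets[i] + pulse_dur)
    tau <- (time[idx] - onsets[i]) / pulse_dur
    rot_z[idx] <- rot_z[idx] + signs[i] * peaks[i] * sin(pi * tau)
  }

  # Forward-velocity bouts: the fly alternates between walking bouts and
  # stationary periods on a ~1 s timescale (sign of a smoothed latent
  # process), independently of saccade timing. Walking speed ~1.5-2.5 cm/s.
  ar <- as.numeric(stats::filter(stats::rnorm(n), 1 - dt, "recursive"))
  ar <- ar / stats::sd(ar)
  walking_bout <- ar > 0
  forward <- ifelse(walking_bout, 1.5 + 0.5 * pmax(ar, 0), 0) # cm/s
  rot_x <- 20 * forward + stats::rnorm(n, 0, noise_sd)
  rot_y <- 7 * forward + stats::rnorm(n, 0, noise_sd)

  amplitude <- sqrt(rot_x^2 + rot_y^2 + rot_z^2)
  heading <- cumsum(rot_z * dt)
  x <- cumsum(forward * cos(heading * pi / 180) * dt)
  y <- cumsum(forward * sin(heading * pi / 180) * dt)

  trace <- structure(
    list(time = time, rot_x = rot_x, rot_y = rot_y, rot_z = rot_z,
         amplitude = amplitude),
    class = "walking_trace"
  )
  trajectory <- structure(
    list(time = time, x = x, y = y, heading = heading,
         angular_velocity = rot_z, forward_velocity = forward),
    class = "trajectory_segment"
  )
  list(trace = trace, trajectory = trajectory, saccade_times = onsets,
       saccade_peaks = peaks, walking_bout = walking_bout)
}
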