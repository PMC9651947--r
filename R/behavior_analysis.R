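#' Walking amplitude from three-axis ball rotation
#'
#' Pointwise magnitude of the total rotation vector,
#' `sqrt(rot_x^2 + rot_y^2 + rot_z^2)`.
#'
#' @param rot_x,rot_y,rot_z Rotation rates about each ball axis (deg/s),
#'   equal lengths.
#' @return Numeric vector of walking amplitudes (deg/s).
#' @export
walking_amplitude <- function(rot_x, rot_y, rot_z) {
  n <- length(rot_x)
  if (length(rot_y) != n || length(rot_z) != n) {
    stop("rotation traces must have equal lengths", call. = FALSE)
  }
  sqrt(rot_x^2 + rot_y^2 + rot_z^2)
}

# Li cross-entropy criterion for a candidate threshold: with S0/S1 the sums
# and m0/m1 the means of values below/above `t`, the data-dependent part of
# the cross entropy is -(S0 log m0 + S1 log m1); empty or all-zero sides
# contribute zero.
li_criterion <- function(values, thresholds) {
  vapply(thresholds, function(t) {
    below <- values[values < t]
    above <- values[values >= t]
    s0 <- sum(below); s1 <- sum(above)
    term <- 0
    if (s0 > 0) term <- term - s0 * log(s0 / length(below))
    if (s1 > 0) term <- term - s1 * log(s1 / length(above))
    term
  }, numeric(1))
}

#' Li minimum cross-entropy threshold
#'
#' Automatic threshold separating low from high values by minimizing Li's
#' cross-entropy criterion. The criterion is evaluated exactly at every
#' midpoint between consecutive sorted unique values and the minimizer is
#' returned, so the result coincides with a brute-force scan by
#' construction. The threshold is scale-equivariant: scaling all values by
#' `c > 0` scales the threshold by `c`.
#'
#' @param values Non-negative numeric vector with >= 2 distinct values.
#' @return The threshold (numeric scalar).
#' @export
li_threshold <- function(values) {
  values <- values[is.finite(values)]
  if (any(values < 0)) stop("`values` must be >= 0", call. = FALSE)
  u <- sort(unique(values))
  if (length(u) < 2) {
    stop("all values identical: threshold undefined", call. = FALSE)
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  crit <- li_criterion(values, cand)
  cand[which.min(crit)]
}

#' Classify trials as behaving versus non-behaving
#'
#' Determines a session-wide threshold from the full walking-amplitude
#' trace with [li_threshold()], then flags each trial as behaving if the
#' amplitude exceeds the threshold for at least `min_fraction` of that
#' trial's time points (boundary inclusive).
#'
#' @param amplitude Walking-amplitude trace (deg/s).
#' @param trial_windows List (or 2-column matrix) of sample-index ranges
#'   `c(first, last)` per trial, within the trace.
#' @param min_fraction Minimum supra-threshold fraction (default 0.25).
#' @return Object of class `behaving_classification`: list with
#'   `threshold`, `fraction_above` per trial, `behaving` logical per trial.
#' @export
classify_behaving <- function(amplitude, trial_windows, min_fraction = 0.25) {
  if (is.matrix(trial_windows)) {
    trial_windows <- split(trial_windows, row(trial_windows))
  }
  thr <- li_threshold(amplitude)
  frac <- vapply(trial_windows, function(w) {
    if (w[1] < 1 || w[2] > length(amplitude) || w[2] < w[1]) {
      stop("trial window outside trace (or empty)", call. = FALSE)
    }
    seg <- amplitude[w[1]:w[2]]
    mean(seg > thr)
  }, numeric(1))
  structure(
    list(threshold = thr, fraction_above = unname(frac),
         behaving = unname(frac >= min_fraction),
         min_fraction = min_fraction),
    class = "behaving_classification"
  )
}

#' Detect saccades from an angular-velocity trace
#'
#' Finds contiguous excursions where angular speed `|v|` meets or exceeds
#' `speed_threshold`; excursions separated by less than `min_separation`
#' are merged into one event. The onset of each event is refined by
#' backtracking from the first supra-threshold sample to where the speed
#' last dropped below `onset_fraction * speed_threshold` (at most
#' `max_backtrack` seconds earlier), which recovers the start of the
#' underlying turn rather than the threshold-crossing time -- turns that
#' barely exceed threshold otherwise appear to start late. The peak speed
#' attained during the excursion is recorded per event.
#'
#' @param angular_velocity Angular-velocity trace (deg/s), uniform sampling.
#' @param dt Sample interval (s).
#' @param speed_threshold Saccade classification threshold (deg/s, > 0);
#'   default 160.
#' @param min_separation Minimum separation between distinct events (s).
#' @param onset_fraction Fraction of `speed_threshold` used as the
#'   backtracked onset level.
#' @param max_backtrack Maximum backtracking time (s).
#' @return Object of class `saccade_events`: list with `onset_times`,
#'   `peak_speeds`, `inter_turn_intervals` (successive onset differences).
#' @export
detect_saccades <- function(angular_velocity, dt, speed_threshold = 160,
                            min_separation = 0.1, onset_fraction = 0.2,
                            max_backtrack = 0.1) {
  if (speed_threshold <= 0) stop("`speed_threshold` must be > 0", call. = FALSE)
  speed <- abs(angular_velocity)
  supra <- speed >= speed_threshold
  if (!any(supra)) {
    return(structure(list(onset_times = numeric(0), peak_speeds = numeric(0),
                          inter_turn_intervals = numeric(0)),
                     class = "saccade_events"))
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # Merge excursions separated by a sub-threshold gap < min_separation.
  gap_samples <- min_separation / dt
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      if (seg$start[i] - merged$end[nrow(merged)] - 1L < gap_samples) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }
  onset_level <- onset_fraction * speed_threshold
  back_samples <- floor(max_backtrack / dt)
  onset_idx <- vapply(merged$start, function(s) {
    lo <- max(1L, s - back_samples)
    below <- which(speed[lo:s] < onset_level)
    as.integer(if (length(below) > 0) lo + max(below) - 1L else lo)
  }, integer(1))
  onsets <- (onset_idx - 1L) * dt
  peaks <- mapply(function(a, b) max(speed[a:b]), merged$start, merged$end)
  structure(
    list(onset_times = onsets, peak_speeds = unname(peaks),
         inter_turn_intervals = diff(onsets)),
    class = "saccade_events"
  )
}

#' @export
print.saccade_events <- function(x, ...) {
  cat(sprintf("<saccade_events> %d events%s\n", length(x$onset_times),
              if (length(x$inter_turn_intervals) > 0)
                sprintf(", median ITI %.2f s", stats::median(x$inter_turn_intervals))
              else ""))
  invisible(x)
}

#' Saccade-cycle statistics
#'
#' Partitions the samples of an angular-velocity/forward-velocity recording
#' into peri-saccade samples (within `window / 2` of a saccade onset) and
#' intersaccade samples, and returns the inter-turn-interval histogram plus
#' angular-speed and forward-velocity histograms for the two phases.
#'
#' @param events A [detect_saccades()] result for the same trace.
#' @param angular_velocity Angular-velocity trace (deg/s).
#' @param forward_velocity Forward-velocity trace (cm/s).
#' @param dt Sample interval (s).
#' @param window Peri-saccade window width (s; default 0.4, i.e. +/- 200 ms).
#' @param iti_breaks,speed_breaks,forward_breaks Histogram bin edges.
#' @return Object of class `saccade_cycle_stats`: list with `iti_hist`
#'   (possibly flagged empty), `peri` / `inter` (per-phase samples:
#'   `angular_speed`, `forward_velocity`), and per-phase histograms.
#' @export
saccade_cycle_stats <- function(events, angular_velocity, forward_velocity,
                                dt, window = 0.4,
                                iti_breaks = seq(0, 10, by = 0.25),
                                speed_breaks = NULL, forward_breaks = NULL) {
  stopifnot(inherits(events, "saccade_events"))
  n <- length(angular_velocity)
  time <- (seq_len(n) - 1L) * dt
  iti <- events$inter_turn_intervals
  iti_hist <- if (length(iti) >= 1) {
    graphics::hist(pmin(iti, max(iti_breaks)), breaks = iti_breaks,
                   plot = FALSE)
  } else NULL

  peri <- rep(FALSE, n)
  for (on in events$onset_times) {
    peri[time >= on - window / 2 & time <= on + window / 2] <- TRUE
  }
  speed <- abs(angular_velocity)
  mk_hist <- function(v, breaks) {
    if (length(v) == 0) return(NULL)
    if (is.null(breaks)) breaks <- "Sturges"
    graphics::hist(v, breaks = breaks, plot = FALSE)
  }
  structure(
    list(
      iti = iti,
      iti_hist = iti_hist,
      iti_empty = length(iti) < 1,
      peri = list(angular_speed = speed[peri],
                  forward_velocity = forward_velocity[peri]),
      inter = list(angular_speed = speed[!peri],
                   forward_velocity = forward_velocity[!peri]),
      peri_speed_hist = mk_hist(speed[peri], speed_breaks),
      inter_speed_hist = mk_hist(speed[!peri], speed_breaks),
      peri_forward_hist = mk_hist(forward_velocity[peri], forward_breaks),
      inter_forward_hist = mk_hist(forward_velocity[!peri], forward_breaks),
      window = window
    ),
    class = "saccade_cycle_stats"
  )
}

#' Read a FicTrac-style rotation CSV
#'
#' Expects per-frame rotation rates in columns `rot_x`, `rot_y`, `rot_z`
#' (deg/s) and optionally `time` (s); rates are taken as already calibrated
#' to degrees per second.
#'
#' @param path CSV file path.
#' @param dt Sample interval used when no `time` column is present.
#' @return A `walking_trace` list (`time`, `rot_x`, `rot_y`, `rot_z`,
#'   `amplitude`).
#' @export
read_fictrac_csv <- function(path, dt = 0.02) {
  df <- utils::read.csv(path)
  need <- c("rot_x", "rot_y", "rot_z")
  if (!all(need %in% names(df))) {
    stop("CSV must contain columns rot_x, rot_y, rot_z", call. = FALSE)
  }
  time <- if ("time" %in% names(df)) df$time else (seq_len(nrow(df)) - 1L) * dt
  structure(
    list(time = time, rot_x = df$rot_x, rot_y = df$rot_y, rot_z = df$rot_z,
         amplitude = walking_amplitude(df$rot_x, df$rot_y, df$rot_z)),
    class = "walking_trace"
  )
}
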