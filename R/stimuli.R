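#' Random-dot motion coherence stimulus
#'
#' Builds a field of dots moving at a common speed on an azimuth x elevation
#' torus. A fraction `coherence` of the dots (rounded half away from zero)
#' moves along `signal_direction`; the remaining dots move in directions
#' drawn independently and uniformly on `[0, 360)` degrees. Dot starting
#' positions are drawn before any direction, so for a fixed seed the dot
#' positions at frame 1 are identical across coherence levels, and the dot
#' count, size, speed -- hence overall intensity, contrast, and motion
#' energy -- are matched across coherence.
#'
#' @param n_dots Number of dots (>= 1, constant across frames).
#' @param coherence Fraction of signal dots, in `[0, 1]`.
#' @param signal_direction Signal direction (degrees; 0 = +azimuth).
#' @param speed Dot speed (deg/s), identical for every dot.
#' @param duration Stimulus duration (s).
#' @param dt Frame interval (s).
#' @param seed Integer seed.
#' @param dot_diameter Dot diameter (degrees).
#' @param field_az,field_el Field extent (degrees); both axes wrap.
#'
#' @return Object of class `dot_field`: list with `az`, `el`
#'   (`n_dots x n_frames` position matrices, degrees), `directions`
#'   (degrees per dot), `n_signal`, and the stimulus parameters.
#' @export
make_dot_field <- function(n_dots, coherence, signal_direction = 0, speed = 80,
                           duration = 3, dt = 0.05, seed = 1,
                           dot_diameter = 15, field_az = 360, field_el = 120) {
  if (n_dots < 1) stop("`n_dots` must be >= 1", call. = FALSE)
  if (coherence < 0 || coherence > 1) {
    stop("`coherence` must be in [0, 1]", call. = FALSE)
  }
  set.seed(as.integer(seed))
  az0 <- stats::runif(n_dots, 0, field_az)
  el0 <- stats::runif(n_dots, 0, field_el)
  n_signal <- floor(coherence * n_dots + 0.5) # round half away from zero
  directions <- numeric(n_dots)
  if (n_signal > 0) directions[seq_len(n_signal)] <- signal_direction
  if (n_signal < n_dots) {
    directions[(n_signal + 1L):n_dots] <- stats::runif(n_dots - n_signal, 0, 360)
  }
  times <- seq(0, duration, by = dt)
  dir_rad <- directions * pi / 180
  az <- (outer(cos(dir_rad) * speed, times) + az0) %% field_az
  el <- (outer(sin(dir_rad) * speed, times) + el0) %% field_el
  structure(
    list(az = az, el = el, directions = directions, n_signal = n_signal,
         n_dots = n_dots, coherence = coherence,
         signal_direction = signal_direction, speed = speed,
         dot_diameter = dot_diameter, field_az = field_az,
         field_el = field_el, time = times),
    class = "dot_field"
  )
}

# Precompute the pixel-offset stamp of a disc of `diameter` degrees at
# `pixel_scale` deg/px. Centers are snapped to pixel centers, so every dot
# covers exactly the same set of offsets wherever it sits on the torus.
disc_stamp <- function(diameter, pixel_scale) {
  r_px <- diameter / 2 / pixel_scale
  half <- ceiling(r_px)
  off <- expand.grid(dr = -half:half, dc = -half:half)
  off[off$dr^2 + off$dc^2 <= r_px^2, , drop = FALSE]
}

#' Render a dot field to frames
#'
#' Renders dots as dark discs on a mean-gray background. Dot centers are
#' snapped to the pixel grid and each dot darkens its disc additively
#' ("transparent" dark dots): a pixel covered by k dots has intensity
#' `background - k * dot_darkness`. This compositing rule makes the total
#' rendered darkness of every frame exactly `n_dots * stamp_area *
#' dot_darkness`, independent of dot positions and hence of coherence.
#'
#' @param field A [make_dot_field()] object.
#' @param pixel_scale Degrees per pixel of the rendering grid.
#' @param background Background intensity.
#' @param dot_darkness Darkness added per covering dot.
#' @return 3D array `rows x cols x frames`.
#' @export
render_dot_field <- function(field, pixel_scale = 2, background = 0.5,
                             dot_darkness = 0.3) {
  stopifnot(inherits(field, "dot_field"))
  nc <- round(field$field_az / pixel_scale)
  nr <- round(field$field_el / pixel_scale)
  stamp <- disc_stamp(field$dot_diameter, pixel_scale)
  nt <- ncol(field$az)
  frames <- array(background, c(nr, nc, nt))
  for (i in seq_len(nt)) {
    k <- dot_cover_counts(field, i, nr, nc, pixel_scale, stamp)
    frames[, , i] <- background - dot_darkness * k
  }
  frames
}

# Integer matrix of per-pixel dot cover counts for one frame.
dot_cover_counts <- function(field, frame, nr, nc, pixel_scale, stamp) {
  rc <- round(field$el[, frame] / pixel_scale) %% nr
  cc <- round(field$az[, frame] / pixel_scale) %% nc
  k <- matrix(0L, nr, nc)
  for (d in seq_len(field$n_dots)) {
    rows <- (rc[d] + stamp$dr) %% nr + 1L
    cols <- (cc[d] + stamp$dc) %% nc + 1L
    idx <- cbind(rows, cols)
    k[idx] <- k[idx] + 1L
  }
  k
}

#' Per-frame dot count and mean rendered intensity
#'
#' Computes, for each frame, the number of dots and the mean intensity of
#' the rendered frame. Because rendering composites dots additively on a
#' pixel-snapped grid, the mean is evaluated by exact integer accounting of
#' covered pixels, so matched configurations (same `n_dots`, size, grid)
#' yield bit-identical means regardless of coherence.
#'
#' @inheritParams render_dot_field
#' @return Data frame with columns `frame`, `n_dots`, `mean_intensity`.
#' @export
dot_field_frame_stats <- function(field, pixel_scale = 2, background = 0.5,
                                  dot_darkness = 0.3) {
  stopifnot(inherits(field, "dot_field"))
  nc <- round(field$field_az / pixel_scale)
  nr <- round(field$field_el / pixel_scale)
  stamp <- disc_stamp(field$dot_diameter, pixel_scale)
  nt <- ncol(field$az)
  means <- numeric(nt)
  for (i in seq_len(nt)) {
    k <- dot_cover_counts(field, i, nr, nc, pixel_scale, stamp)
    total_cover <- sum(as.numeric(k)) # exact: small integers
    means[i] <- background - dot_darkness * total_cover / (nr * nc)
  }
  data.frame(frame = seq_len(nt), n_dots = field$n_dots,
             mean_intensity = means)
}

#' Saccade playback displacement profile
#'
#' Azimuthal displacement of the background image mimicking a walking
#' saccade: zero before `onset`, a linear ramp reaching `amplitude` degrees
#' at `onset + duration`, constant afterwards. The default 70 degrees over
#' 200 ms corresponds to a constant-velocity turn of 350 deg/s.
#'
#' @param t Time or vector of times (s).
#' @param onset Saccade onset (s).
#' @param amplitude Total displacement (degrees).
#' @param duration Saccade duration (s, > 0).
#' @return Displacement in degrees, same length as `t`.
#' @export
saccade_displacement <- function(t, onset = 0, amplitude = 70, duration = 0.2) {
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  amplitude * pmin(pmax((t - onset) / duration, 0), 1)
}

#' Drifting grating with a moving probe spot
#'
#' Renders a sinusoidal luminance grating drifting at `grating_speed` with
#' an optional dark probe disc moving horizontally across the field. The
#' temporal frequency is `grating_speed / spatial_period` and must be
#' resolvable at the chosen frame interval.
#'
#' @param spatial_period Grating spatial period (degrees, > 0).
#' @param grating_speed Grating drift speed (deg/s).
#' @param probe A [spot_spec] or `NULL` to disable the probe.
#' @param duration Stimulus duration (s).
#' @param dt Frame interval (s); errors if the temporal frequency exceeds
#'   the Nyquist limit `1 / (2 dt)`.
#' @param pixel_scale Degrees per pixel.
#' @param field_az,field_el Field extent (degrees); azimuth wraps.
#' @param contrast Grating Michelson contrast.
#'
#' @return Object of class `grating_probe`: list with `frames`
#'   (`rows x cols x n_frames`), `temporal_frequency` (Hz), `time`, and
#'   `probe_window` (times the probe center is on screen; `NULL` without a
#'   probe).
#' @export
make_grating_probe <- function(spatial_period, grating_speed,
                               probe = spot_spec(), duration = 1, dt = 0.02,
                               pixel_scale = 1, field_az = 360, field_el = 60,
                               contrast = 1) {
  if (spatial_period <= 0) stop("`spatial_period` must be > 0", call. = FALSE)
  tf <- grating_speed / spatial_period
  if (abs(tf) > 1 / (2 * dt)) {
    stop(sprintf("temporal frequency %.3g Hz exceeds the Nyquist limit %.3g Hz",
                 abs(tf), 1 / (2 * dt)), call. = FALSE)
  }
  nc <- round(field_az / pixel_scale)
  nr <- round(field_el / pixel_scale)
  col_az <- (seq_len(nc) - 0.5) * pixel_scale
  row_el <- (seq_len(nr) - 0.5) * pixel_scale
  times <- seq(0, duration, by = dt)
  nt <- length(times)
  frames <- array(NA_real_, c(nr, nc, nt))
  probe_el <- if (!is.null(probe)) (probe$path_elevation %||% (field_el / 2)) else NA
  probe_on <- logical(nt)
  for (i in seq_len(nt)) {
    t <- times[i]
    profile <- 0.5 + 0.5 * contrast *
      sin(2 * pi * (col_az - grating_speed * t) / spatial_period)
    fr <- matrix(profile, nr, nc, byrow = TRUE)
    if (!is.null(probe)) {
      paz <- probe$speed * t
      probe_on[i] <- paz >= 0 && paz <= field_az
      if (probe_on[i]) {
        dmat <- ang_dist(outer(rep(1, nr), col_az), outer(row_el, rep(1, nc)),
                         paz, probe_el, wrap = field_az >= 360)
        fr[dmat <= probe$diameter / 2] <- probe$intensity
      }
    }
    frames[, , i] <- fr
  }
  structure(
    list(frames = frames, temporal_frequency = tf, time = times,
         spatial_period = spatial_period, grating_speed = grating_speed,
         pixel_scale = pixel_scale,
         probe_window = if (!is.null(probe) && any(probe_on))
           range(times[probe_on]) else NULL),
    class = "grating_probe"
  )
}

#' Randomly interleaved trial order
#'
#' Produces a seeded random permutation of the multiset in which each
#' stimulus specification appears exactly `n_trials_per_spec` times.
#'
#' @param stimulus_specs Vector (or list) of stimulus identifiers.
#' @param n_trials_per_spec Trials per specification (>= 1).
#' @param seed Integer seed.
#' @return Vector of stimulus identifiers of length
#'   `length(stimulus_specs) * n_trials_per_spec`.
#' @export
interleave_trials <- function(stimulus_specs, n_trials_per_spec, seed = 1) {
  if (length(stimulus_specs) == 0) {
    stop("`stimulus_specs` must be non-empty", call. = FALSE)
  }
  if (n_trials_per_spec < 1) {
    stop("`n_trials_per_spec` must be >= 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  idx <- rep(seq_along(stimulus_specs), each = n_trials_per_spec)
  idx <- sample(idx)
  if (is.list(stimulus_specs)) stimulus_specs[idx] else stimulus_specs[idx]
}
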