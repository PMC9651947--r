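#' Circular receptive field specification
#'
#' @param center_az,center_el Receptive-field center (degrees).
#' @param diameter Diameter in degrees (hard disc).
#' @return An object of class `receptive_field`.
#' @export
receptive_field <- function(center_az, center_el, diameter = 30) {
  if (diameter <= 0) stop("`diameter` must be > 0", call. = FALSE)
  structure(list(center = c(az = center_az, el = center_el),
                 diameter = diameter),
            class = "receptive_field")
}

#' Default moving-spot specification
#'
#' A 15-degree dark spot moving horizontally at 100 deg/s, the probe used
#' throughout the gain experiments.
#'
#' @param diameter Spot diameter (degrees).
#' @param intensity Spot luminance (0 = dark).
#' @param speed Spot speed (deg/s).
#' @param path_elevation Elevation of the (horizontal) spot path; defaults to
#'   the receptive-field elevation when used in [render_trace()].
#' @return A list of class `spot_spec`.
#' @export
spot_spec <- function(diameter = 15, intensity = 0, speed = 100,
                      path_elevation = NULL) {
  structure(list(diameter = diameter, intensity = intensity, speed = speed,
                 path_elevation = path_elevation),
            class = "spot_spec")
}

# Angular distance on the equirectangular grid, with azimuthal wrap.
ang_dist <- function(az1, el1, az2, el2, wrap = TRUE) {
  daz <- az1 - az2
  if (wrap) daz <- ((daz + 180) %% 360) - 180
  sqrt(daz^2 + (el1 - el2)^2)
}

#' Render luminance/contrast traces for a spot crossing a receptive field
#'
#' Composites an opaque dark disc (the spot) on top of a background panorama
#' that rotates azimuthally at `background_speed`, then records, frame by
#' frame, the mean pixel intensity (local luminance) and the variance of
#' pixel intensities normalized by their mean (local spatial contrast)
#' within the receptive-field disc. Geometry is equirectangular: azimuth by
#' elevation with no perspective correction. The reported `window` is the
#' time interval during which the spot center lies inside the receptive
#' field disc (computed whether or not the spot is drawn, so present/absent
#' pairs share the same window).
#'
#' @param scene An [image_scene]; must wrap if `background_speed != 0`.
#' @param rf A [receptive_field].
#' @param spot A [spot_spec].
#' @param background_speed Background rotation speed (deg/s).
#' @param spot_present Draw the spot (TRUE) or background only (FALSE).
#' @param duration Trace duration (s). Default: the time for the spot to
#'   travel 3 receptive-field radii either side of the center.
#' @param dt Frame interval (s). Must satisfy
#'   `spot$speed * dt < spot$diameter`.
#' @param spot_start_az Spot center azimuth at `t = 0`. Default places the
#'   path symmetric about the receptive-field center.
#' @param background_phase Static pre-rotation of the background (degrees).
#'
#' @return An object of class `scene_trace`: list with `time`, `luminance`,
#'   `contrast`, `window` (`c(t_start, t_end)`), and the parameters used.
#' @export
render_trace <- function(scene, rf, spot = spot_spec(), background_speed = 0,
                         spot_present = TRUE, duration = NULL, dt = 0.01,
                         spot_start_az = NULL, background_phase = 0) {
  stopifnot(inherits(scene, "image_scene"), inherits(rf, "receptive_field"))
  if (spot$diameter > rf$diameter) {
    stop("spot is larger than the receptive field", call. = FALSE)
  }
  if (background_speed != 0 && !scene$wrap) {
    stop("background rotation requires a wrapping (cylindrical) scene",
         call. = FALSE)
  }
  if (spot$speed * dt >= spot$diameter) {
    stop("`dt` too coarse: spot displacement per frame exceeds spot diameter",
         call. = FALSE)
  }
  if (is.null(duration)) duration <- 3 * rf$diameter / spot$speed
  el <- spot$path_elevation %||% rf$center[["el"]]
  if (is.null(spot_start_az)) {
    spot_start_az <- rf$center[["az"]] - spot$speed * duration / 2
  }
  # Path must cross the RF center (within the elevation extent of the disc).
  if (abs(el - rf$center[["el"]]) > rf$diameter / 2) {
    stop("spot path does not cross the receptive field", call. = FALSE)
  }

  px <- scene$pixels
  nr <- nrow(px); nc <- ncol(px)
  sc <- scene$pixel_scale
  col_az <- (seq_len(nc) - 0.5) * sc[["az"]]
  row_el <- (seq_len(nr) - 0.5) * sc[["el"]]

  d_rf <- ang_dist(outer(rep(1, nr), col_az), outer(row_el, rep(1, nc)),
                   rf$center[["az"]], rf$center[["el"]], wrap = scene$wrap)
  rf_idx <- which(d_rf <= rf$diameter / 2)
  if (length(rf_idx) == 0) stop("receptive field mask is empty at this resolution",
                                call. = FALSE)
  rf_rows <- ((rf_idx - 1L) %% nr) + 1L
  rf_cols <- ((rf_idx - 1L) %/% nr) + 1L
  rf_az <- col_az[rf_cols]
  rf_el <- row_el[rf_rows]

  times <- seq(0, duration, by = dt)
  n_t <- length(times)
  lum <- numeric(n_t)
  con <- numeric(n_t)

  for (i in seq_len(n_t)) {
    t <- times[i]
    shift <- round((background_speed * t + background_phase) / sc[["az"]]) %% nc
    src_cols <- ((rf_cols - 1L - shift) %% nc) + 1L
    vals <- px[cbind(rf_rows, src_cols)]
    if (spot_present) {
      spot_az <- spot_start_az + spot$speed * t
      inside <- ang_dist(rf_az, rf_el, spot_az, el, wrap = scene$wrap) <=
        spot$diameter / 2
      vals[inside] <- spot$intensity
    }
    m <- mean(vals)
    lum[i] <- m
    con[i] <- if (m > 0) var_pop(vals) / m else NA_real_
  }

  spot_az_t <- spot_start_az + spot$speed * times
  in_rf <- ang_dist(spot_az_t, el, rf$center[["az"]], rf$center[["el"]],
                    wrap = scene$wrap) <= rf$diameter / 2
  window <- if (any(in_rf)) range(times[in_rf]) else c(NA_real_, NA_real_)

  structure(
    list(time = times, luminance = lum, contrast = con, window = window,
         spot_present = spot_present, background_speed = background_speed),
    class = "scene_trace"
  )
}

#' Ideal-observer discriminability between spot-present and spot-absent traces
#'
#' Computes `d' = (mean_present - mean_absent) / sqrt((var_present +
#' var_absent) / 2)` from the samples falling within the shared window during
#' which the spot crosses the receptive field. Variances use the population
#' (1/N) convention. For the luminance channel the sign of `d'` is inverted,
#' because a dark spot lowers local luminance (so that detectable spots give
#' positive `d'` in both channels). If the pooled variance is zero with a
#' nonzero mean difference, discrimination is perfect: the result is
#' `+/- Inf` with attribute `capped = TRUE`.
#'
#' @param present,absent [render_trace()] outputs sharing time base and window.
#' @param channel `"luminance"` or `"contrast"`.
#' @return A numeric scalar (possibly infinite, with attribute `capped`).
#' @export
dprime <- function(present, absent, channel = c("luminance", "contrast")) {
  channel <- match.arg(channel)
  stopifnot(inherits(present, "scene_trace"), inherits(absent, "scene_trace"))
  if (length(present$time) != length(absent$time) ||
      any(abs(present$time - absent$time) > 1e-9)) {
    stop("traces do not share a time base", call. = FALSE)
  }
  if (any(abs(present$window - absent$window) > 1e-9)) {
    stop("traces do not share a spot window", call. = FALSE)
  }
  idx <- present$time >= present$window[1] & present$time <= present$window[2]
  xp <- present[[channel]][idx]
  xa <- absent[[channel]][idx]
  md <- mean(xp) - mean(xa)
  pooled <- (var_pop(xp) + var_pop(xa)) / 2
  if (pooled == 0) {
    if (md == 0) return(0)
    d <- sign(md) * Inf
    if (channel == "luminance") d <- -d
    return(structure(d, capped = TRUE))
  }
  d <- md / sqrt(pooled)
  if (channel == "luminance") d <- -d
  structure(d, capped = FALSE)
}

#' Spot discriminability as a function of background speed
#'
#' Runs the ideal-observer task over a collection of background images and
#' background rotation speeds, one present/absent trace pair per
#' (image, speed, repetition), and summarizes mean +/- SEM of `d'` across
#' images per speed and channel. Each repetition uses a seeded random
#' azimuthal phase for the background so that repetitions sample different
#' parts of each panorama.
#'
#' Capped (infinite) values are retained in the per-speed summary when the
#' background is static or absent (where perfect discrimination is the
#' expected outcome) and excluded for moving backgrounds.
#'
#' @param images List of [image_scene] objects.
#' @param speeds Background speeds (deg/s, >= 0; at least 2).
#' @param rf A [receptive_field].
#' @param spot A [spot_spec].
#' @param n_reps Repetitions per (image, speed).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param dt Frame interval (s).
#'
#' @return Object of class `speed_sweep`: list with `results` (one row per
#'   image x speed x rep x channel) and `summary` (mean +/- SEM per
#'   speed x channel).
#' @export
speed_sweep <- function(images, speeds, rf, spot = spot_spec(), n_reps = 1,
                        seed = 1, dt = 0.01) {
  if (length(images) == 0) stop("`images` must be non-empty", call. = FALSE)
  if (length(speeds) < 2) stop("need at least 2 speeds", call. = FALSE)
  if (any(speeds < 0)) stop("speeds must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  phases <- matrix(stats::runif(length(images) * n_reps, 0, 360),
                   length(images), n_reps)
  rows <- list()
  k <- 1L
  for (i in seq_along(images)) {
    for (s in speeds) {
      for (r in seq_len(n_reps)) {
        pres <- render_trace(images[[i]], rf, spot, background_speed = s,
                             spot_present = TRUE, dt = dt,
                             background_phase = phases[i, r])
        abs_ <- render_trace(images[[i]], rf, spot, background_speed = s,
                             spot_present = FALSE, dt = dt,
                             background_phase = phases[i, r])
        for (ch in c("luminance", "contrast")) {
          d <- dprime(pres, abs_, ch)
          rows[[k]] <- data.frame(
            image_id = i, speed_deg_s = s, rep = r, channel = ch,
            dprime = as.numeric(d), capped = isTRUE(attr(d, "capped"))
          )
          k <- k + 1L
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(
    results, list(results$speed_deg_s, results$channel)), function(g) {
      vals <- g$dprime
      if (g$speed_deg_s[1] > 0) vals <- vals[is.finite(vals)]
      data.frame(speed_deg_s = g$speed_deg_s[1], channel = g$channel[1],
                 mean_dprime = mean(vals), sem_dprime = sem(vals[is.finite(vals)]),
                 n = length(vals))
    }))
  summary <- summary[order(summary$channel, summary$speed_deg_s), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary), class = "speed_sweep")
}

#' @export
print.speed_sweep <- function(x, ...) {
  cat("<speed_sweep>\n")
  print(x$summary)
  invisible(x)
}
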