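DATASET_LAYOUT_VERSION <- "1.0"

#' Write a trial tensor dataset
#'
#' Serializes a [trial_tensor] (responses, labels, behavior, and optional
#' ground truth) to a single JSON file. Numbers are written at full
#' precision, so a write-then-read round trip reproduces the dataset
#' exactly. The layout carries a version string; reading a file with a
#' different layout version is an explicit error.
#'
#' @param tensor A [trial_tensor].
#' @param path Output file path (`.json`).
#' @param truth Optional ground-truth list (as from [generate_trials()]).
#' @return `path`, invisibly.
#' @export
write_trial_tensor <- function(tensor, path, truth = NULL) {
  stopifnot(inherits(tensor, "trial_tensor"))
  payload <- list(
    layout_version = DATASET_LAYOUT_VERSION,
    dims = dim(tensor$dff),
    dff = as.numeric(tensor$dff),
    raw_f = if (!is.null(tensor$raw_f)) as.numeric(tensor$raw_f),
    time = tensor$time,
    labels = tensor$labels,
    epoch = tensor$epoch,
    behavior_amplitude = tensor$behavior_amplitude,
    glomerulus_names = tensor$glomerulus_names,
    truth = truth
  )
  payload <- payload[!vapply(payload, is.null, logical(1))]
  # digits = I(17): 17 significant digits guarantee an exact double
  # round-trip, which `digits = NA` (15 significant digits) does not.
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a trial tensor dataset
#'
#' @param path File written by [write_trial_tensor()].
#' @return List with `tensor` (a [trial_tensor]) and `truth` (or `NULL`).
#' @export
read_trial_tensor <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$layout_version) ||
      !identical(payload$layout_version, DATASET_LAYOUT_VERSION)) {
    stop(sprintf("dataset layout version mismatch: file '%s', reader '%s'",
                 payload$layout_version %||% "<missing>",
                 DATASET_LAYOUT_VERSION), call. = FALSE)
  }
  dims <- as.integer(payload$dims)
  dff <- array(as.numeric(payload$dff), dims)
  raw_f <- if (!is.null(payload$raw_f)) array(as.numeric(payload$raw_f), dims)
  tensor <- trial_tensor(
    dff, payload$time, payload$labels, payload$epoch,
    behavior_amplitude = payload$behavior_amplitude,
    glomerulus_names = payload$glomerulus_names,
    raw_f = raw_f
  )
  list(tensor = tensor, truth = payload$truth)
}

#' Default experiment configuration
#'
#' A single global seed expands deterministically into per-stage child
#' seeds (see the documented scheme in [expand_seeds()]-style derivation),
#' so any stage can be rerun in isolation.
#'
#' @param seed Global seed.
#' @param out_dir Output directory (created on demand).
#' @return A `run_config` list with per-module parameter blocks.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("glomcode_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    scenes = list(height_px = 64, width_px = 256, pixel_scale = c(1.40625, 1),
                  slope = -2, n_images = 20),
    discrimination = list(speeds = c(0, 20, 40, 80, 160, 320),
                          rf_diameter = 30, spot_diameter = 15,
                          spot_speed = 100, dt = 0.01),
    generator = list(n_glomeruli = 13, n_stimuli = 10, n_groups = 4,
                     n_trials_per_stim = 30, gain_sd = 0.4, noise_sd = 0.05,
                     behavior_coupling = -1, n_modulated = 5),
    decoding = list(train_frac = 0.9, n_iterations = 100, lambda = 0.001),
    behavior = list(duration_s = 300, saccade_rate_hz = 0.8,
                    refractory_s = 0.5, dt = 0.02, speed_threshold = 160),
    gain = list(n_glomeruli = 8, n_trials_per_cell = 50, interaction = 0,
                noise_cv = 0.25, n_boot = 1000),
    verbosity = 1L
  ), class = "run_config")
}

validate_config <- function(config) {
  if (!inherits(config, "run_config")) {
    stop("`config` must be a run_config (see default_config())", call. = FALSE)
  }
  need <- c("seed", "out_dir", "scenes", "discrimination", "generator",
            "decoding", "behavior", "gain")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    stop(sprintf("config missing block(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  invisible(config)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_sidecar <- function(config, experiment, outputs, dir) {
  sidecar <- list(
    experiment = experiment,
    seed = config$seed,
    config_hash = config_hash(config),
    parameters = unclass(config),
    outputs = outputs,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, paste0(experiment, ".provenance.json"))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  path
}

log_stage <- function(config, fmt, ...) {
  if ((config$verbosity %||% 1L) > 0) message(sprintf(fmt, ...))
}

#' Run an end-to-end experiment on synthetic data
#'
#' Each experiment generates its synthetic inputs, runs the corresponding
#' analysis chain, writes result tables (CSV) plus a machine-readable
#' summary (JSON) with all seeds and parameters, and returns the result
#' bundle. Reruns with the same config are deterministic.
#'
#' Experiments:
#' \describe{
#'   \item{`spot_discriminability`}{spot d' versus background speed over a
#'     collection of 1/f^2 surrogate images.}
#'   \item{`stimulus_decoding`}{stimulus decoding from generator trial tensors,
#'     intact versus trial-shuffled.}
#'   \item{`behavior_gain`}{gain-behavior Spearman correlations across
#'     simulated flies with Holm correction, plus gain vs walking
#'     amplitude.}
#'   \item{`saccade_statistics`}{saccade detection and inter-turn-interval
#'     statistics on generated walking.}
#'   \item{`gain_independence`}{visual x motor gain-independence test on a
#'     simulated two-factor gain experiment.}
#' }
#'
#' @param config A `run_config` (see [default_config()]).
#' @param experiment Experiment name (see Details).
#' @return List with `summary` (also written as JSON), `tables`, and paths
#'   of files written.
#' @export
run_experiment <- function(config = default_config(),
                           experiment = c("spot_discriminability",
                                          "stimulus_decoding",
                                          "behavior_gain",
                                          "saccade_statistics",
                                          "gain_independence")) {
  experiment <- match.arg(experiment)
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- expand_seeds(config$seed, 8)

  result <- switch(
    experiment,
    spot_discriminability = {
      p <- config$scenes; q <- config$discrimination
      log_stage(config, "[discriminability] generating %d surrogate images", p$n_images)
      images <- lapply(seq_len(p$n_images), function(i) {
        generate_pink_image(p$height_px, p$width_px, p$pixel_scale,
                            slope = p$slope,
                            seed = (seeds[1] + i) %% .Machine$integer.max)
      })
      rf <- receptive_field(180, p$height_px * p$pixel_scale[2] / 2,
                            q$rf_diameter)
      spot <- spot_spec(q$spot_diameter, 0, q$spot_speed)
      log_stage(config, "[discriminability] sweeping %d speeds", length(q$speeds))
      sw <- speed_sweep(images, q$speeds, rf, spot, seed = seeds[2], dt = q$dt)
      nz <- subset(sw$summary, speed_deg_s > 0)
      rho <- vapply(split(nz, nz$channel), function(g) {
        stats::cor(g$speed_deg_s, g$mean_dprime, method = "spearman")
      }, numeric(1))
      list(tables = list(results = sw$results, summary = sw$summary),
           summary = list(spearman_speed_vs_dprime = as.list(rho),
                          n_images = p$n_images))
    },
    stimulus_decoding = {
      p <- config$generator; q <- config$decoding
      log_stage(config, "[decoding] generating trial tensor")
      tun <- generate_tuning(p$n_glomeruli, p$n_stimuli, p$n_groups,
                             seed = seeds[1])
      gen <- generate_trials(tun, p$n_trials_per_stim, gain_sd = p$gain_sd,
                             noise_sd = p$noise_sd, seed = seeds[2])
      amps <- peak_amplitudes(gen$tensor)
      log_stage(config, "[decoding] decoding intact and shuffled inputs")
      intact <- decode_stimulus(amps, q$train_frac, q$n_iterations,
                                seed = seeds[3], lambda = q$lambda)
      shuf <- decode_stimulus(shuffle_trials(amps, seed = seeds[4]),
                              q$train_frac, q$n_iterations,
                              seed = seeds[3], lambda = q$lambda)
      list(tables = list(confusion = as.data.frame(as.table(intact$confusion))),
           summary = list(
             accuracy_intact = intact$overall_accuracy,
             accuracy_shuffled = shuf$overall_accuracy,
             shuffle_decrement_pct =
               100 * (1 - shuf$overall_accuracy / intact$overall_accuracy),
             chance = 1 / p$n_stimuli))
    },
    behavior_gain = {
      p <- config$generator
      n_flies <- 8
      log_stage(config, "[behavior-gain] simulating %d flies", n_flies)
      modulated <- seq_len(p$n_modulated)
      rho <- matrix(NA_real_, n_flies, p$n_glomeruli)
      tun <- generate_tuning(p$n_glomeruli, 1, 1, seed = seeds[1])
      for (f in seq_len(n_flies)) {
        gen <- generate_trials(tun, n_trials_per_stim = 100,
                               gain_sd = p$gain_sd, noise_sd = p$noise_sd,
                               behavior_coupling = p$behavior_coupling,
                               modulated = modulated,
                               seed = (seeds[2] + f) %% .Machine$integer.max)
        amps <- peak_amplitudes(gen$tensor)
        rho[f, ] <- behavior_correlation(amps, gen$tensor$behavior_amplitude)
      }
      colnames(rho) <- tun$glomerulus_names
      agg <- aggregate_behavior_correlation(rho)
      gen <- generate_trials(tun, n_trials_per_stim = 100,
                             gain_sd = p$gain_sd, noise_sd = p$noise_sd,
                             behavior_coupling = p$behavior_coupling,
                             modulated = modulated, seed = seeds[3])
      curve <- gain_vs_walking(peak_amplitudes(gen$tensor),
                               gen$tensor$behavior_amplitude)
      list(tables = list(rho_table = agg,
                         gain_curve = data.frame(walking = curve$x,
                                                 gain = curve$y,
                                                 sem = curve$sem)),
           summary = list(
             n_significant_modulated = sum(agg$significant[modulated]),
             n_significant_unmodulated =
               sum(agg$significant[-modulated]),
             mean_rho_modulated = mean(agg$mean_rho[modulated])))
    },
    saccade_statistics = {
      p <- config$behavior
      log_stage(config, "[saccades] generating %g s walking trace", p$duration_s)
      walk <- generate_walking(p$duration_s, p$saccade_rate_hz,
                               p$refractory_s, dt = p$dt, seed = seeds[1])
      ev <- detect_saccades(walk$trace$rot_z, p$dt, p$speed_threshold)
      st <- saccade_cycle_stats(ev, walk$trajectory$angular_velocity,
                                walk$trajectory$forward_velocity, p$dt)
      matched <- vapply(walk$saccade_times, function(on) {
        any(abs(ev$onset_times - on) <= 0.05)
      }, logical(1))
      list(tables = list(events = data.frame(onset_s = ev$onset_times,
                                             peak_speed = ev$peak_speeds)),
           summary = list(
             n_true = length(walk$saccade_times),
             n_detected = length(ev$onset_times),
             recall_50ms = mean(matched),
             frac_iti_below_refractory =
               mean(ev$inter_turn_intervals < p$refractory_s)))
    },
    gain_independence = {
      p <- config$gain
      log_stage(config, "[independence] simulating two-factor gain experiment")
      sim <- simulate_gain_experiment(p$n_glomeruli, p$n_trials_per_cell,
                                      interaction = p$interaction,
                                      noise_cv = p$noise_cv, seed = seeds[1])
      res <- independence_test(sim$data, n_boot = p$n_boot, seed = seeds[2])
      covers <- res$ci_lo <= 0 & res$ci_hi >= 0
      list(tables = list(independence = as.data.frame(res)),
           summary = list(
             frac_ci_covering_zero = mean(covers),
             mean_deviation = mean(res$deviation)))
    }
  )

  files <- character(0)
  for (nm in names(result$tables)) {
    f <- file.path(config$out_dir, sprintf("%s_%s.csv", experiment, nm))
    utils::write.csv(result$tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  summary_path <- file.path(config$out_dir,
                            sprintf("%s_summary.json", experiment))
  jsonlite::write_json(c(list(experiment = experiment, seed = config$seed),
                         result$summary),
                       summary_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, summary_path)
  sidecar <- write_sidecar(config, experiment, basename(files),
                           config$out_dir)
  files <- c(files, sidecar)
  log_stage(config, "[%s] wrote %d files to %s", experiment, length(files),
            config$out_dir)
  invisible(list(summary = result$summary, tables = result$tables,
                 files = files))
}
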