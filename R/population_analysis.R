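#' Convert raw fluorescence to dF/F
#'
#' `dF/F = (F - F0) / F0` per glomerulus per trial, where `F0` is the mean
#' fluorescence over a pre-stimulus baseline window.
#'
#' @param raw_f 3D array, glomeruli x trials x timepoints.
#' @param time Timepoints (s) relative to stimulus onset.
#' @param baseline_window `c(t0, t1)` with `t1 <= 0` (before onset).
#' @return Array of dF/F values, same shape as `raw_f`.
#' @export
compute_dff <- function(raw_f, time, baseline_window = c(-1.5, 0)) {
  stopifnot(length(dim(raw_f)) == 3L, length(time) == dim(raw_f)[3])
  if (baseline_window[2] > 0) {
    stop("baseline window must precede stimulus onset", call. = FALSE)
  }
  idx <- which(time >= baseline_window[1] & time <= baseline_window[2])
  if (length(idx) == 0) stop("baseline window contains no samples", call. = FALSE)
  d <- dim(raw_f)
  dff <- array(NA_real_, d)
  for (g in seq_len(d[1])) {
    for (tr in seq_len(d[2])) {
      f0 <- mean(raw_f[g, tr, idx])
      if (!is.finite(f0) || f0 <= 0) {
        stop(sprintf("non-positive baseline F0 for glomerulus %d, trial %d",
                     g, tr), call. = FALSE)
      }
      dff[g, tr, ] <- (raw_f[g, tr, ] - f0) / f0
    }
  }
  dff
}

#' Amplitude matrix container
#'
#' Trials x glomeruli peak-response matrix with stimulus labels; the
#' canonical single-trial response statistic for decoding, correlation, and
#' gain analyses.
#'
#' @param values Numeric matrix, trials x glomeruli (finite).
#' @param labels Stimulus identity per trial (length `nrow(values)`).
#' @param z_scored Flag.
#' @return Object of class `amplitude_matrix`.
#' @export
amplitude_matrix <- function(values, labels, z_scored = FALSE) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("`values` must be finite", call. = FALSE)
  if (length(labels) != nrow(values)) {
    stop("`labels` length must equal the number of trials (rows)", call. = FALSE)
  }
  structure(list(values = values, labels = labels, z_scored = isTRUE(z_scored)),
            class = "amplitude_matrix")
}

#' @export
print.amplitude_matrix <- function(x, ...) {
  cat(sprintf("<amplitude_matrix> %d trials x %d glomeruli, %d stimuli%s\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels)),
              if (x$z_scored) " (z-scored)" else ""))
  invisible(x)
}

#' Peak response amplitudes per glomerulus per trial
#'
#' Maximum dF/F within a response window, the scalar response statistic
#' used throughout the downstream analyses.
#'
#' @param tensor A [trial_tensor].
#' @param response_window `c(t0, t1)` in seconds relative to stimulus onset;
#'   default the stimulus epoch.
#' @return An [amplitude_matrix] (trials x glomeruli).
#' @export
peak_amplitudes <- function(tensor, response_window = NULL) {
  stopifnot(inherits(tensor, "trial_tensor"))
  if (is.null(response_window)) response_window <- c(0, tensor$epoch[2])
  idx <- which(tensor$time >= response_window[1] &
                 tensor$time <= response_window[2])
  if (length(idx) == 0) stop("response window contains no samples", call. = FALSE)
  vals <- apply(tensor$dff[, , idx, drop = FALSE], c(1, 2), max)
  vals <- t(vals) # trials x glomeruli
  colnames(vals) <- tensor$glomerulus_names
  amplitude_matrix(vals, tensor$labels)
}

#' Trial-to-trial (noise) correlation matrix
#'
#' Pearson correlations of peak amplitudes across trials, computed within
#' each stimulus (so stimulus-driven tuning differences do not contribute)
#' and then averaged across stimuli. Glomeruli with zero variance within a
#' stimulus have undefined correlations; those entries are excluded from
#' the average with a warning.
#'
#' @param amps An [amplitude_matrix].
#' @param per_stimulus If `TRUE` (default) correlate within stimulus and
#'   average; if `FALSE`, correlate across all trials pooled.
#' @return Object of class `correlation_matrix`: list with `values`
#'   (symmetric, unit diagonal), `n_trials_used`, `aggregation`.
#' @export
trial_correlations <- function(amps, per_stimulus = TRUE) {
  stopifnot(inherits(amps, "amplitude_matrix"))
  x <- amps$values
  if (per_stimulus) {
    stims <- unique(amps$labels)
    mats <- list()
    n_used <- 0L
    for (s in stims) {
      rows <- which(amps$labels == s)
      if (length(rows) < 3) next
      xs <- x[rows, , drop = FALSE]
      sds <- apply(xs, 2, stats::sd)
      if (any(sds == 0)) {
        warning(sprintf(
          "zero-variance glomerulus within stimulus '%s'; correlations excluded",
          s), call. = FALSE)
      }
      cm <- suppressWarnings(stats::cor(xs))
      cm[!is.finite(cm)] <- NA
      mats[[length(mats) + 1L]] <- cm
      n_used <- n_used + length(rows)
    }
    if (length(mats) == 0) stop("need >= 3 trials per stimulus", call. = FALSE)
    arr <- simplify2array(mats)
    values <- apply(arr, c(1, 2), mean, na.rm = TRUE)
    aggregation <- "averaged"
  } else {
    if (nrow(x) < 3) stop("need >= 3 trials", call. = FALSE)
    values <- stats::cor(x)
    n_used <- nrow(x)
    aggregation <- "pooled"
  }
  diag(values) <- 1
  structure(list(values = values, n_trials_used = n_used,
                 aggregation = aggregation),
            class = "correlation_matrix")
}

#' Functional clustering of glomerulus tuning
#'
#' Agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance) of mean response vectors, cut at `n_clusters`.
#'
#' @param tuning A [generate_tuning()] object or a numeric matrix
#'   (glomeruli x stimuli).
#' @param n_clusters Number of clusters (<= number of glomeruli).
#' @return List with `labels` (integer per glomerulus) and `tree`
#'   (an [stats::hclust] object).
#' @export
cluster_tuning <- function(tuning, n_clusters = 4) {
  values <- if (inherits(tuning, "tuning_matrix")) tuning$values else as.matrix(tuning)
  if (anyNA(values)) stop("tuning matrix contains NAs", call. = FALSE)
  if (n_clusters > nrow(values)) {
    stop("`n_clusters` must be <= number of glomeruli", call. = FALSE)
  }
  tree <- stats::hclust(stats::dist(values), method = "complete")
  labels <- stats::cutree(tree, k = n_clusters)
  list(labels = labels, tree = tree)
}

#' Shared trial-to-trial gain factor
#'
#' Estimates the single multiplicative gain that co-modulates the
#' population on each trial as the first principal component of the
#' trials x glomeruli amplitude matrix after removing each glomerulus's
#' per-stimulus mean (so the component reflects trial-to-trial, not tuning,
#' variance). The loading vector is oriented to have a positive mean, the
#' gain convention: a larger score means a globally stronger trial.
#'
#' @param amps An [amplitude_matrix] with >= 2 glomeruli and >= 3 trials.
#' @return List with `score` (per-trial gain score), `loadings`
#'   (per glomerulus), `var_explained` (fraction in `[0, 1]`).
#' @export
shared_gain <- function(amps) {
  stopifnot(inherits(amps, "amplitude_matrix"))
  x <- amps$values
  if (ncol(x) < 2) stop("need >= 2 glomeruli", call. = FALSE)
  if (nrow(x) < 3) stop("need >= 3 trials", call. = FALSE)
  for (s in unique(amps$labels)) {
    rows <- amps$labels == s
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2,
                       colMeans(x[rows, , drop = FALSE]))
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  v <- pc$rotation[, 1]
  score <- pc$x[, 1]
  if (mean(v) < 0) {
    v <- -v
    score <- -score
  }
  list(score = unname(score), loadings = v,
       var_explained = unname(pc$sdev[1]^2 / sum(pc$sdev^2)))
}

#' Per-glomerulus gain-behavior correlation (single fly)
#'
#' Spearman's rho between single-trial response amplitudes and the
#' walking amplitude on the corresponding trials.
#'
#' @param amps An [amplitude_matrix].
#' @param behavior_amplitude Walking amplitude per trial.
#' @return Named numeric vector of rho, one per glomerulus.
#' @export
behavior_correlation <- function(amps, behavior_amplitude) {
  stopifnot(inherits(amps, "amplitude_matrix"))
  if (length(behavior_amplitude) != nrow(amps$values)) {
    stop("behavior must be aligned per trial", call. = FALSE)
  }
  if (stats::sd(behavior_amplitude) == 0) {
    stop("behavior vector is constant", call. = FALSE)
  }
  apply(amps$values, 2, stats::cor, y = behavior_amplitude,
        method = "spearman")
}

#' Across-fly test for negative gain-behavior correlation
#'
#' Aggregates per-fly Spearman rho values with a one-sample, one-sided
#' t-test per glomerulus (H1: mean rho < 0), followed by Holm (step-down
#' Bonferroni) correction across glomeruli at level `alpha`.
#'
#' @param rho_by_fly Matrix of Spearman rho, flies x glomeruli.
#' @param alpha Significance criterion after correction.
#' @return Data frame with per-glomerulus `mean_rho`, `t`, `p`, `p_holm`,
#'   `significant`.
#' @export
aggregate_behavior_correlation <- function(rho_by_fly, alpha = 0.05) {
  rho_by_fly <- as.matrix(rho_by_fly)
  if (nrow(rho_by_fly) < 2) stop("need >= 2 flies", call. = FALSE)
  res <- apply(rho_by_fly, 2, function(r) {
    tt <- stats::t.test(r, mu = 0, alternative = "less")
    c(mean_rho = mean(r), t = unname(tt$statistic), p = tt$p.value)
  })
  out <- as.data.frame(t(res))
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out$significant <- out$p_holm < alpha
  out$glomerulus <- colnames(rho_by_fly) %||% seq_len(ncol(rho_by_fly))
  rownames(out) <- NULL
  out[, c("glomerulus", "mean_rho", "t", "p", "p_holm", "significant")]
}

#' Decode stimulus identity from single-trial population amplitudes
#'
#' Multinomial logistic regression (ridge-penalized, fixed L2 strength) on
#' the trials x glomeruli peak-amplitude matrix. Each iteration draws a
#' stratified train/test split (`train_frac` of trials per class),
#' z-scores each glomerulus using training-fold statistics only, fits the
#' model, and evaluates held-out accuracy. Accuracies and the
#' row-normalized confusion matrix are averaged across iterations.
#'
#' @param amps An [amplitude_matrix]; >= 2 classes and >= 2 trials per class.
#' @param train_frac Training fraction per class.
#' @param n_iterations Number of train/test iterations.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param lambda L2 penalty strength.
#' @return Object of class `decoding_result`: list with `overall_accuracy`,
#'   `per_class_accuracy`, `confusion` (rows sum to 1), `n_iterations`,
#'   `shuffled` flag (FALSE here; see [shuffle_trials()]).
#' @export
decode_stimulus <- function(amps, train_frac = 0.9, n_iterations = 100,
                            seed = 1, lambda = 0.001) {
  stopifnot(inherits(amps, "amplitude_matrix"))
  x <- amps$values
  y <- factor(amps$labels)
  classes <- levels(y)
  k <- length(classes)
  if (k < 2) stop("need >= 2 stimulus classes", call. = FALSE)
  counts <- table(y)
  if (any(counts < 2)) {
    stop(sprintf("class '%s' has fewer than 2 trials",
                 names(counts)[which.min(counts)]), call. = FALSE)
  }
  set.seed(as.integer(seed))
  confusion <- matrix(0, k, k, dimnames = list(classes, classes))
  acc <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    test_idx <- unlist(lapply(classes, function(cl) {
      rows <- which(y == cl)
      n_test <- max(1L, round((1 - train_frac) * length(rows)))
      sample(rows, n_test)
    }))
    train_idx <- setdiff(seq_along(y), test_idx)
    mu <- colMeans(x[train_idx, , drop = FALSE])
    sdv <- apply(x[train_idx, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    xtr <- sweep(sweep(x[train_idx, , drop = FALSE], 2, mu), 2, sdv, `/`)
    xte <- sweep(sweep(x[test_idx, , drop = FALSE], 2, mu), 2, sdv, `/`)
    # Fit along a decreasing lambda path ending at the target penalty:
    # coordinate descent warm-starts along the path, whereas a cold-start
    # single-lambda multinomial fit can terminate far from the optimum.
    path <- exp(seq(log(10), log(lambda), length.out = 15))
    fit <- glmnet::glmnet(xtr, y[train_idx], family = "multinomial",
                          alpha = 0, lambda = path, standardize = FALSE)
    pred <- predict(fit, xte, type = "class", s = lambda, exact = FALSE)
    pred <- factor(as.character(pred), levels = classes)
    truth <- y[test_idx]
    acc[it] <- mean(pred == truth)
    confusion <- confusion + table(truth, pred)
  }
  conf <- sweep(confusion, 1, rowSums(confusion), `/`)
  structure(
    list(overall_accuracy = mean(acc),
         per_class_accuracy = diag(conf),
         confusion = conf,
         accuracy_by_iteration = acc,
         n_iterations = n_iterations,
         shuffled = isTRUE(attr(amps, "shuffled"))),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> overall accuracy %.3f over %d iterations (chance %.3f)%s\n",
              x$overall_accuracy, x$n_iterations, 1 / nrow(x$confusion),
              if (x$shuffled) " [trial-shuffled input]" else ""))
  invisible(x)
}

#' Trial-shuffle control for noise correlations
#'
#' Independently permutes response amplitudes across trials of the same
#' stimulus identity for each glomerulus. Per-stimulus, per-glomerulus
#' means and variances are exactly preserved (permutation), while
#' cross-glomerulus trial-to-trial correlations are destroyed in
#' expectation.
#'
#' @param amps An [amplitude_matrix].
#' @param seed Integer seed.
#' @return An [amplitude_matrix] with attribute `shuffled = TRUE`.
#' @export
shuffle_trials <- function(amps, seed = 1) {
  stopifnot(inherits(amps, "amplitude_matrix"))
  set.seed(as.integer(seed))
  x <- amps$values
  for (s in unique(amps$labels)) {
    rows <- which(amps$labels == s)
    for (g in seq_len(ncol(x))) {
      x[rows, g] <- x[rows[sample.int(length(rows))], g]
    }
  }
  out <- amplitude_matrix(x, amps$labels, amps$z_scored)
  attr(out, "shuffled") <- TRUE
  out
}
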