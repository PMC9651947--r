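# Independent oracles used across the suite. These deliberately re-derive
# each quantity from its definition (naive loops, direct formulas) and must
# stay independent of the package implementation paths they check.

# d-prime from the printed definition, straight off the formula.
oracle_dprime <- function(xp, xa, invert = FALSE) {
  vp <- mean((xp - mean(xp))^2)
  va <- mean((xa - mean(xa))^2)
  d <- (mean(xp) - mean(xa)) / sqrt((vp + va) / 2)
  if (invert) -d else d
}

# Li cross-entropy criterion evaluated naively, and its exhaustive-scan
# minimizer over midpoints of sorted unique values.
oracle_li_criterion <- function(values, t) {
  below <- values[values < t]
  above <- values[values >= t]
  ce <- 0
  if (length(below) > 0 && mean(below) > 0) {
    for (x in below) ce <- ce - x * log(mean(below))
  }
  if (length(above) > 0 && mean(above) > 0) {
    for (x in above) ce <- ce - x * log(mean(above))
  }
  ce
}

oracle_li_threshold <- function(values) {
  u <- sort(unique(values))
  cand <- (u[-1] + u[-length(u)]) / 2
  crit <- vapply(cand, function(t) oracle_li_criterion(values, t), numeric(1))
  cand[which.min(crit)]
}

# Hand-stepped Holm (step-down Bonferroni) rejection decisions at level
# alpha: sort ascending, compare p_(i) <= alpha / (m - i + 1), stop at the
# first failure.
oracle_holm_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) {
      reject[ord[i]] <- TRUE
    } else {
      break
    }
  }
  reject
}

# Circular resultant length of a set of directions in degrees.
circular_resultant <- function(deg) {
  Mod(sum(exp(1i * deg * pi / 180))) / length(deg)
}

# Build a scene_trace directly (for formula-level d-prime tests).
fake_trace <- function(values, channel = "contrast", dt = 0.1) {
  n <- length(values)
  tr <- list(time = seq(0, by = dt, length.out = n),
             luminance = values, contrast = values,
             window = c(0, (n - 1) * dt),
             spot_present = NA, background_speed = 0)
  class(tr) <- "scene_trace"
  tr
}

# Small deterministic pink-image cache shared by scene tests.
test_pink <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_pink_image(64, 256, c(1.40625, 1), slope = -2,
                                    seed = 101)
    }
    cache
  }
})
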