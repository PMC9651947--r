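#' Panoramic image scene
#'
#' Container for a 2D luminance panorama used as a visual background. Rows
#' index elevation and columns index azimuth. When `wrap = TRUE` the azimuth
#' axis is treated as periodic (a cylindrical panorama), which requires the
#' image to span at least 360 degrees of azimuth.
#'
#' @param pixels Numeric matrix of non-negative luminance values
#'   (rows = elevation, columns = azimuth).
#' @param pixel_scale Degrees of visual angle per pixel; either a single
#'   value or `c(az, el)`.
#' @param wrap Logical; is azimuth periodic?
#'
#' @return An object of class `image_scene` with elements `pixels`,
#'   `pixel_scale` (named `az`/`el`) and `wrap`.
#' @export
image_scene <- function(pixels, pixel_scale, wrap = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(pixels))) stop("`pixels` must be finite", call. = FALSE)
  if (length(pixel_scale) == 1L) pixel_scale <- rep(pixel_scale, 2L)
  pixel_scale <- as.numeric(pixel_scale)
  if (any(pixel_scale <= 0)) stop("`pixel_scale` must be > 0", call. = FALSE)
  names(pixel_scale) <- c("az", "el")
  if (isTRUE(wrap) && ncol(pixels) * pixel_scale[["az"]] < 360 - 1e-9) {
    stop("a wrapping scene must cover >= 360 degrees of azimuth", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_scale = pixel_scale, wrap = isTRUE(wrap)),
    class = "image_scene"
  )
}

#' @export
print.image_scene <- function(x, ...) {
  cat(sprintf(
    "<image_scene> %d x %d px (%.3g x %.3g deg/px)%s\n",
    nrow(x$pixels), ncol(x$pixels),
    x$pixel_scale[["el"]], x$pixel_scale[["az"]],
    if (x$wrap) ", azimuth wraps" else ""
  ))
  invisible(x)
}

#' @export
dim.image_scene <- function(x) dim(x$pixels)

# 2D spatial frequency magnitude grid (cycles/degree) matching fft() layout.
freq_grid <- function(nr, nc, pixel_scale) {
  fr <- fft_freq(nr, pixel_scale[["el"]])
  fc <- fft_freq(nc, pixel_scale[["az"]])
  sqrt(outer(fr^2, fc^2, `+`))
}

fft_freq <- function(n, d) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

#' Generate a surrogate natural image with a power-law spectrum
#'
#' Synthesizes a grayscale panorama whose radially averaged power spectrum
#' follows `p ~ f^slope` over low spatial frequencies. With `slope = -2`
#' these images reproduce the long-range intensity correlations and
#' low-spatial-frequency dominance characteristic of natural scenes; with
#' `slope = 0` they are white noise. Spectral synthesis: a white-noise field
#' is transformed to the frequency domain and its amplitudes are reweighted
#' by `f^(slope/2)` (DC removed), which guarantees the target spectrum in
#' expectation while keeping phases random.
#'
#' The result is rescaled to mean 0.5 with pixel standard deviation
#' `contrast_sd` and clipped to `[0, 1]`.
#'
#' @param height_px,width_px Image size in pixels (both >= 32).
#' @param pixel_scale Degrees per pixel (scalar or `c(az, el)`).
#' @param slope Log-log spectral slope; must be <= 0.
#' @param seed Integer seed; the image is deterministic given the seed.
#' @param contrast_sd Pixel standard deviation before clipping.
#' @param wrap Mark the scene as azimuthally periodic (default TRUE; the
#'   synthesis is periodic by construction).
#'
#' @return An [image_scene].
#' @export
generate_pink_image <- function(height_px, width_px, pixel_scale = 1,
                                slope = -2, seed = 1, contrast_sd = 0.2,
                                wrap = TRUE) {
  if (height_px < 32 || width_px < 32) {
    stop("image dimensions must be >= 32 pixels", call. = FALSE)
  }
  if (slope > 0) stop("`slope` must be <= 0", call. = FALSE)
  if (length(pixel_scale) == 1L) pixel_scale <- rep(pixel_scale, 2L)
  names(pixel_scale) <- c("az", "el")

  set.seed(as.integer(seed))
  white <- matrix(stats::rnorm(height_px * width_px), height_px, width_px)
  f <- freq_grid(height_px, width_px, pixel_scale)
  amp <- f
  amp[f > 0] <- f[f > 0]^(slope / 2)
  amp[1, 1] <- 0 # zero DC; mean set explicitly below
  spec <- stats::fft(white) * amp
  img <- Re(stats::fft(spec, inverse = TRUE)) / (height_px * width_px)
  if (!all(is.finite(img))) stop("non-finite pixels in spectral synthesis", call. = FALSE)

  s <- stats::sd(img)
  if (s > 0) img <- img / s * contrast_sd
  img <- img + 0.5
  img <- pmin(pmax(img, 0), 1)
  image_scene(img, pixel_scale, wrap = wrap)
}

#' Radially averaged power spectrum and low-frequency slope
#'
#' Estimates the 2D power spectrum of a scene by Welch's method --
#' Hann-windowed, 50%-overlapping azimuthal segments whose periodograms are
#' averaged -- then reports the radially binned spectrum and fits a log-log
#' slope by least squares on the averaged periodogram ordinates within a
#' stated frequency band. Segment averaging reduces the variance of each
#' ordinate roughly `n_segments`-fold, which is what makes a single-image
#' slope estimate usable. Each segment is mean-subtracted and the DC
#' ordinate is excluded, so the estimate is invariant to adding a constant
#' to the image.
#'
#' @param image An [image_scene].
#' @param band Fit band `c(f_lo, f_hi)` in cycles/degree; must lie within
#'   the resolvable range (above 0, at or below Nyquist).
#' @param n_bins Number of radial bins spanning the resolvable range.
#' @param n_segments Number of overlapping azimuthal segments (1 = plain
#'   periodogram of the full image).
#'
#' @return An object of class `spectrum_estimate`: list with `frequency`
#'   (radial bin centers, cycles/degree), `power` (mean power per bin),
#'   `fitted_slope`, and `band`.
#' @export
estimate_spectrum <- function(image, band = c(0.01, 0.2), n_bins = 40,
                              n_segments = 4) {
  stopifnot(inherits(image, "image_scene"))
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  nyq <- min(1 / (2 * image$pixel_scale))
  if (band[1] <= 0 || band[2] > nyq + 1e-12 || band[1] >= band[2]) {
    stop(sprintf("fit band must lie within (0, %.4g] cycles/degree", nyq),
         call. = FALSE)
  }
  w_seg <- if (n_segments > 1) floor(nc / ((n_segments + 1) / 2)) else nc
  if (w_seg < 8) stop("image too narrow for the requested segmentation",
                      call. = FALSE)
  starts <- if (n_segments > 1) {
    round(seq(1, nc - w_seg + 1, length.out = n_segments))
  } else 1L
  win <- outer(hann(nr), hann(w_seg))
  p <- 0
  for (s in starts) {
    seg <- px[, s:(s + w_seg - 1L), drop = FALSE]
    seg <- (seg - mean(seg)) * win
    p <- p + Mod(stats::fft(seg))^2
  }
  p <- p / (length(starts) * nr * w_seg * mean(win^2))
  f <- freq_grid(nr, w_seg, image$pixel_scale)

  keep <- f > 0 & f <= nyq
  fmin <- min(f[keep])
  edges <- exp(seq(log(fmin * 0.999), log(nyq), length.out = n_bins + 1L))
  bin <- findInterval(f[keep], edges, rightmost.closed = TRUE)
  power <- tapply(p[keep], bin, mean)
  freq <- tapply(f[keep], bin, mean)
  ord <- order(freq)
  freq <- as.numeric(freq[ord]); power <- as.numeric(power[ord])

  pt <- f[keep] >= band[1] & f[keep] <= band[2] & p[keep] > 0
  if (sum(pt) < 2) {
    stop("no spectral support in the fit band (constant image?)", call. = FALSE)
  }
  fit <- stats::lm(log(p[keep][pt]) ~ log(f[keep][pt]))
  structure(
    list(frequency = freq, power = power,
         fitted_slope = unname(stats::coef(fit)[2L]), band = band),
    class = "spectrum_estimate"
  )
}

hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate> %d radial bins, slope %.3f over [%.3g, %.3g] c/deg\n",
              length(x$frequency), x$fitted_slope, x$band[1], x$band[2]))
  invisible(x)
}

#' Spatial-frequency filtering of a scene
#'
#' Applies radially symmetric Gaussian transfer functions in the frequency
#' domain. `lowpass` uses `H(f) = exp(-log(2)/2 * (f/cutoff)^2)` (half-power
#' at `cutoff`); `highpass` uses the amplitude complement `1 - H(f)`, so a
#' matched high/low-pass pair reconstructs the input exactly before
#' rescaling. `whitened` flattens the amplitude spectrum (each component is
#' divided by its own amplitude with an epsilon floor, DC preserved).
#'
#' Rescaling follows the conventions used for filtered natural-image
#' stimuli: high- and low-pass outputs are rescaled to the input's mean and
#' standard deviation; the whitened output is scaled to the input's peak
#' pixel intensity.
#'
#' @param image An [image_scene].
#' @param mode One of `"original"`, `"whitened"`, `"highpass"`, `"lowpass"`.
#' @param cutoff Half-power frequency (cycles/degree) for high/low-pass.
#' @param rescale If `FALSE`, return the raw filtered image without the
#'   mean/sd or peak rescaling step (useful for reconstruction checks).
#'
#' @return An [image_scene].
#' @export
filter_image <- function(image, mode = c("original", "whitened", "highpass", "lowpass"),
                         cutoff = 0.1, rescale = TRUE) {
  stopifnot(inherits(image, "image_scene"))
  mode <- match.arg(mode)
  if (mode == "original") return(image)
  px <- image$pixels
  if (mode %in% c("whitened", "highpass") && stats::sd(px) == 0) {
    stop("zero-variance image: no structure to filter", call. = FALSE)
  }
  nr <- nrow(px); nc <- ncol(px)
  fgrid <- freq_grid(nr, nc, image$pixel_scale)
  spec <- stats::fft(px)

  if (mode == "whitened") {
    amp <- Mod(spec)
    out_spec <- spec / pmax(amp, 1e-8)
    out_spec[1, 1] <- spec[1, 1] # DC preserved
    out <- Re(stats::fft(out_spec, inverse = TRUE)) / (nr * nc)
    if (rescale) {
      mx <- max(out)
      if (mx > 0) out <- out * (max(px) / mx)
    }
  } else {
    if (cutoff <= 0) stop("`cutoff` must be > 0", call. = FALSE)
    h_lp <- exp(-log(2) / 2 * (fgrid / cutoff)^2)
    h <- if (mode == "lowpass") h_lp else 1 - h_lp
    out <- Re(stats::fft(spec * h, inverse = TRUE)) / (nr * nc)
    if (rescale) {
      s <- stats::sd(out)
      if (s == 0) stop("filtered image has zero variance; cannot match input moments",
                       call. = FALSE)
      out <- (out - mean(out)) / s * stats::sd(px) + mean(px)
    }
  }
  if (!all(is.finite(out))) stop("non-finite pixels after filtering", call. = FALSE)
  image_scene(out, image$pixel_scale, wrap = image$wrap)
}

#' Rotate a scene about the azimuth axis
#'
#' Circularly shifts the panorama by `degrees` of azimuth (nearest-pixel).
#' Only valid for wrapping scenes.
#'
#' @param image An [image_scene] with `wrap = TRUE`.
#' @param degrees Rotation (positive shifts content toward larger azimuth).
#' @return An [image_scene].
#' @export
rotate_scene <- function(image, degrees) {
  stopifnot(inherits(image, "image_scene"))
  if (!image$wrap) stop("cannot rotate a non-wrapping scene", call. = FALSE)
  nc <- ncol(image$pixels)
  shift <- round(degrees / image$pixel_scale[["az"]]) %% nc
  if (shift == 0) return(image)
  idx <- ((seq_len(nc) - 1L - shift) %% nc) + 1L
  image_scene(image$pixels[, idx, drop = FALSE], image$pixel_scale, image$wrap)
}

#' Export a scene as an 8-bit PNG
#'
#' Pixels are scaled linearly from `[min, max]` to 0..255.
#'
#' @param image An [image_scene].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scene_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export", call. = FALSE)
  }
  px <- image$pixels
  rng <- range(px)
  scaled <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  png::writePNG(scaled, path)
  invisible(path)
}
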