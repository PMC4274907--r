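#' Noise-stimulus configuration
#'
#' Parameters of the one-dimensional noise patterns used to drive the
#' network: raw white noise is scaled so that about `amplitude_sd_clip`
#' standard deviations fit in `[-1, 1]`, spatially low-pass filtered by
#' convolution with a Gaussian of width `sigma_lowpass_deg`, and (after
#' windowing into the receptive field) attenuated by a fixed Gaussian
#' envelope of width `sigma_envelope_deg` that models the spatial limits
#' of the receptive field.
#'
#' @param sigma_lowpass_deg Low-pass Gaussian width in degrees.
#' @param sigma_envelope_deg Envelope Gaussian width in degrees.
#' @param amplitude_sd_clip Number of standard deviations mapped into
#'   `[-1, 1]` before filtering.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(sigma_lowpass_deg = 0.25,
                         sigma_envelope_deg = 2.5,
                         amplitude_sd_clip = 4) {
  stopifnot(sigma_lowpass_deg > 0, sigma_envelope_deg > 0,
            amplitude_sd_clip > 0)
  structure(list(sigma_lowpass_deg = sigma_lowpass_deg,
                 sigma_envelope_deg = sigma_envelope_deg,
                 amplitude_sd_clip = amplitude_sd_clip),
            class = "noise_config")
}

# Gaussian convolution kernel truncated at +/- 4 sigma, renormalized to
# unit sum. sigma is in grid units.
gaussian_kernel <- function(sigma_units) {
  stopifnot(sigma_units > 0)
  half <- max(1L, ceiling(4 * sigma_units))
  x <- seq.int(-half, half)
  k <- exp(-x^2 / (2 * sigma_units^2))
  k / sum(k)
}

# Convolve a vector with a symmetric odd-length kernel, reflecting the
# signal at both boundaries (mirror excluding the edge sample, repeated
# as often as the kernel requires).
convolve_reflect <- function(x, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  stopifnot(n >= 2L)
  i <- (1L - half):(n + half)
  per <- 2L * n - 2L
  j <- (i - 1L) %% per + 1L
  j <- ifelse(j > n, 2L * n - j, j)
  out <- stats::filter(x[j], kernel, method = "convolution", sides = 2L)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Generate a low-pass-filtered noise strip
#'
#' Draws `length_units` independent Gaussian values scaled so that about
#' `cfg$amplitude_sd_clip` (default 4) standard deviations span
#' `[-1, 1]`, then low-pass filters them by convolution with a Gaussian
#' of width `cfg$sigma_lowpass_deg` (expressed in grid units). The strip
#' is longer than the receptive field so that a moving window can slide
#' over it; fresh correlated noise then enters the field during motion,
#' mimicking dots that are repositioned after leaving the aperture.
#'
#' @param length_units Strip length in grid units; at least
#'   `grid$n_units`.
#' @param cfg A [noise_config()].
#' @param grid A [spatial_grid()].
#' @param seed Optional integer; when given the strip is reproducible.
#' @return Numeric vector of length `length_units`.
#' @export
make_noise_strip <- function(length_units, cfg = noise_config(),
                             grid = default_grid("full"), seed = NULL) {
  stopifnot(inherits(cfg, "noise_config"), inherits(grid, "spatial_grid"),
            length_units >= grid$n_units)
  raw <- if (is.null(seed)) {
    stats::rnorm(length_units, sd = 1 / cfg$amplitude_sd_clip)
  } else {
    withr::with_seed(seed,
      stats::rnorm(length_units, sd = 1 / cfg$amplitude_sd_clip))
  }
  lowpass_strip(raw, cfg, grid)
}

# Low-pass an already-drawn raw strip (kept separate so the training loop
# can batch its own RNG draws). The convolution is rescaled by the
# kernel's L2 norm so the FINAL values keep the raw standard deviation:
# the amplitude clip refers to the values presented to the network, not
# the pre-filter draws.
lowpass_strip <- function(raw, cfg, grid) {
  sigma_units <- cfg$sigma_lowpass_deg / grid$delta_deg
  k <- gaussian_kernel(sigma_units)
  convolve_reflect(raw, k) / sqrt(sum(k^2))
}

# Gaussian receptive-field envelope sampled at unit centers, peak 1 at
# the center of the grid.
rf_envelope <- function(cfg, grid) {
  x <- (seq_len(grid$n_units) - 0.5) * grid$delta_deg - grid$span_deg / 2
  exp(-x^2 / (2 * cfg$sigma_envelope_deg^2))
}

new_stimulus_sequence <- function(frames, shift, speed_deg_s, kind,
                                  grid, extra = list()) {
  structure(c(list(frames = frames,
                   shift_units_per_frame = as.integer(shift),
                   speed_deg_s = speed_deg_s,
                   kind = kind,
                   grid = grid),
              extra),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("<stimulus_sequence> kind=%s, %d frames x %d units, shift=%d units/frame\n",
              x$kind, nrow(x$frames), ncol(x$frames), x$shift_units_per_frame))
  invisible(x)
}

#' Build a moving-noise stimulus sequence from a strip
#'
#' Frame `k` (1-based) is the window of `grid$n_units` contiguous strip
#' values starting at offset `(k - 1) * shift` (negative shifts start
#' from the far end), multiplied by the fixed receptive-field envelope.
#' Un-enveloped consecutive frames are exact integer translations of one
#' another.
#'
#' @param strip Numeric strip from [make_noise_strip()].
#' @param n_frames Number of frames.
#' @param shift Signed integer displacement in units per frame.
#' @param cfg A [noise_config()]; supplies the envelope width.
#' @param grid A [spatial_grid()].
#' @param envelope Logical; apply the receptive-field envelope.
#' @return A `stimulus_sequence` whose `frames` field is an
#'   `n_frames x n_units` matrix.
#' @export
make_motion_sequence <- function(strip, n_frames, shift,
                                 cfg = noise_config(),
                                 grid = default_grid("full"),
                                 envelope = TRUE) {
  stopifnot(n_frames >= 1, shift == round(shift))
  shift <- as.integer(shift)
  need <- grid$n_units + (n_frames - 1L) * abs(shift)
  if (length(strip) < need)
    stop(sprintf("strip too short: need %d units, got %d", need, length(strip)))
  # the window slides against the motion direction so the pattern content
  # moves toward +x by `shift` units per frame
  start0 <- if (shift >= 0L) (n_frames - 1L) * shift else 0L
  idx <- outer(-(seq_len(n_frames) - 1L) * shift + start0, seq_len(grid$n_units), `+`)
  frames <- matrix(strip[idx], nrow = n_frames)
  if (envelope)
    frames <- sweep(frames, 2L, rf_envelope(cfg, grid), `*`)
  new_stimulus_sequence(frames, shift,
                        shift * grid$delta_deg / grid$frame_dt_s,
                        "noise", grid)
}

#' Generate a moving low-pass noise sequence in one call
#'
#' Convenience wrapper: computes the integer shift for `speed_deg_s`,
#' draws a strip just long enough, and windows it into a sequence.
#'
#' @inheritParams make_motion_sequence
#' @param speed_deg_s Signed speed in degrees per second.
#' @param seed Optional integer seed.
#' @export
make_moving_noise <- function(speed_deg_s, n_frames = 5L,
                              cfg = noise_config(),
                              grid = default_grid("full"), seed = NULL,
                              envelope = TRUE) {
  shift <- speed_to_shift(speed_deg_s, grid)
  strip <- make_noise_strip(grid$n_units + (n_frames - 1L) * abs(shift),
                            cfg, grid, seed = seed)
  seq <- make_motion_sequence(strip, n_frames, shift, cfg, grid,
                              envelope = envelope)
  seq$speed_deg_s <- speed_deg_s
  seq
}

#' Drifting sinusoidal grating
#'
#' Frame `k` (0-based) samples `sin(2 * pi * sf * (x - v * k * dt) + phase0)`
#' at the unit centers `x`. The temporal frequency is `sf * v`; spatial
#' frequencies above the grid Nyquist limit are rejected.
#'
#' @param sf_cpd Spatial frequency in cycles per degree.
#' @param speed_deg_s Signed drift speed in degrees per second.
#' @param duration_s Duration in seconds; the number of frames is
#'   `round(duration_s / frame_dt_s)`.
#' @param grid A [spatial_grid()].
#' @param phase0 Initial phase in radians.
#' @param amplitude Peak amplitude (contrast) of the grating, at most 1.
#' @return A `stimulus_sequence` of kind `"grating"` with fields
#'   `sf_cpd` and `tf_hz`.
#' @export
make_grating_sequence <- function(sf_cpd, speed_deg_s, duration_s,
                                  grid = default_grid("full"),
                                  phase0 = 0, amplitude = 1) {
  stopifnot(sf_cpd > 0, duration_s > 0)
  nyquist <- 1 / (2 * grid$delta_deg)
  if (sf_cpd > nyquist)
    stop(sprintf("spatial frequency %.3g c/deg aliases on this grid (Nyquist %.3g c/deg)",
                 sf_cpd, nyquist))
  n_frames <- as.integer(round(duration_s / grid$frame_dt_s))
  x <- (seq_len(grid$n_units) - 0.5) * grid$delta_deg
  k <- seq_len(n_frames) - 1L
  phase_t <- 2 * pi * sf_cpd * speed_deg_s * k * grid$frame_dt_s
  stopifnot(amplitude > 0, amplitude <= 1)
  frames <- amplitude * sin(outer(-phase_t, 2 * pi * sf_cpd * x, `+`) + phase0)
  new_stimulus_sequence(frames, speed_to_shift(speed_deg_s, grid),
                        speed_deg_s, "grating", grid,
                        extra = list(sf_cpd = sf_cpd,
                                     tf_hz = sf_cpd * speed_deg_s))
}

#' Temporally independent bar-noise stream for reverse correlation
#'
#' Generates a stream of stimulus frames for reverse correlation:
#' frames are mutually independent in time, and each frame is rendered
#' as bars of `bar_width_units` grid units (one value per bar,
#' replicated across the bar's units). Grouping units into bars reduces
#' the effective stimulus dimension by the bar width, e.g. 2-unit
#' (0.027 deg) bars for output-unit probing and 3-unit (0.04 deg) bars
#' for hidden-unit probing on the full grid.
#'
#' With `spatial = "lowpass"` (default) each frame has the same spatial
#' statistics as the individual frames of the moving training patterns:
#' Gaussian noise low-pass filtered and attenuated by the
#' receptive-field envelope, then averaged within bars. This keeps the
#' probe ensemble in the stimulus regime the network was trained on.
#' `spatial = "white"` draws one independent value per bar instead
#' (a spatially white probe, useful for controlled simulations).
#'
#' @param bar_width_units Integer bar width in grid units.
#' @param n_frames Number of frames.
#' @param grid A [spatial_grid()].
#' @param seed Optional integer seed.
#' @param cfg A [noise_config()] (low-pass and envelope widths, clip).
#' @param spatial `"lowpass"` or `"white"` (see Details).
#' @return A `stimulus_sequence` of kind `"bar_noise"` with the reduced
#'   `bar_values` matrix (`n_frames x n_bars`) and `bar_width_units`.
#' @export
make_bar_noise_stream <- function(bar_width_units, n_frames,
                                  grid = default_grid("full"),
                                  seed = NULL, cfg = noise_config(),
                                  spatial = c("lowpass", "white")) {
  spatial <- match.arg(spatial)
  stopifnot(bar_width_units >= 1, bar_width_units == round(bar_width_units),
            n_frames >= 1)
  bar_width_units <- as.integer(bar_width_units)
  n_bars <- as.integer(ceiling(grid$n_units / bar_width_units))
  sd_raw <- 1 / cfg$amplitude_sd_clip
  grp <- rep(seq_len(n_bars), each = bar_width_units)[seq_len(grid$n_units)]
  draw <- function() {
    if (spatial == "white") {
      matrix(stats::rnorm(n_frames * n_bars, sd = sd_raw), nrow = n_frames)
    } else {
      raw <- matrix(stats::rnorm(n_frames * grid$n_units, sd = sd_raw),
                    nrow = n_frames)
      K <- lowpass_operator(cfg, grid)
      full <- sweep(raw %*% K, 2L, rf_envelope(cfg, grid), `*`)
      t(rowsum(t(full), grp) / as.vector(table(grp)))
    }
  }
  bars <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  frames <- bars[, grp, drop = FALSE]
  new_stimulus_sequence(frames, 0L, 0, "bar_noise", grid,
                        extra = list(bar_values = bars,
                                     bar_width_units = bar_width_units))
}

# Dense linear operator equivalent to lowpass_strip on a vector of
# length n_units (reflect boundaries, L2-renormalized kernel), applied
# from the right to row-vector frames.
lowpass_operator <- function(cfg, grid) {
  n <- grid$n_units
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    K[j, ] <- lowpass_strip(e, cfg, grid)
  }
  K
}
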