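test_that("speed-to-shift mapping reproduces the experimental geometry", {
  g <- default_grid("full")
  expect_equal(g$n_units, 750L)
  expect_equal(g$delta_deg, 10 / 750)
  expect_identical(speed_to_shift(64, g), 64L)
  expect_identical(speed_to_shift(1, g), 1L)
  expect_identical(speed_to_shift(0, g), 0L)
  # odd symmetry over the whole speed range, both grids
  for (grid in list(g, default_grid("desk")))
    for (v in c(training_speeds(), 3.3, 17.8))
      expect_identical(speed_to_shift(-v, grid), -speed_to_shift(v, grid))
  expect_error(speed_to_shift(Inf, g))
})

test_that("noise strips are reproducible, linear, and correctly scaled", {
  g <- default_grid("full")
  expect_identical(make_noise_strip(2000, seed = 7),
                   make_noise_strip(2000, seed = 7))
  # linearity of the filter: zero in, zero out
  expect_equal(recmotion:::lowpass_strip(numeric(1000), noise_config(), g),
               numeric(1000))
  # final values are N(0, 1/16): tail beyond 1 matches the 4-SD clip
  strip <- make_noise_strip(1e6, seed = 42)
  tail_frac <- mean(abs(strip) > 1)
  expect_gt(tail_frac, 1e-5)
  expect_lt(tail_frac, 1.6e-4)   # P(|Z| > 4) = 6.33e-5
})

test_that("strip autocovariance matches the kernel self-convolution", {
  g <- default_grid("full")
  cfg <- noise_config()
  strip <- make_noise_strip(1e6, cfg, g, seed = 43)
  k <- recmotion:::gaussian_kernel(cfg$sigma_lowpass_deg / g$delta_deg)
  theo <- stats::convolve(k, k, type = "open")   # kernel self-convolution
  mid <- (length(theo) + 1L) %/% 2L
  lags <- 0:40
  theo_rho <- theo[mid + lags] / theo[mid]
  emp_rho <- drop(stats::acf(strip, lag.max = 40, plot = FALSE)$acf)
  expect_gt(stats::cor(emp_rho, theo_rho), 0.999)
  expect_equal(emp_rho[11], theo_rho[11], tolerance = 0.02)
})

test_that("motion sequences are exact translations under the envelope", {
  g <- default_grid("desk")
  cfg <- noise_config()
  strip <- make_noise_strip(g$n_units + 4 * 16, cfg, g, seed = 1)
  # shift 0: all frames identical
  s0 <- make_motion_sequence(strip, 5, 0, cfg, g)
  expect_true(all(apply(s0$frames, 2, function(col) all(col == col[1]))))
  # un-enveloped frames: exact equality on the overlapping support, and
  # brute-force cross-correlation peaks at the shift
  s16 <- make_motion_sequence(strip, 5, 16, cfg, g, envelope = FALSE)
  n <- g$n_units
  for (t in 1:4)
    expect_identical(s16$frames[t + 1, (1 + 16):n], s16$frames[t, 1:(n - 16)])
  cc <- vapply(-40:40, function(L) {
    if (L >= 0) stats::cor(s16$frames[2, (1 + L):n], s16$frames[1, 1:(n - L)])
    else stats::cor(s16$frames[2, 1:(n + L)], s16$frames[1, (1 - L):n])
  }, numeric(1))
  expect_identical((-40:40)[which.max(cc)], 16L)
  expect_error(make_motion_sequence(strip, 50, 16, cfg, g), "too short")
})

test_that("the receptive-field envelope attenuates off-center variance", {
  g <- default_grid("full")
  cfg <- noise_config()
  set.seed(5)
  frames <- do.call(rbind, lapply(1:400, function(i)
    make_moving_noise(16, 1, cfg, g)$frames))
  center <- round(g$n_units / 2)
  off <- center + round(2.5 / g$delta_deg)   # 2.5 deg off-center
  ratio <- stats::var(frames[, off]) / stats::var(frames[, center])
  expect_equal(ratio, exp(-1), tolerance = 0.25)  # envelope^2 at 1 SD
})

test_that("gratings drift at tf = v * sf and respect the Nyquist limit", {
  g <- default_grid("full")
  sq <- make_grating_sequence(0.5, 16, 1, g)   # 75 frames, 1 s
  expect_equal(sq$tf_hz, 8)
  px <- sq$frames[, 100]
  spec <- Mod(stats::fft(px))[2:38]
  expect_identical(which.max(spec), 8L)        # 8 Hz bin at 1 Hz resolution
  # static grating
  s0 <- make_grating_sequence(0.5, 0, 0.2, g)
  expect_true(all(apply(s0$frames, 2, function(col) all(col == col[1]))))
  # 10 s at 75 Hz
  expect_equal(nrow(make_grating_sequence(0.5, 16, 10, g)$frames), 750L)
  expect_error(make_grating_sequence(100, 16, 1, g), "alias")
})

test_that("bar streams reduce dimension and are temporally independent", {
  g <- default_grid("full")
  s <- make_bar_noise_stream(2, 50, g, seed = 3)
  expect_equal(ncol(s$bar_values), 375L)       # dimension halved
  expect_identical(s$frames[, 1], s$frames[, 2])  # bar replication
  s1 <- make_bar_noise_stream(1, 20, g, seed = 3, spatial = "white")
  expect_equal(ncol(s1$bar_values), 750L)
  # temporal independence (white variant, 1e4 frames)
  gw <- spatial_grid(40, 40 / 75)
  w <- make_bar_noise_stream(1, 1e4, gw, seed = 4, spatial = "white")
  lag1 <- mean(vapply(seq_len(40), function(j)
    stats::cor(w$bar_values[-1e4, j], w$bar_values[-1, j]), numeric(1)))
  expect_lt(abs(lag1), 0.05)
  # low-pass variant keeps the training-frame spatial statistics
  lp <- make_bar_noise_stream(2, 500, default_grid("desk"), seed = 5)
  expect_gt(stats::cor(lp$bar_values[1, -1], lp$bar_values[1, -75]), 0.8)
  expect_error(make_bar_noise_stream(0, 10, g))
})

test_that("moving noise concentrates Fourier power on the tf = v*sf line", {
  g <- default_grid("desk")
  # a slightly finer low-pass keeps power in several spatial-frequency
  # bins of the 2-degree field; spectra averaged over 10 strips
  cfg <- noise_config(sigma_lowpass_deg = 0.1)
  shift <- 16    # 16 deg/s on this grid
  nf <- 64L
  Savg <- 0
  for (seed in 1:10) {
    strip <- make_noise_strip(g$n_units + (nf - 1L) * shift, cfg, g,
                              seed = seed)
    sq <- make_motion_sequence(strip, nf, shift, cfg, g, envelope = FALSE)
    Savg <- Savg + Mod(stats::mvfft(t(stats::mvfft(sq$frames))))^2
  }
  # spatial frequency bin m <-> m / span cycles/deg; expected temporal
  # frequency |tf| = v * sf -> bin offset v * m / span / (75/64)
  for (m in 1:4) {
    bin_expect <- 16 * (m / g$span_deg) / (75 / nf)
    tf_spec <- Savg[m + 1, ]
    idx <- which.max(tf_spec[2:(nf - 1L)]) + 1L   # skip DC
    bin_found <- min(idx - 1L, nf - (idx - 1L))   # fold negative tf
    expect_lt(abs(bin_found - bin_expect), 1.6)
  }
})
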