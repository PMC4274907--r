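test_that("F1/F0 classification matches closed-form modulation ratios", {
  dt <- 1 / 75; tf <- 3
  tt <- (0:(5 + 750 - 1)) * dt
  # r = 1 + cos: F1 = F0 = 1, the boundary case, labeled complex
  m1 <- f1f0_classify(1 + cos(2 * pi * tf * tt), tf, dt)
  expect_equal(m1$ratio, 1, tolerance = 1e-9)
  expect_identical(m1$label, "complex")
  # constant response: ratio 0 -> complex
  m0 <- f1f0_classify(rep(2.5, 400), tf, dt)
  expect_equal(m0$ratio, 0, tolerance = 1e-12)
  expect_identical(m0$label, "complex")
  # half-wave rectified cosine: ratio pi/2 -> simple
  mr <- f1f0_classify(pmax(cos(2 * pi * tf * tt), 0), tf, dt)
  expect_equal(mr$ratio, pi / 2, tolerance = 1e-2)
  expect_identical(mr$label, "simple")
  # zero response flagged
  expect_warning(mz <- f1f0_classify(rep(0, 400), tf, dt), "undefined")
  expect_identical(mz$label, "complex-indeterminate")
})

test_that("F1/F0 is gain-invariant and decreases with added baseline", {
  dt <- 1 / 75; tf <- 5
  tt <- (0:599) * dt
  r <- 1 + 0.8 * cos(2 * pi * tf * tt)
  base_ratio <- f1f0_classify(r, tf, dt)$ratio
  expect_equal(f1f0_classify(3.7 * r, tf, dt)$ratio, base_ratio,
               tolerance = 1e-9)
  ratios <- vapply(c(0.5, 1, 2), function(b)
    f1f0_classify(r + b, tf, dt)$ratio, numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_lt(ratios[3], base_ratio)
})

test_that("indirect input is the exact one-step relay product", {
  withr::with_seed(4, {
    D <- matrix(rnorm(30), 5, 6)
    M1 <- matrix(rnorm(25), 5); M2 <- matrix(rnorm(25), 5)
  })
  expect_identical(indirect_input(diag(5), D), D)
  expect_identical(indirect_input(matrix(0, 5, 5), D), matrix(0, 5, 6))
  # single lateral connection copies (scales) one direct row
  M <- matrix(0, 5, 5); M[2, 4] <- 3.5
  expect_equal(indirect_input(M, D)[2, ], 3.5 * D[4, ])
  # bilinearity
  expect_equal(indirect_input(2 * M1 - 3 * M2, D),
               2 * indirect_input(M1, D) - 3 * indirect_input(M2, D))
  expect_error(indirect_input(matrix(0, 5, 4), D))
})

test_that("shift estimation recovers constructed displacements exactly", {
  g <- default_grid("full")
  strip <- make_noise_strip(g$n_units + 100, seed = 31, grid = g)
  direct <- strip[51:(50 + g$n_units)]
  # indirect displaced so that direct[j + 37] == indirect[j]
  indirect <- strip[(51 + 37):(50 + 37 + g$n_units)]
  s <- estimate_shift(direct, indirect, noise_config(), g)
  expect_identical(s$dx_units, 37L)
  expect_gt(s$peak_correlation, 0.99)
  expect_true(s$valid)
  # identical rows: zero lag, perfect correlation
  s0 <- estimate_shift(direct, direct, noise_config(), g)
  expect_identical(s0$dx_units, 0L)
  expect_equal(s0$peak_correlation, 1)
  # recovery across a range of shifts, both signs, up to half the
  # (boundary-trimmed) row length
  strip2 <- make_noise_strip(2000, seed = 32, grid = g)
  for (k in c(-250, -150, -64, -5, 5, 64, 150, 250)) {
    d2 <- strip2[601:(600 + g$n_units)]
    i2 <- strip2[(601 + k):(600 + k + g$n_units)]
    sk <- estimate_shift(d2, i2, noise_config(), g)
    expect_identical(sk$dx_units, as.integer(k))
    expect_equal(sk$peak_correlation, 1)
  }
  # degenerate rows are invalid
  sz <- estimate_shift(rep(1, 100), rnorm(100), noise_config(), g)
  expect_false(sz$valid)
})

test_that("independent rows rarely reach the validity threshold", {
  # frozen Monte-Carlo oracle (1000 reps): the smoothed best-lag
  # correlation of white independent rows falls below 0.5 in ~23% of
  # draws (median peak 0.61, q99 0.91); true shifted copies reach 1
  g <- default_grid("full")
  withr::with_seed(17, {
    peaks <- replicate(200, estimate_shift(rnorm(g$n_units), rnorm(g$n_units),
                                           noise_config(), g)$peak_correlation)
  })
  expect_gt(mean(peaks < 0.5), 0.12)
  expect_lt(mean(peaks < 0.5), 0.38)
  expect_lt(max(peaks), 0.99)
})

test_that("linear prediction converts shifts to speeds with sign", {
  g <- default_grid("full")
  mk <- function(dx) structure(list(dx_units = dx, dx_deg = dx * g$delta_deg,
                                    peak_correlation = 0.9, valid = TRUE),
                               class = "shift_estimate")
  expect_equal(linear_prediction(mk(16L), g), 16)   # 0.2133 deg / 13.3 ms
  expect_equal(linear_prediction(mk(0L), g), 0)
  expect_equal(linear_prediction(mk(-8L), g), -8)
  bad <- mk(3L); bad$valid <- FALSE
  expect_error(linear_prediction(bad, g), "not valid")
})

test_that("a constructed delay-line network sits on the dx/dt identity", {
  grid <- default_grid("desk")
  ks <- c(4L, 8L, 16L, 32L)
  net <- make_delay_line_net(ks, grid)
  I <- indirect_input(net$M, net$D)
  shifts <- lapply(seq_along(ks), function(i)
    estimate_shift(net$D[i, ], I[i, ], noise_config(), grid))
  preds <- vapply(shifts, linear_prediction, numeric(1), grid = grid)
  expect_identical(vapply(shifts, `[[`, 0L, "dx_units"), ks)
  expect_equal(preds, as.numeric(ks))   # exactly on the identity line
  # the designed preference is real: responses to fine-grained noise are
  # larger at +k than at -k for each detector
  cfg_fine <- noise_config(sigma_lowpass_deg = 0.04)
  for (i in c(2, 3)) {
    mean_resp <- function(v) {
      r <- 0
      for (rep in 1:60) {
        s <- make_moving_noise(v, 5, cfg_fine, grid, seed = 3000 + rep)
        r <- r + mean(run_sequence(net, s)$hidden[2:5, i])
      }
      r / 60
    }
    expect_gt(mean_resp(ks[i]), mean_resp(-ks[i]) * 1.05)
  }
  # units with invalid shifts are excluded from the joined table
  fake_invalid <- structure(list(dx_units = NA_integer_, dx_deg = NA_real_,
                                 peak_correlation = 0.2, valid = FALSE),
                            class = "shift_estimate")
  pv <- prediction_vs_actual(c(ks, 10), c(shifts, list(fake_invalid)),
                             rep(c("simple", "complex"), c(4, 1)), grid)
  expect_identical(pv$table$unit, 1:4)
  expect_equal(pv$table$predicted, as.numeric(ks))
  expect_equal(pv$stats[pv$stats$label == "simple", "sign_agreement"], 1)
  expect_error(prediction_vs_actual(10, list(fake_invalid), "simple", grid),
               "no units")
})

test_that("weight sorting separates matched from mismatched speeds", {
  withr::with_seed(8, {
    hidden_pref <- 2^runif(40, 0, 6)
    output_pref <- 2^runif(6, 3, 5)
    # constructed weights: excitation only between matched speeds
    dist <- abs(outer(log2(output_pref), log2(hidden_pref), `-`))
    W <- ifelse(dist <= 0.5, 1, -0.2) + matrix(rnorm(240, sd = 0.01), 6)
    ws <- weight_sorting(W, hidden_pref, output_pref)
    expect_gt(ws$matched_mean, ws$mismatched_mean)
    expect_identical(dim(ws$sorted), dim(W))
    expect_identical(ws$hidden_order, order(hidden_pref))
    # random weights: matched and mismatched block means indistinguishable
    # against a permutation null
    Wr <- matrix(rnorm(240), 6)
    wsr <- weight_sorting(Wr, hidden_pref, output_pref)
    obs <- wsr$matched_mean - wsr$mismatched_mean
    null <- replicate(500, {
      wp <- weight_sorting(Wr, sample(hidden_pref), output_pref)
      wp$matched_mean - wp$mismatched_mean
    })
    expect_gt(mean(abs(null) >= abs(obs)), 0.01)
  })
})

test_that("input-weight PCA identifies low-rank weight structure", {
  n_in <- 48
  gab <- sin(2 * pi * (1:n_in) / 16) * exp(-((1:n_in) - 24)^2 / 100)
  # rows are the same Gabor at unit-specific amplitudes: rank one
  D1 <- outer(seq(0.5, 2, length.out = 10), gab)
  pca1 <- input_weight_pca(D1)
  expect_equal(pca1$variance_fraction[1], 1, tolerance = 1e-9)
  expect_equal(sum(pca1$variance_fraction), 1, tolerance = 1e-12)
  # rows mixing 3 orthogonal quadrature pairs + small noise: 6 components
  withr::with_seed(12, {
    basis <- qr.Q(qr(matrix(rnorm(n_in * 6), n_in, 6)))
    Dm <- matrix(rnorm(80 * 6), 80, 6) %*% t(basis) +
      matrix(rnorm(80 * n_in, sd = 0.02), 80, n_in)
  })
  pcam <- input_weight_pca(Dm)
  expect_gt(sum(pcam$variance_fraction[1:6]), 0.95)
  expect_equal(sum(pcam$variance_fraction), 1, tolerance = 1e-12)
  expect_error(input_weight_pca(D1[1, , drop = FALSE]))
})
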