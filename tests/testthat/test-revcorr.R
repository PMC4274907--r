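# Shared white-probe fixture: 16 spatial samples x 5 history bins.
rc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      grid <- spatial_grid(16, 16 / 75)
      stream <- make_bar_noise_stream(1, 2e5, grid, seed = 5,
                                      spatial = "white")
      X <- recmotion:::build_history_design(stream$bar_values, 5L)
      f1 <- as.numeric(t(st_gabor(16, 5, 0.15, 0)))
      f2 <- as.numeric(t(st_gabor(16, 5, 0.15, pi / 2)))
      f2 <- f2 - f1 * sum(f1 * f2); f2 <- f2 / sqrt(sum(f2^2))
      cache <<- list(grid = grid, X = X, f1 = f1, f2 = f2)
    }
    cache
  }
})

test_that("spike conversion scales the peak to 30 and is monotone", {
  act <- c(0, 1, 2, 4, 2, 1)
  spk <- rates_to_spikes(act)
  expect_identical(max(spk$counts), 30L)
  expect_identical(spk$counts[4], 30L)
  expect_identical(spk$counts[3], 15L)        # half of peak -> 15
  expect_equal(spk$peak_scale, 4)
  expect_warning(z <- rates_to_spikes(numeric(10)), "degenerate")
  expect_true(z$degenerate)
  expect_identical(z$counts, integer(10))
  withr::with_seed(2, {
    a <- sort(runif(50)); s <- rates_to_spikes(a)$counts
    expect_true(all(diff(s) >= 0))
  })
})

test_that("the STA recovers the filter of a monotone LN neuron", {
  fx <- rc_fixture()
  p1 <- drop(fx$X %*% fx$f1)
  counts <- as.integer(round(30 * stats::plogis(3 * p1 / stats::sd(p1) - 1)))
  sta <- compute_sta(fx$X, counts, 5L)
  expect_gt(abs(sum(as.numeric(t(sta$weights)) * fx$f1)), 0.95)
  expect_error(compute_sta(fx$X, integer(nrow(fx$X))), "no spikes")
  # stimulus-independent spikes: the STA norm shrinks like 1/sqrt(N)
  norms <- vapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      w_small <- rpois(2000, 3)
      w_big <- rpois(32000, 3)
    })
    small <- compute_sta(fx$X[1:2000, ], w_small)$norm
    big <- compute_sta(fx$X[1:32000, ], w_big)$norm
    big / small
  }, numeric(1))
  expect_lt(mean(norms), 0.5)   # expect ~ 1/4 at 16x the data
})

test_that("STC finds quadrature pairs and suppressive channels", {
  fx <- rc_fixture()
  en <- drop(fx$X %*% fx$f1)^2 + drop(fx$X %*% fx$f2)^2
  counts <- as.integer(round(30 * en / max(en)))
  stc <- compute_stc(fx$X, counts, 5L)
  expect_lt(principal_angle_deg(stc$vectors[, 1:2], cbind(fx$f1, fx$f2)), 10)
  # energy-model STA carries no structure (polarity insensitive)
  sta_e <- compute_sta(fx$X, counts, 5L)
  expect_lt(abs(sum(as.numeric(t(sta_e$weights)) * fx$f1)), 0.2)
  # stimulus-independent spikes: eigenvalues concentrate near zero
  withr::with_seed(7, w0 <- rpois(nrow(fx$X), 3))
  stc0 <- compute_stc(fx$X, w0, 5L)
  expect_lt(max(abs(stc0$values)) / max(diag(stc0$C_raw)), 0.05)
  # an added suppressive squared channel yields a negative eigenvalue
  f3 <- as.numeric(t(st_gabor(16, 5, 0.3, 0.7)))
  p3 <- drop(fx$X %*% f3) / stats::sd(drop(fx$X %*% f3))
  base <- 10 + 4 * drop(fx$X %*% fx$f1) / stats::sd(drop(fx$X %*% fx$f1))
  counts_s <- as.integer(round(pmax(base - 3 * p3^2, 0)))
  stc_s <- compute_stc(fx$X, counts_s, 5L)
  expect_lt(stc_s$values[length(stc_s$values)] /
              max(abs(stc_s$values)), -0.5)
  v_min <- stc_s$vectors[, which.min(stc_s$values)]
  expect_gt(abs(sum(v_min * f3)), 0.95)
})

test_that("information ranking matches the closed-form Gaussian KL", {
  # identical spike-triggered and raw ensembles -> zero information
  stc_same <- list(C_raw = diag(3), C_spike = diag(3),
                   mu_raw = numeric(3), mu_spike = numeric(3),
                   history = 1L)
  bank0 <- istac_rank(stc_same, n_filters = 3)
  expect_equal(max(abs(bank0$info_bits)), 0, tolerance = 1e-9)
  # variance ratio 2 in one dimension: KL = (2 - ln 2 - 1)/2 nats
  stc_var <- list(C_raw = diag(3), C_spike = diag(c(2, 1, 1)),
                  mu_raw = numeric(3), mu_spike = numeric(3),
                  history = 1L)
  bank1 <- istac_rank(stc_var, n_filters = 1)
  expect_equal(bank1$info_bits[1], 0.5 * (2 - log(2) - 1) / log(2),
               tolerance = 1e-9)   # 0.2213 bits
  expect_equal(abs(as.numeric(bank1$filters[[1]]$weights)), c(1, 0, 0),
               tolerance = 1e-9)
  expect_identical(bank1$filters[[1]]$sign, "excitatory")
  # a pure mean shift is also information
  stc_mu <- list(C_raw = diag(2), C_spike = diag(2),
                 mu_raw = numeric(2), mu_spike = c(1, 0), history = 1L)
  bank2 <- istac_rank(stc_mu, n_filters = 1)
  expect_equal(bank2$info_bits[1], 0.5 / log(2), tolerance = 1e-9)
  expect_error(istac_rank(stc_var, n_filters = 10), "n_filters")
})

test_that("iSTAC recovers the generating subspace with ranked information", {
  fx <- rc_fixture()
  en <- drop(fx$X %*% fx$f1)^2 + drop(fx$X %*% fx$f2)^2
  counts <- as.integer(round(30 * en / max(en)))
  sta <- compute_sta(fx$X, counts, 5L)
  stc <- compute_stc(fx$X, counts, 5L)
  bank <- istac_rank(stc, n_filters = 4, sta = sta)
  F2 <- vapply(bank$filters[1:2], function(f) as.numeric(t(f$weights)),
               numeric(80))
  expect_lt(principal_angle_deg(F2, cbind(fx$f1, fx$f2)), 10)
  expect_true(all(bank$info_bits >= 0))
  expect_true(all(diff(bank$info_bits) <= 1e-12))   # non-increasing
  expect_gt(sum(bank$info_bits[1:2]) / sum(bank$info_bits), 0.9)
  expect_identical(vapply(bank$filters, `[[`, 0L, "rank"), 1:4)
})

test_that("estimated nonlinearities reproduce the generating shapes", {
  fx <- rc_fixture()
  # energy neuron: symmetric, minimum at zero projection
  en <- drop(fx$X %*% fx$f1)^2 + drop(fx$X %*% fx$f2)^2
  counts <- as.integer(round(30 * en / max(en)))
  nl <- estimate_nonlinearity(fx$f1, fx$X, counts)
  ok <- !is.na(nl$rates) & rev(!is.na(nl$rates))
  expect_gt(stats::cor(nl$rates[ok], rev(nl$rates)[ok]), 0.9)
  expect_lt(abs(nl$bin_centers[which.min(nl$rates)]), stats::sd(drop(fx$X %*% fx$f1)))
  # quadratic within binning error
  quad <- stats::lm(nl$rates[ok] ~ poly(nl$bin_centers[ok], 2))
  expect_gt(summary(quad)$r.squared, 0.95)
  # suppressive channel: maximum at zero projection
  base <- 10 + 0 * en
  p3 <- drop(fx$X %*% fx$f2) / stats::sd(drop(fx$X %*% fx$f2))
  counts_s <- as.integer(round(pmax(base - 2.5 * p3^2, 0)))
  nl_s <- estimate_nonlinearity(fx$f2, fx$X, counts_s)
  expect_lt(abs(nl_s$bin_centers[which.max(nl_s$rates)]),
            stats::sd(drop(fx$X %*% fx$f2)))
  # half-rectified linear neuron: monotone, asymmetric
  p1 <- drop(fx$X %*% fx$f1)
  counts_r <- as.integer(round(20 * pmax(p1 / stats::sd(p1), 0)))
  nl_r <- estimate_nonlinearity(fx$f1, fx$X, counts_r)
  okr <- !is.na(nl_r$rates)
  expect_gt(stats::cor(nl_r$bin_centers[okr], nl_r$rates[okr],
                       method = "spearman"), 0.9)
})

test_that("separable LN simulation combines filters as sum minus (n-1) mean", {
  fx <- rc_fixture()
  # hand-built bank: one linear filter with identity nonlinearity
  lin_nl <- structure(list(bin_centers = seq(-4, 4, length.out = 25),
                           rates = seq(-4, 4, length.out = 25),
                           mean_rate = 0), class = "nonlinearity")
  filt <- structure(list(weights = matrix(fx$f1, 5, 16, byrow = TRUE),
                         info_bits = 1, sign = "excitatory", rank = 1L,
                         history = 5L), class = "space_time_filter")
  bank1 <- structure(list(filters = list(filt), nonlinearities = list(lin_nl),
                          history = 5L, n_space = 16L), class = "filter_bank")
  X <- fx$X[1:100, ]
  expect_equal(ln_simulate(bank1, X), pmax(drop(X %*% fx$f1), 0))
  # two identical filters each returning the mean rate -> combined = mean
  const_nl <- structure(list(bin_centers = seq(-4, 4, length.out = 25),
                             rates = rep(7, 25), mean_rate = 7),
                        class = "nonlinearity")
  bank2 <- structure(list(filters = list(filt, filt),
                          nonlinearities = list(const_nl, const_nl),
                          history = 5L, n_space = 16L), class = "filter_bank")
  expect_equal(ln_simulate(bank2, X), rep(7, 100))
  bank_empty <- structure(list(filters = list(), nonlinearities = list()),
                          class = "filter_bank")
  expect_error(ln_simulate(bank_empty, X))
})

test_that("filter spectra peak at the filter's own frequencies", {
  # drifting sinusoid filter: peak exactly at (sf, tf) and its mirror
  h <- 8L; ns <- 16L
  sf_cyc <- 2 / ns; tf_cyc <- 3 / h
  w <- outer(seq_len(h) - 1, seq_len(ns) - 1, function(t, x)
    sin(2 * pi * (sf_cyc * x - tf_cyc * t)))
  filt <- structure(list(weights = w, sign = "excitatory", rank = 1L,
                         info_bits = 1, history = h),
                    class = "space_time_filter")
  sp <- filter_spectra(list(filt))
  a <- sp$spectra[[1]]
  peak <- which(a == max(a), arr.ind = TRUE)
  # zero-frequency is centered at (h/2 + 1, ns/2 + 1)
  expect_setequal(abs(peak[, 1] - (h / 2 + 1)), 3)
  expect_setequal(abs(peak[, 2] - (ns / 2 + 1)), 2)
  # a static filter has power only at zero temporal frequency
  w0 <- matrix(rep(sin(2 * pi * (1:ns) / ns), each = h), h, ns)
  filt0 <- structure(list(weights = w0, sign = "suppressive", rank = 1L,
                          info_bits = 1, history = h),
                     class = "space_time_filter")
  sp0 <- filter_spectra(list(filt0))
  a0 <- sp0$spectra[[1]]
  expect_equal(sum(a0[-(h / 2 + 1), ]), 0, tolerance = 1e-8)
  # pooled spectra are normalized to peak 1 per sign group
  spb <- filter_spectra(list(filt, filt0))
  expect_equal(max(spb$pooled$excitatory), 1)
  expect_equal(max(spb$pooled$suppressive), 1)
})

test_that("the full pipeline on a simulated LN neuron is self-consistent", {
  fx <- rc_fixture()
  # polarity-insensitive neuron on a *network* activity path: rates in
  # (0,1) like sigmoid units, peak rescaled by the spike conversion
  en <- drop(fx$X %*% fx$f1)^2 + drop(fx$X %*% fx$f2)^2
  act <- en / max(en)
  spk <- rates_to_spikes(act)
  sta <- compute_sta(fx$X, spk$counts, 5L)
  stc <- compute_stc(fx$X, spk$counts, 5L)
  bank <- istac_rank(stc, n_filters = 4, sta = sta)
  bank$nonlinearities <- lapply(bank$filters, function(f)
    estimate_nonlinearity(f, fx$X, spk$counts))
  F2 <- vapply(bank$filters[1:2], function(f) as.numeric(t(f$weights)),
               numeric(80))
  expect_lt(principal_angle_deg(F2, cbind(fx$f1, fx$f2)), 10)
  # symmetric nonlinearities for both leading filters
  for (i in 1:2) {
    nl <- bank$nonlinearities[[i]]
    ok <- !is.na(nl$rates) & rev(!is.na(nl$rates))
    expect_gt(stats::cor(nl$rates[ok], rev(nl$rates)[ok]), 0.9)
  }
  # LN simulation correlates with the generating rate on held-out input
  Xnew <- fx$X[150001:150500, ]
  pred <- ln_simulate(bank, Xnew)
  truth <- (drop(Xnew %*% fx$f1)^2 + drop(Xnew %*% fx$f2)^2)
  expect_gt(stats::cor(pred, truth, method = "spearman"), 0.9)
})
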