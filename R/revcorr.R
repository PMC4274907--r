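#' Convert a continuous activity trace to integer spike counts
#'
#' Scales the peak response of the trace to `peak_spikes` (default 30)
#' spikes per time bin and rounds every bin to the nearest integer.
#'
#' @param activity Non-negative activity trace.
#' @param peak_spikes Count assigned to the peak bin.
#' @return An object of class `spike_record` with integer `counts`, the
#'   `peak_scale` (activity value mapped to `peak_spikes`) and a
#'   `degenerate` flag set when the trace is all zero (in which case the
#'   counts are all zero and no scaling is applied).
#' @export
rates_to_spikes <- function(activity, peak_spikes = 30) {
  stopifnot(all(activity >= 0), peak_spikes > 0)
  peak <- max(activity)
  if (peak == 0) {
    warning("all-zero activity: spike conversion degenerate")
    return(structure(list(counts = integer(length(activity)),
                          peak_scale = 0, degenerate = TRUE),
                     class = "spike_record"))
  }
  structure(list(counts = as.integer(round(peak_spikes * activity / peak)),
                 peak_scale = peak, degenerate = FALSE),
            class = "spike_record")
}

# Stimulus-history design matrix. bar_values: frames x space. Row t of
# the result is the concatenation of frames t-history+1 .. t (earliest
# lag first), i.e. column (h-1)*n_space + j is the value of spatial
# sample j at lag (history - h) frames before the response bin. The
# first history-1 frames have no full window and are dropped; the
# matching response bins are counts[history:T].
build_history_design <- function(bar_values, history = 5L) {
  TT <- nrow(bar_values); ns <- ncol(bar_values)
  stopifnot(TT > history)
  n_rows <- TT - history + 1L
  X <- matrix(0, n_rows, history * ns)
  for (h in seq_len(history))
    X[, (h - 1L) * ns + seq_len(ns)] <- bar_values[(h - 1L) + seq_len(n_rows), , drop = FALSE]
  X
}

# Zero-padded variant: every frame gets a row; history before the first
# frame is blank (matches a network starting from rest).
build_history_design_padded <- function(bar_values, history = 5L) {
  pad <- matrix(0, history - 1L, ncol(bar_values))
  build_history_design(rbind(pad, bar_values), history)
}

# First and second moments of a (possibly spike-weighted) stimulus
# ensemble.
ensemble_moments <- function(X, w = NULL) {
  n <- nrow(X)
  if (is.null(w)) {
    mu <- colMeans(X)
    C <- crossprod(X) / n - tcrossprod(mu)
  } else {
    stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
    sw <- sum(w)
    mu <- drop(crossprod(X, w)) / sw
    C <- crossprod(X * w, X) / sw - tcrossprod(mu)
  }
  list(mu = mu, C = C)
}

as_filter_matrix <- function(v, history, n_space) {
  matrix(v, history, n_space, byrow = TRUE)
}

#' Spike-triggered average
#'
#' Spike-count-weighted mean of the stimulus-history windows preceding
#' each response bin, minus the raw (unweighted) mean.
#'
#' @param X Stimulus-history design matrix (`windows x (history * space)`).
#' @param counts Spike counts aligned with the rows of `X`.
#' @param history Number of history bins (used to reshape).
#' @return A `space_time_filter` whose `weights` is a unit-norm
#'   `history x space` matrix (earliest lag in row 1); the unnormalized
#'   average is kept in `raw`.
#' @export
compute_sta <- function(X, counts, history = 5L) {
  stopifnot(nrow(X) == length(counts))
  if (sum(counts) == 0) stop("no spikes: STA undefined")
  n_space <- ncol(X) / history
  sta <- drop(crossprod(X, counts)) / sum(counts) - colMeans(X)
  nrm <- sqrt(sum(sta^2))
  structure(list(weights = as_filter_matrix(if (nrm > 0) sta / nrm else sta,
                                            history, n_space),
                 raw = as_filter_matrix(sta, history, n_space),
                 norm = nrm, sign = "sta", history = history),
            class = "space_time_filter")
}

#' Spike-triggered covariance analysis
#'
#' Eigendecomposition of the difference between the spike-triggered
#' stimulus covariance (around the spike-triggered mean) and the raw
#' stimulus covariance. Positive eigenvalues mark excitatory
#' (variance-increasing) directions, negative eigenvalues suppressive
#' ones.
#'
#' @inheritParams compute_sta
#' @return List with `values` (eigenvalues, decreasing), `vectors`
#'   (unit-norm columns), and the moment matrices `C_spike`, `C_raw`,
#'   `mu_spike`, `mu_raw`.
#' @export
compute_stc <- function(X, counts, history = 5L) {
  stopifnot(nrow(X) == length(counts))
  if (sum(counts) == 0) stop("no spikes: STC undefined")
  raw <- ensemble_moments(X)
  spk <- ensemble_moments(X, counts)
  dC <- spk$C - raw$C
  eg <- eigen(dC, symmetric = TRUE)
  list(values = eg$values, vectors = eg$vectors,
       C_spike = spk$C, C_raw = raw$C,
       mu_spike = spk$mu, mu_raw = raw$mu, history = history)
}

# Gaussian KL divergence (nats) of the spike-triggered vs raw ensemble
# restricted to the subspace spanned by the orthonormal columns of B,
# in coordinates whitened with respect to the raw ensemble.
subspace_kl <- function(B, Lambda, mu) {
  k <- ncol(B)
  LB <- crossprod(B, Lambda %*% B)
  mb <- drop(crossprod(B, mu))
  0.5 * (sum(diag(LB)) - determinant(LB, logarithm = TRUE)$modulus[1] -
           k + sum(mb^2))
}

#' Rank the most informative filters (iSTAC)
#'
#' Greedy selection of the filters, within the space spanned by the STA
#' and the STC eigenvectors, that maximize the Gaussian
#' Kullback-Leibler divergence between the spike-triggered and raw
#' stimulus ensembles. Each filter's incremental information (in bits)
#' quantifies how much it adds to the description of the unit's
#' selectivity; filters are returned in order of decreasing information.
#'
#' @param stc Result of [compute_stc()].
#' @param n_filters Number of filters to keep; `NULL` keeps the smallest
#'   set capturing at least `info_fraction` of the cumulative
#'   information over `max_filters` candidates.
#' @param max_filters Cap on the number of filters.
#' @param info_fraction Cumulative-information criterion used when
#'   `n_filters` is `NULL`.
#' @param sta Optional [compute_sta()] result used to tag STA-like
#'   filters (cosine similarity > 0.9).
#' @param dim_tol Relative eigenvalue cutoff on the raw covariance:
#'   whitening (and the filter search) is restricted to the stimulus
#'   subspace with raw variance at least `dim_tol` times the largest
#'   eigenvalue. Spatially low-pass probe ensembles carry essentially
#'   no power at high spatial frequencies; directions without stimulus
#'   power hold no information and would only amplify estimation noise.
#' @return A `filter_bank` (without nonlinearities; see
#'   [estimate_nonlinearity()]): list of `space_time_filter`s with
#'   `info_bits`, `sign` (`"excitatory"`, `"suppressive"` or `"sta"`)
#'   and `rank`.
#' @export
istac_rank <- function(stc, n_filters = NULL, max_filters = 20L,
                       info_fraction = 0.9, sta = NULL, dim_tol = 1e-5) {
  d0 <- ncol(stc$C_raw)
  history <- stc$history
  n_space <- d0 / history
  # whiten with respect to the raw ensemble, within its supported
  # subspace
  eg0 <- eigen(stc$C_raw, symmetric = TRUE)
  keep0 <- eg0$values >= dim_tol * max(eg0$values)
  V <- eg0$vectors[, keep0, drop = FALSE]
  W0 <- V %*% diag(1 / sqrt(eg0$values[keep0]), sum(keep0))
  d <- ncol(W0)
  Lambda <- crossprod(W0, stc$C_spike %*% W0)
  Lambda <- (Lambda + t(Lambda)) / 2
  mu <- drop(crossprod(W0, stc$mu_spike - stc$mu_raw))
  if (!is.null(n_filters) && n_filters > d)
    stop("n_filters exceeds the dimension of the supported stimulus basis")

  # candidate directions: eigenvectors of the whitened spike-triggered
  # covariance (ranked by deviation from unit variance) plus the mean
  # shift direction
  egL <- eigen(Lambda, symmetric = TRUE)
  dev <- abs(egL$values - 1)
  n_cand <- min(d, 2L * max_filters + 5L)
  cand <- egL$vectors[, order(dev, decreasing = TRUE)[seq_len(n_cand)], drop = FALSE]
  if (sqrt(sum(mu^2)) > 1e-12) cand <- cbind(mu / sqrt(sum(mu^2)), cand)

  n_max <- min(max_filters, if (!is.null(n_filters)) n_filters else max_filters, d)
  B <- matrix(0, d, 0)
  kl_prev <- 0
  info <- numeric(0)
  used <- rep(FALSE, ncol(cand))
  for (step in seq_len(n_max)) {
    best <- -Inf; best_j <- NA_integer_; best_v <- NULL
    for (j in which(!used)) {
      v <- cand[, j]
      if (ncol(B) > 0) v <- v - B %*% crossprod(B, v)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-8) { used[j] <- TRUE; next }
      v <- v / nv
      kl <- subspace_kl(cbind(B, v), Lambda, mu)
      if (kl > best) { best <- kl; best_j <- j; best_v <- v }
    }
    if (is.na(best_j)) break
    used[best_j] <- TRUE
    B <- cbind(B, best_v)
    info <- c(info, (best - kl_prev) / log(2))
    kl_prev <- best
  }
  # order by information (greedy increments are almost always already
  # decreasing; enforce the container invariant)
  ord <- order(info, decreasing = TRUE)
  B <- B[, ord, drop = FALSE]; info <- info[ord]

  if (is.null(n_filters)) {
    cum <- cumsum(info) / sum(info)
    keep <- min(which(cum >= info_fraction))
    B <- B[, seq_len(keep), drop = FALSE]; info <- info[seq_len(keep)]
  }

  sta_vec <- if (!is.null(sta)) as.numeric(t(sta$weights)) else NULL
  filters <- lapply(seq_len(ncol(B)), function(i) {
    f <- drop(W0 %*% B[, i])
    f <- f / sqrt(sum(f^2))
    quad <- drop(crossprod(B[, i], (Lambda - diag(d)) %*% B[, i]))
    sgn <- if (!is.null(sta_vec) &&
               abs(sum(f * sta_vec)) > 0.9) "sta"
           else if (quad >= 0) "excitatory" else "suppressive"
    structure(list(weights = as_filter_matrix(f, history, n_space),
                   info_bits = info[i], sign = sgn, rank = i,
                   history = history, stc_quadform = quad),
              class = "space_time_filter")
  })
  structure(list(filters = filters, info_bits = info,
                 history = history, n_space = n_space),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  signs <- vapply(x$filters, `[[`, "", "sign")
  cat(sprintf("<filter_bank> %d filters (%d excitatory, %d suppressive, %d STA-like), %.3g bits total\n",
              length(x$filters), sum(signs == "excitatory"),
              sum(signs == "suppressive"), sum(signs == "sta"),
              sum(x$info_bits)))
  invisible(x)
}

#' Estimate the static nonlinearity of a filter
#'
#' Bins the raw stimulus projections onto the filter over
#' `mean +/- sd_span` standard deviations and computes the mean spike
#' count of the windows falling in each bin. Empty bins are reported as
#' `NA`, not interpolated.
#'
#' @param filter A `space_time_filter` (or numeric filter vector).
#' @param X Stimulus-history design matrix.
#' @param counts Spike counts aligned with rows of `X`.
#' @param n_bins Number of equal-width projection bins.
#' @param sd_span Half-width of the binned range in projection SDs.
#' @return An object of class `nonlinearity` with `bin_centers`,
#'   `rates`, `mean_rate` and `counts_per_bin`.
#' @export
estimate_nonlinearity <- function(filter, X, counts, n_bins = 25L,
                                  sd_span = 4) {
  f <- if (inherits(filter, "space_time_filter"))
    as.numeric(t(filter$weights)) else as.numeric(filter)
  stopifnot(length(f) == ncol(X), nrow(X) == length(counts))
  p <- drop(X %*% f)
  m <- mean(p); s <- stats::sd(p)
  edges <- seq(m - sd_span * s, m + sd_span * s, length.out = n_bins + 1L)
  bin <- findInterval(p, edges, rightmost.closed = TRUE)
  inside <- bin >= 1L & bin <= n_bins
  rates <- rep(NA_real_, n_bins)
  nb <- tabulate(bin[inside], n_bins)
  sums <- vapply(seq_len(n_bins), function(b)
    sum(counts[inside & bin == b]), numeric(1))
  rates[nb > 0] <- sums[nb > 0] / nb[nb > 0]
  structure(list(bin_centers = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                 rates = rates, mean_rate = mean(counts),
                 counts_per_bin = nb,
                 proj_mean = m, proj_sd = s),
            class = "nonlinearity")
}

# Evaluate a nonlinearity at projection values (nearest-bin lookup with
# clamping; NA bins fall back to linear interpolation between the
# nearest estimated bins).
eval_nonlinearity <- function(nl, p) {
  ok <- !is.na(nl$rates)
  if (!any(ok)) return(rep(nl$mean_rate, length(p)))
  stats::approx(nl$bin_centers[ok], nl$rates[ok], xout = p,
                rule = 2)$y
}

#' Simulate the separable LN model of a filter bank
#'
#' Per response bin, the combined rate is the sum of the individual
#' filter outputs minus `(n - 1)` times the mean rate
#' (`sum_i g_i(p_i) - (n - 1) * rbar`), floored at zero. With a single
#' filter this reduces to `g_1(p_1)` with no correction.
#'
#' @param bank A `filter_bank` with estimated nonlinearities attached
#'   (field `nonlinearities`, parallel to `filters`).
#' @param X Stimulus-history design matrix whose rows are the windows to
#'   respond to (use [build_history_design_padded()] for onset
#'   sequences).
#' @return Numeric rate trajectory, one value per row of `X`.
#' @export
ln_simulate <- function(bank, X) {
  stopifnot(inherits(bank, "filter_bank"), length(bank$filters) >= 1,
            !is.null(bank$nonlinearities))
  n <- length(bank$filters)
  rbar <- bank$nonlinearities[[1L]]$mean_rate
  total <- rep(-(n - 1) * rbar, nrow(X))
  for (i in seq_len(n)) {
    f <- as.numeric(t(bank$filters[[i]]$weights))
    total <- total + eval_nonlinearity(bank$nonlinearities[[i]],
                                       drop(X %*% f))
  }
  pmax(total, 0)
}

#' Fourier-domain summary of space-time filters
#'
#' Two-dimensional discrete Fourier amplitude spectrum of each filter
#' (temporal frequency x spatial frequency, zero frequency centered),
#' plus pooled spectra: the sum of amplitudes over the excitatory and
#' over the suppressive group, each normalized to peak 1.
#'
#' @param bank A `filter_bank` (or list of `space_time_filter`s).
#' @param delta_deg Degrees per spatial sample (bar width), for the
#'   frequency axes.
#' @param frame_dt_s Seconds per time bin.
#' @return List with `spectra` (per filter), `pooled` (named list with
#'   `excitatory`/`suppressive`/`sta` entries present in the bank),
#'   `sf_cpd` and `tf_hz` axes.
#' @export
filter_spectra <- function(bank, delta_deg = 1, frame_dt_s = 1 / 75) {
  filters <- if (inherits(bank, "filter_bank")) bank$filters else bank
  amp <- function(w) {
    a <- Mod(stats::fft(w))
    # center zero frequency
    a[c(((nrow(a) %/% 2) + 1):nrow(a), seq_len(nrow(a) %/% 2)),
      c(((ncol(a) %/% 2) + 1):ncol(a), seq_len(ncol(a) %/% 2))]
  }
  spectra <- lapply(filters, function(f) amp(f$weights))
  signs <- vapply(filters, `[[`, "", "sign")
  pooled <- lapply(split(seq_along(filters), signs), function(idx) {
    s <- Reduce(`+`, spectra[idx])
    s / max(s)
  })
  h <- nrow(filters[[1L]]$weights); ns <- ncol(filters[[1L]]$weights)
  tf <- (seq_len(h) - 1L - h %/% 2) / (h * frame_dt_s)
  sf <- (seq_len(ns) - 1L - ns %/% 2) / (ns * delta_deg)
  list(spectra = spectra, pooled = pooled, tf_hz = tf, sf_cpd = sf)
}

#' Reverse-correlation characterization of network units
#'
#' Probes the trained network with one continuous bar-noise stream
#' (hidden state carried across frames, as when probing an ongoing
#' system), converts each unit's activity to spike counts, and runs the
#' full pipeline: STA, STC, most-informative filter ranking, and a
#' static nonlinearity per filter.
#'
#' @param params A [network_params()].
#' @param grid A [spatial_grid()].
#' @param units Integer indices of the units to characterize.
#' @param type `"output"` or `"hidden"`.
#' @param n_frames Stream length in frames.
#' @param bar_width_units Bar width in grid units (2 for output units,
#'   3 for hidden units on the full-scale grid).
#' @param history History bins per window (5 frames ~ 67 ms).
#' @param n_filters Filters to keep per unit (`NULL` = information
#'   criterion, see [istac_rank()]).
#' @param seed Integer seed for the stream.
#' @param n_bins Nonlinearity bins.
#' @return List of `filter_bank`s (one per unit), each with
#'   `nonlinearities`, `sta`, `stc_values`, `unit`, `mean_rate` and
#'   `bar_width_units` attached.
#' @export
revcorr_units <- function(params, grid, units, type = c("output", "hidden"),
                          n_frames = 2e5, bar_width_units = 2L,
                          history = 5L, n_filters = NULL, seed = 1L,
                          n_bins = 25L) {
  type <- match.arg(type)
  stream <- make_bar_noise_stream(bar_width_units, n_frames, grid,
                                  seed = seed)
  run <- run_sequence(params, stream)
  act <- if (type == "output") run$outputs else run$hidden
  X <- build_history_design(stream$bar_values, history)
  keep <- history:n_frames
  banks <- lapply(units, function(u) {
    spk <- rates_to_spikes(act[keep, u])
    sta <- compute_sta(X, spk$counts, history)
    stc <- compute_stc(X, spk$counts, history)
    bank <- istac_rank(stc, n_filters = n_filters, sta = sta)
    bank$nonlinearities <- lapply(bank$filters, function(f)
      estimate_nonlinearity(f, X, spk$counts, n_bins = n_bins))
    bank$sta <- sta
    bank$stc_values <- stc$values
    bank$unit <- u
    bank$type <- type
    bank$mean_rate <- mean(spk$counts)
    bank$bar_width_units <- bar_width_units
    bank
  })
  names(banks) <- paste0(type, units)
  banks
}

#' Present the same motion inputs to the network and its LN models
#'
#' Simulates `n_patterns` fresh moving-noise sequences per condition and
#' records, for every characterized unit, both the recurrent network's
#' response and the response of its separable LN approximation
#' ([ln_simulate()]) to the identical stimuli. LN windows at sequence
#' onset are zero-padded, matching a network starting from rest.
#'
#' @param params A [network_params()].
#' @param banks List of `filter_bank`s from [revcorr_units()] (output
#'   units).
#' @param grid A [spatial_grid()].
#' @param speeds Speed levels.
#' @param n_patterns Fresh patterns per condition.
#' @param n_frames Frames per sequence.
#' @param seed Integer seed.
#' @param noise_cfg A [noise_config()].
#' @return List with arrays `rmm` and `ln`
#'   (`patterns x conditions x bins x units`), plus `speeds`,
#'   `directions`.
#' @export
compare_rmm_ln <- function(params, banks, grid,
                           speeds = training_speeds(),
                           n_patterns = 200L, n_frames = 5L, seed = 1L,
                           noise_cfg = noise_config()) {
  units <- vapply(banks, `[[`, numeric(1), "unit")
  directions <- rep(c(1, -1), each = length(speeds))
  cond_speeds <- rep(speeds, 2L) * directions
  n_cond <- length(cond_speeds)
  nu <- length(banks)
  rmm <- array(0, c(n_patterns, n_cond, n_frames, nu))
  ln <- array(0, c(n_patterns, n_cond, n_frames, nu))
  withr::with_seed(seed, {
    for (ci in seq_len(n_cond)) {
      sh <- speed_to_shift(cond_speeds[ci], grid)
      for (p in seq_len(n_patterns)) {
        strip <- make_noise_strip(grid$n_units + (n_frames - 1L) * abs(sh),
                                  noise_cfg, grid)
        sq <- make_motion_sequence(strip, n_frames, sh, noise_cfg, grid)
        r <- run_sequence(params, sq)
        rmm[p, ci, , ] <- r$outputs[, units, drop = FALSE]
        for (b in seq_len(nu)) {
          bars <- frames_to_bars(sq$frames, banks[[b]]$bar_width_units)
          Xp <- build_history_design_padded(bars, banks[[b]]$history)
          ln[p, ci, , b] <- ln_simulate(banks[[b]], Xp)
        }
      }
    }
  })
  list(rmm = rmm, ln = ln, speeds = speeds, directions = directions,
       units = units)
}

#' Downsample full-resolution stimulus frames to bar space
#'
#' Averages each frame over the bar groups used during reverse
#' correlation, so that full-resolution stimuli can be projected onto
#' filters estimated in bar space.
#'
#' @param frames `time x n_units` stimulus matrix.
#' @param bar_width_units Bar width in grid units.
#' @return `time x n_bars` matrix.
#' @export
frames_to_bars <- function(frames, bar_width_units) {
  n <- ncol(frames)
  grp <- rep(seq_len(ceiling(n / bar_width_units)),
             each = bar_width_units)[seq_len(n)]
  t(rowsum(t(frames), grp) / as.vector(table(grp)))
}
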