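#' Simple/complex classification from the F1/F0 modulation ratio
#'
#' Presents a drifting grating at the unit's preferred spatial frequency
#' and direction, removes the initial transient, and computes the ratio
#' of the response modulation at the grating temporal frequency (F1,
#' single-sided Fourier amplitude `2|X(f)|/N`) to the mean response
#' (F0). Units with F1/F0 > 1 are phase-sensitive ("simple"-like),
#' others phase-invariant ("complex"-like). The post-transient trace is
#' truncated to an integer number of stimulus cycles so the F1 estimate
#' is leakage-free.
#'
#' @param response Response trace, one value per frame.
#' @param tf_hz Grating temporal frequency in Hz.
#' @param frame_dt_s Seconds per frame.
#' @param transient_frames Frames removed from the start (default 5,
#'   ~67 ms).
#' @return An object of class `modulation_ratio` with `f1`, `f0`,
#'   `ratio` and `label` (`"simple"`/`"complex"`; degenerate zero-mean
#'   traces are flagged `"complex-indeterminate"`).
#' @export
f1f0_classify <- function(response, tf_hz, frame_dt_s = 1 / 75,
                          transient_frames = 5L) {
  stopifnot(length(response) > transient_frames, tf_hz > 0)
  r <- response[-seq_len(transient_frames)]
  n <- length(r)
  # truncate to an integer number of cycles when possible
  cyc <- n * tf_hz * frame_dt_s
  n_use <- floor(floor(cyc) / (tf_hz * frame_dt_s) + 1e-9)
  if (n_use >= 2 && n_use <= n) r <- r[seq_len(n_use)] else n_use <- n
  f0 <- mean(r)
  tt <- (seq_len(n_use) - 1L) * frame_dt_s
  f1 <- 2 * Mod(sum(r * exp(-2i * pi * tf_hz * tt))) / n_use
  if (f0 <= 0) {
    warning("zero mean response: modulation ratio undefined")
    return(structure(list(f1 = f1, f0 = f0, ratio = NA_real_,
                          label = "complex-indeterminate"),
                     class = "modulation_ratio"))
  }
  ratio <- f1 / f0
  structure(list(f1 = f1, f0 = f0, ratio = ratio,
                 label = if (ratio > 1) "simple" else "complex"),
            class = "modulation_ratio")
}

#' Classify every hidden unit with its preferred grating
#'
#' Runs a 10 s drifting grating (0.5 cycles/deg, 16 deg/s by default) in
#' each unit's preferred direction through the network and computes the
#' per-unit F1/F0 ratio.
#'
#' @param params A [network_params()].
#' @param grid A [spatial_grid()].
#' @param pref_direction Vector of +1/-1 per hidden unit (from tuning
#'   measurement); +1 uses positive drift speed.
#' @param sf_cpd,speed_deg_s,duration_s Grating parameters.
#' @return Data frame with `unit`, `f1`, `f0`, `ratio`, `label`.
#' @export
classify_hidden_units <- function(params, grid, pref_direction,
                                  sf_cpd = 0.5, speed_deg_s = 16,
                                  duration_s = 10) {
  n_hidden <- nrow(params$D)
  stopifnot(length(pref_direction) == n_hidden)
  res <- vector("list", 2L)
  for (s in c(1, -1)) {
    g <- make_grating_sequence(sf_cpd, s * speed_deg_s, duration_s, grid)
    res[[if (s > 0) 1L else 2L]] <- run_sequence(params, g)$hidden
  }
  tf <- sf_cpd * speed_deg_s
  out <- lapply(seq_len(n_hidden), function(u) {
    trace <- if (pref_direction[u] > 0) res[[1L]][, u] else res[[2L]][, u]
    m <- f1f0_classify(trace, tf, grid$frame_dt_s)
    data.frame(unit = u, f1 = m$f1, f0 = m$f0, ratio = m$ratio,
               label = m$label)
  })
  do.call(rbind, out)
}

#' One-step indirect input map
#'
#' The indirect input of hidden unit `i` is the afferent input it
#' receives via one step of the recurrent connections: the lateral
#' weight from unit `k` to `i` times the direct input of unit `k`,
#' summed over `k` -- in matrix form `I = M %*% D`.
#'
#' @param M Hidden x hidden lateral weight matrix.
#' @param D Hidden x input direct weight matrix.
#' @return The hidden x input matrix `M %*% D`.
#' @export
indirect_input <- function(M, D) {
  stopifnot(ncol(M) == nrow(D))
  M %*% D
}

#' Spatial shift between direct and indirect input
#'
#' Low-pass filters both weight profiles with the same Gaussian used for
#' the motion inputs, then computes the normalized cross-correlation
#' (Pearson correlation per lag) and takes the lag with the largest
#' value; ties are broken toward the smaller absolute lag. The estimate
#' is valid only when the peak correlation reaches `min_peak`.
#'
#' Sign convention: `dx_units > 0` means the direct profile is displaced
#' by `dx_units` grid units in the positive direction relative to the
#' indirect profile (`direct[j] ~ indirect[j - dx]`), so that a stimulus
#' moving in the positive direction at `dx` units/frame excites the
#' indirect path one frame before the direct path.
#'
#' @param direct_row,indirect_row Weight profiles over input units.
#' @param cfg A [noise_config()] (supplies the low-pass width).
#' @param grid A [spatial_grid()] (degrees per unit).
#' @param max_lag_frac Lags searched as a fraction of the row length.
#' @param min_peak Validity threshold on the peak correlation.
#' @return An object of class `shift_estimate` with `dx_units`,
#'   `dx_deg`, `peak_correlation` and `valid`.
#' @export
estimate_shift <- function(direct_row, indirect_row,
                           cfg = noise_config(),
                           grid = default_grid("full"),
                           max_lag_frac = 0.5, min_peak = 0.5) {
  n <- length(direct_row)
  stopifnot(length(indirect_row) == n)
  if (stats::sd(direct_row) == 0 || stats::sd(indirect_row) == 0)
    return(structure(list(dx_units = NA_integer_, dx_deg = NA_real_,
                          peak_correlation = NA_real_, valid = FALSE),
                     class = "shift_estimate"))
  kernel <- gaussian_kernel(cfg$sigma_lowpass_deg / grid$delta_deg)
  d <- convolve_reflect(direct_row, kernel)
  i <- convolve_reflect(indirect_row, kernel)
  # where the rows are long enough, drop the boundary-contaminated
  # samples (kernel half-width at each end) so that shifted copies stay
  # exact translations after filtering
  half <- (length(kernel) - 1L) %/% 2L
  if (n > 2L * half + 20L) {
    keep <- (half + 1L):(n - half)
    d <- d[keep]; i <- i[keep]
    n <- length(keep)
  }
  max_lag <- floor(n * max_lag_frac)
  lags <- seq.int(-max_lag, max_lag)
  lags <- lags[order(abs(lags))]   # ties resolve toward smaller |lag|
  best <- -Inf; best_lag <- 0L
  for (L in lags) {
    if (L >= 0) { a <- d[(1L + L):n]; b <- i[1L:(n - L)] }
    else        { a <- d[1L:(n + L)]; b <- i[(1L - L):n] }
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    if (r > best + 1e-12) { best <- r; best_lag <- L }
  }
  structure(list(dx_units = as.integer(best_lag),
                 dx_deg = best_lag * grid$delta_deg,
                 peak_correlation = best,
                 valid = is.finite(best) && best >= min_peak),
            class = "shift_estimate")
}

#' Delay-line speed prediction
#'
#' Under a linear-summation reading of the recurrent network -- the
#' indirect input is a copy of the direct input displaced by `dx` and
#' delayed by one simulation step `dt` -- the unit's preferred speed
#' would be `dx / dt`.
#'
#' @param shift A valid `shift_estimate`.
#' @param grid A [spatial_grid()].
#' @return Signed predicted speed in deg/s.
#' @export
linear_prediction <- function(shift, grid) {
  stopifnot(inherits(shift, "shift_estimate"))
  if (!isTRUE(shift$valid)) stop("shift estimate is not valid")
  shift$dx_deg / grid$frame_dt_s
}

#' Predicted versus measured preferred speed per hidden unit
#'
#' Joins the delay-line speed predictions with the measured preferred
#' speeds, keeping only units with a valid shift estimate, and reports
#' agreement statistics split by simple/complex label.
#'
#' @param actual_speed Signed measured preferred speed per hidden unit
#'   (sign = direction).
#' @param shifts List of `shift_estimate`s, one per hidden unit.
#' @param labels Character vector of `"simple"`/`"complex"` labels.
#' @param grid A [spatial_grid()].
#' @return List with `table` (unit, predicted, actual, label) and
#'   `stats` (per label: n, sign-agreement rate, fraction within a
#'   factor of 2 in magnitude).
#' @export
prediction_vs_actual <- function(actual_speed, shifts, labels, grid) {
  n <- length(actual_speed)
  stopifnot(length(shifts) == n, length(labels) == n)
  valid <- vapply(shifts, function(s) isTRUE(s$valid), logical(1))
  if (!any(valid)) stop("no units with a valid shift estimate")
  tab <- data.frame(
    unit = which(valid),
    predicted = vapply(shifts[valid], linear_prediction, numeric(1),
                       grid = grid),
    actual = actual_speed[valid],
    label = labels[valid])
  per_label <- lapply(split(tab, tab$label), function(g) {
    nonzero <- g$predicted != 0 & g$actual != 0
    data.frame(
      label = g$label[1], n = nrow(g),
      sign_agreement = mean(sign(g$predicted[nonzero]) ==
                              sign(g$actual[nonzero])),
      within_factor2 = mean(nonzero &
        abs(log2(abs(g$predicted / g$actual))) <= 1))
  })
  list(table = tab, stats = do.call(rbind, per_label))
}

#' Sort the hidden-to-output weight matrix by preferred speed
#'
#' Permutes the columns (hidden units) and rows (output units) of
#' `W_out` by preferred speed and summarizes the block structure: the
#' mean weight between speed-matched pairs (preferred speeds within
#' `match_oct` octaves) versus mismatched pairs.
#'
#' @param W_out Output x hidden weight matrix.
#' @param hidden_pref Preferred speed (deg/s, magnitude) per hidden
#'   unit; use the preferred-direction or anti-preferred-direction
#'   tuning to reproduce the two sorting layouts.
#' @param output_pref Preferred speed per output unit.
#' @param match_oct Octave tolerance defining "matched" speeds.
#' @return List with `sorted` (permuted matrix), `hidden_order`,
#'   `output_order`, `matched_mean`, `mismatched_mean`.
#' @export
weight_sorting <- function(W_out, hidden_pref, output_pref,
                           match_oct = 0.5) {
  stopifnot(ncol(W_out) == length(hidden_pref),
            nrow(W_out) == length(output_pref))
  ho <- order(hidden_pref); oo <- order(output_pref)
  sorted <- W_out[oo, ho, drop = FALSE]
  dist_oct <- abs(outer(log2(output_pref), log2(hidden_pref), `-`))
  matched <- dist_oct <= match_oct
  list(sorted = sorted, hidden_order = ho, output_order = oo,
       matched_mean = mean(W_out[matched]),
       mismatched_mean = mean(W_out[!matched]))
}

#' Principal components of the direct input weights
#'
#' PCA of the hidden units' direct-weight rows (mean-centered, no
#' variance scaling). In a trained motion network a handful of
#' quadrature-pair (Gabor-like) components typically capture most of
#' the variance.
#'
#' @param D Hidden x input weight matrix.
#' @return List with `components` (input x component matrix),
#'   `variance_fraction` and the `prcomp` object.
#' @export
input_weight_pca <- function(D) {
  stopifnot(nrow(D) >= 2)
  pc <- stats::prcomp(D, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(components = pc$rotation, variance_fraction = vf, prcomp = pc)
}
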