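#' Direction selectivity index
#'
#' `(preferred - anti) / (preferred + anti)` evaluated at the speed that
#' maximizes the preferred-direction curve; `anti` is the
#' anti-preferred-direction response at that same speed.
#'
#' @param pref_curve Non-negative responses over speeds, preferred
#'   direction.
#' @param anti_curve Matching responses in the anti-preferred direction.
#' @return DSI in `[-1, 1]` (in `[0, 1]` when the preferred direction
#'   truly dominates); `NA` with a warning when the denominator is zero.
#' @export
dsi <- function(pref_curve, anti_curve) {
  stopifnot(length(pref_curve) == length(anti_curve),
            all(pref_curve >= 0), all(anti_curve >= 0))
  i <- which.max(pref_curve)
  p <- unname(pref_curve[i]); a <- unname(anti_curve[i])
  if (p + a == 0) {
    warning("DSI undefined: zero response at the preferred speed")
    return(NA_real_)
  }
  (p - a) / (p + a)
}

#' Speed tuning index
#'
#' `(max - min) / (max + min)` over the speed tuning curve in the
#' preferred direction.
#'
#' @param pref_curve Non-negative responses over speeds.
#' @return SI in `[0, 1]`; `NA` with a warning when the curve is all
#'   zero.
#' @export
si <- function(pref_curve) {
  stopifnot(all(pref_curve >= 0))
  mx <- max(pref_curve); mn <- min(pref_curve)
  if (mx == 0) {
    warning("SI undefined: all-zero tuning curve")
    return(NA_real_)
  }
  (mx - mn) / (mx + mn)
}

#' Summarize a unit's tuning from pattern x condition x bin responses
#'
#' The tuning curve is the mean response over time bins and stimulus
#' patterns per condition. The preferred direction of the unit is the
#' direction containing the global maximum of the curve (ties broken
#' toward the population-preferred direction, `directions == 1`);
#' steady-state DSI/SI use the whole trained window, per-step indices
#' ([per_step_indices()]) use single bins 2 onwards.
#'
#' @param responses Array `patterns x conditions x bins` (a single
#'   pattern may be passed as a `conditions x bins` matrix) of
#'   non-negative responses.
#' @param speeds Speed level per condition-half (length `n_cond / 2`).
#' @param directions Direction labels per condition (+1 / -1), paired
#'   with `rep(speeds, 2)`.
#' @return An object of class `tuning_summary` with fields `curve`
#'   (speed x direction matrix of condition means), `dsi`, `si`,
#'   `pref_speed_deg_s` (signed: negative = anti-preferred direction
#'   preferred), `pref_direction`, `per_step_dsi`, `per_step_si`.
#' @export
measure_tuning <- function(responses, speeds = training_speeds(),
                           directions = rep(c(1, -1), each = length(speeds))) {
  if (length(dim(responses)) == 2L)
    responses <- array(responses, c(1L, dim(responses)))
  stopifnot(length(dim(responses)) == 3L,
            dim(responses)[2] == 2L * length(speeds),
            all(responses >= 0))
  cond_mean <- apply(responses, 2L, mean)
  curve <- cbind(pref = cond_mean[directions > 0],
                 anti = cond_mean[directions < 0])
  rownames(curve) <- as.character(speeds)
  if (max(curve) == 0) {
    warning("all-zero responses: tuning indices undefined")
    return(structure(list(curve = curve, dsi = NA_real_, si = NA_real_,
                          pref_speed_deg_s = NA_real_,
                          pref_direction = NA_real_,
                          per_step_dsi = NULL, per_step_si = NULL),
                     class = "tuning_summary"))
  }
  pref_dir <- if (max(curve[, "pref"]) >= max(curve[, "anti"])) 1 else -1
  pc <- if (pref_dir > 0) curve[, "pref"] else curve[, "anti"]
  ac <- if (pref_dir > 0) curve[, "anti"] else curve[, "pref"]
  ps <- per_step_indices(responses, speeds, directions,
                         pref_direction = pref_dir)
  structure(list(curve = curve,
                 dsi = dsi(pc, ac),
                 si = si(pc),
                 pref_speed_deg_s = pref_dir * speeds[which.max(pc)],
                 pref_direction = pref_dir,
                 per_step_dsi = ps$dsi, per_step_si = ps$si),
            class = "tuning_summary")
}

#' @export
print.tuning_summary <- function(x, ...) {
  cat(sprintf("<tuning_summary> pref %.3g deg/s, DSI %.3f, SI %.3f\n",
              x$pref_speed_deg_s, x$dsi, x$si))
  invisible(x)
}

#' Per-motion-step selectivity indices
#'
#' DSI and SI computed from the mean response within each single time
#' bin from bin 2 onwards (the first bin reflects a single frame and
#' carries no motion information yet). Used to trace the build-up of
#' selectivity over successive steps of an apparent-motion sequence
#' (sequential recruitment).
#'
#' @inheritParams measure_tuning
#' @param steps Bin indices to evaluate (default 2..n_bins).
#' @param pref_direction Optional fixed preferred direction (+1/-1);
#'   when `NULL` it is taken from the across-bin mean curve.
#' @return List with vectors `dsi` and `si` (named by bin) and `steps`.
#' @export
per_step_indices <- function(responses, speeds = training_speeds(),
                             directions = rep(c(1, -1), each = length(speeds)),
                             steps = NULL, pref_direction = NULL) {
  if (length(dim(responses)) == 2L)
    responses <- array(responses, c(1L, dim(responses)))
  nb <- dim(responses)[3]
  if (is.null(steps)) steps <- 2:nb
  stopifnot(all(steps >= 1), all(steps <= nb))
  if (is.null(pref_direction)) {
    cm <- apply(responses, 2L, mean)
    pref_direction <- if (max(cm[directions > 0]) >= max(cm[directions < 0])) 1 else -1
  }
  out_dsi <- out_si <- numeric(length(steps))
  for (j in seq_along(steps)) {
    bm <- apply(responses[, , steps[j], drop = FALSE], 2L, mean)
    pc <- bm[directions == pref_direction]
    ac <- bm[directions == -pref_direction]
    out_dsi[j] <- dsi(pc, ac)
    out_si[j] <- si(pc)
  }
  names(out_dsi) <- names(out_si) <- paste0("bin", steps)
  list(dsi = out_dsi, si = out_si, steps = steps)
}

#' Squared correlation between two tuning curves
#'
#' Squared Pearson correlation between two pooled tuning-curve vectors
#' (e.g. the velocity curve measured with noise patterns versus with
#' gratings). Affine transformations of either curve leave it unchanged.
#'
#' @param curve_a,curve_b Numeric vectors (or matrices, flattened) on
#'   matched condition grids.
#' @return R^2 in `[0, 1]`; `NA` with a warning for zero-variance input.
#' @export
pattern_invariance_r2 <- function(curve_a, curve_b) {
  a <- as.numeric(curve_a); b <- as.numeric(curve_b)
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance curve: R^2 undefined")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Measure tuning of every network unit with fresh noise patterns
#'
#' Presents `n_patterns` new moving-noise sequences at each of the 14
#' conditions (7 speeds x 2 directions) and records the per-bin
#' responses of either the output or the hidden units, from which
#' per-unit [measure_tuning()] summaries are computed.
#'
#' @param params A [network_params()].
#' @param grid A [spatial_grid()].
#' @param speeds Speed levels.
#' @param n_patterns Fresh patterns per condition.
#' @param n_frames Frames per sequence.
#' @param units `"output"` or `"hidden"`.
#' @param seed Integer seed; pattern `p` of condition `c` is seeded
#'   reproducibly from it.
#' @param noise_cfg A [noise_config()].
#' @return List with `summaries` (per-unit `tuning_summary`),
#'   `responses` (`patterns x conditions x bins x units` array),
#'   `speeds`, `directions`.
#' @export
measure_network_tuning <- function(params, grid, speeds = training_speeds(),
                                   n_patterns = 100L, n_frames = 5L,
                                   units = c("output", "hidden"),
                                   seed = 1L,
                                   noise_cfg = noise_config()) {
  units <- match.arg(units)
  directions <- rep(c(1, -1), each = length(speeds))
  cond_speeds <- rep(speeds, 2L) * directions
  n_cond <- length(cond_speeds)
  n_units <- if (units == "output") nrow(params$W_out) else nrow(params$D)
  resp <- array(0, c(n_patterns, n_cond, n_frames, n_units))
  withr::with_seed(seed, {
    for (ci in seq_len(n_cond)) {
      sh <- speed_to_shift(cond_speeds[ci], grid)
      for (p in seq_len(n_patterns)) {
        strip <- make_noise_strip(grid$n_units + (n_frames - 1L) * abs(sh),
                                  noise_cfg, grid)
        sq <- make_motion_sequence(strip, n_frames, sh, noise_cfg, grid)
        r <- run_sequence(params, sq)
        resp[p, ci, , ] <- if (units == "output") r$outputs else r$hidden
      }
    }
  })
  summaries <- lapply(seq_len(n_units), function(u)
    measure_tuning(resp[, , , u, drop = TRUE], speeds, directions))
  list(summaries = summaries, responses = resp,
       speeds = speeds, directions = directions)
}

#' Measure tuning with drifting gratings
#'
#' As [measure_network_tuning()] but with drifting sinusoidal gratings
#' of spatial frequency `sf_cpd` at every condition, using `n_phases`
#' random initial phases in place of fresh noise patterns.
#'
#' @inheritParams measure_network_tuning
#' @param sf_cpd Grating spatial frequency (cycles/deg).
#' @param n_phases Random initial phases per condition.
#' @param amplitude Grating amplitude; the default 0.3 matches the RMS
#'   contrast of the moving-noise inputs the network is trained on
#'   (noise SD ~0.21, sine RMS `amplitude / sqrt(2)`).
#' @return Same structure as [measure_network_tuning()].
#' @export
measure_grating_tuning <- function(params, grid, speeds = training_speeds(),
                                   sf_cpd = 0.5, n_phases = 20L,
                                   n_frames = 5L,
                                   units = c("output", "hidden"),
                                   seed = 1L, amplitude = 0.3) {
  units <- match.arg(units)
  directions <- rep(c(1, -1), each = length(speeds))
  cond_speeds <- rep(speeds, 2L) * directions
  n_cond <- length(cond_speeds)
  n_units <- if (units == "output") nrow(params$W_out) else nrow(params$D)
  resp <- array(0, c(n_phases, n_cond, n_frames, n_units))
  duration <- n_frames * grid$frame_dt_s
  withr::with_seed(seed, {
    phases <- stats::runif(n_phases, 0, 2 * pi)
    for (ci in seq_len(n_cond)) {
      for (p in seq_len(n_phases)) {
        sq <- make_grating_sequence(sf_cpd, cond_speeds[ci], duration,
                                    grid, phase0 = phases[p],
                                    amplitude = amplitude)
        sq$frames <- sq$frames[seq_len(n_frames), , drop = FALSE]
        r <- run_sequence(params, sq)
        resp[p, ci, , ] <- if (units == "output") r$outputs else r$hidden
      }
    }
  })
  summaries <- lapply(seq_len(n_units), function(u)
    measure_tuning(resp[, , , u, drop = TRUE], speeds, directions))
  list(summaries = summaries, responses = resp,
       speeds = speeds, directions = directions)
}
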