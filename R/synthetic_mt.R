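#' Specification of a synthetic MT-like cell
#'
#' Parameterizes the firing-rate model used to emulate the statistical
#' structure of speed- and direction-tuned MT responses: log-Gaussian
#' band-pass speed tuning, a saturating onset ramp after a ~30 ms
#' latency, and direction selectivity that develops over the ramp to a
#' steady-state direction selectivity index (DSI) of `dsi_target`. The
#' onset response is unselective and selectivity is maximal once tuning
#' has stabilized (~93 ms after onset), matching the population dynamics
#' the model is trained to reproduce.
#'
#' @param pref_speed_deg_s Preferred speed in deg/s (selection window is
#'   8--32 deg/s).
#' @param speed_bandwidth_oct Tuning width (SD of the log2-speed
#'   Gaussian) in octaves.
#' @param dsi_target Steady-state DSI in (0.1, 1].
#' @param latency_ms Response latency in ms.
#' @param peak_rate_hz Steady-state rate at the preferred speed and
#'   direction, in spikes/s.
#' @param ramp_time_ms Time at which tuning is stable (the center of the
#'   last trained bin); the onset ramp and the selectivity ramp are
#'   normalized to reach 1 exactly there.
#' @param tau_ms Time constant of the saturating exponential ramp.
#' @param anti_pref_speed_deg_s Preferred speed of the (weaker)
#'   anti-preferred-direction tuning; defaults to `pref_speed_deg_s`, and
#'   may be set lower to emulate the excitation/suppression asymmetry
#'   seen in MT-like populations.
#' @param dsi_ramp Logical; if `TRUE` (default) direction selectivity
#'   develops over the onset ramp, if `FALSE` it is constant in time.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(pref_speed_deg_s,
                      speed_bandwidth_oct = 1.5,
                      dsi_target = 0.5,
                      latency_ms = 30,
                      peak_rate_hz = 40,
                      ramp_time_ms = NULL,
                      tau_ms = 25,
                      anti_pref_speed_deg_s = NULL,
                      dsi_ramp = TRUE) {
  if (is.null(ramp_time_ms)) ramp_time_ms <- target_bin_centers_ms()[5L]
  stopifnot(pref_speed_deg_s > 0, speed_bandwidth_oct > 0,
            dsi_target > 0, dsi_target <= 1,
            latency_ms >= 0, peak_rate_hz > 0,
            ramp_time_ms > latency_ms, tau_ms > 0)
  if (is.null(anti_pref_speed_deg_s))
    anti_pref_speed_deg_s <- pref_speed_deg_s
  structure(list(pref_speed_deg_s = pref_speed_deg_s,
                 speed_bandwidth_oct = speed_bandwidth_oct,
                 dsi_target = dsi_target,
                 latency_ms = latency_ms,
                 peak_rate_hz = peak_rate_hz,
                 ramp_time_ms = ramp_time_ms,
                 tau_ms = tau_ms,
                 anti_pref_speed_deg_s = anti_pref_speed_deg_s,
                 dsi_ramp = dsi_ramp),
            class = "cell_spec")
}

#' The seven experimental speeds
#' @return Numeric vector `c(1, 2, 4, 8, 16, 32, 64)` deg/s.
#' @export
training_speeds <- function() c(1, 2, 4, 8, 16, 32, 64)

#' Centers of the five trained time bins
#'
#' The network is trained on the window in which speed tuning and
#' direction selectivity emerge: five 13.33 ms monitor-frame bins
#' spanning 27--93 ms after stimulus onset (bins 3--7 of a 75 Hz
#' binning).
#'
#' @param frame_rate_hz Frame rate defining the bin width.
#' @return Bin-center times in ms (length 5).
#' @export
target_bin_centers_ms <- function(frame_rate_hz = 75) {
  dt <- 1000 / frame_rate_hz
  2 * dt + (seq_len(5L) - 0.5) * dt
}

# Saturating-exponential ramp, 0 before latency, exactly 1 at ramp_time.
onset_ramp <- function(t_ms, spec) {
  num <- 1 - exp(-pmax(t_ms - spec$latency_ms, 0) / spec$tau_ms)
  den <- 1 - exp(-(spec$ramp_time_ms - spec$latency_ms) / spec$tau_ms)
  pmin(num / den, 1)
}

log_gauss_tuning <- function(speed, center, bw_oct) {
  exp(-log2(speed / center)^2 / (2 * bw_oct^2))
}

#' Generate the response matrix of one synthetic cell
#'
#' Rates (spikes/s) for the 14 conditions (7 speeds x 2 directions) at
#' the five trained bin centers. The preferred-direction response is
#' `peak * tuning(speed) * ramp(t)`; the anti-preferred response is
#' additionally multiplied by a direction gain that (when `dsi_ramp`)
#' relaxes from 1 at onset to `(1 - DSI) / (1 + DSI)` at the last bin,
#' so the steady-state DSI equals `dsi_target` exactly. Optional
#' multiplicative noise emulates trial-to-trial variability.
#'
#' @param spec A [cell_spec()].
#' @param speeds Speed levels in deg/s.
#' @param seed Optional seed for the noise.
#' @param noise_sd SD of multiplicative Gaussian noise (0 = noise-free).
#' @return A `14 x 5` matrix (conditions x bins) with condition metadata
#'   in attributes `speeds` and `direction` (+1 preferred, -1 anti).
#' @export
generate_cell_response <- function(spec, speeds = training_speeds(),
                                   seed = NULL, noise_sd = 0) {
  stopifnot(inherits(spec, "cell_spec"), all(speeds > 0), noise_sd >= 0)
  t_ms <- target_bin_centers_ms()
  ramp <- onset_ramp(t_ms, spec)
  g_anti <- (1 - spec$dsi_target) / (1 + spec$dsi_target)
  gain_t <- if (spec$dsi_ramp) 1 - (1 - g_anti) * ramp else rep(g_anti, 5L)
  pref <- outer(log_gauss_tuning(speeds, spec$pref_speed_deg_s,
                                 spec$speed_bandwidth_oct), ramp)
  anti <- outer(log_gauss_tuning(speeds, spec$anti_pref_speed_deg_s,
                                 spec$speed_bandwidth_oct), ramp) *
    matrix(gain_t, length(speeds), 5L, byrow = TRUE)
  rates <- spec$peak_rate_hz * rbind(pref, anti)
  if (noise_sd > 0) {
    jitter <- function() matrix(stats::rnorm(length(rates), 1, noise_sd),
                                nrow = nrow(rates))
    eps <- if (is.null(seed)) jitter() else withr::with_seed(seed, jitter())
    rates <- pmax(rates * eps, 0)
  }
  attr(rates, "speeds") <- rep(speeds, 2L)
  attr(rates, "direction") <- rep(c(1, -1), each = length(speeds))
  rates
}

#' Draw a population of synthetic cell specifications
#'
#' Preferred speeds are log-uniform over `pref_range`, steady-state DSI
#' uniform over `dsi_range`, peak rates uniform over `rate_range`, and
#' the anti-preferred tuning peak is shifted down by up to one octave to
#' emulate the asymmetry between excitation and suppression.
#'
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param pref_range,dsi_range,rate_range,bw_range Parameter ranges.
#' @return List of [cell_spec()] objects.
#' @export
mt_population <- function(n_cells = 26L, seed = 1L,
                          pref_range = c(8, 32),
                          dsi_range = c(0.2, 0.8),
                          rate_range = c(20, 60),
                          bw_range = c(1.2, 1.8)) {
  stopifnot(n_cells >= 1)
  withr::with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      pref <- 2^stats::runif(1, log2(pref_range[1]), log2(pref_range[2]))
      cell_spec(pref_speed_deg_s = pref,
                speed_bandwidth_oct = stats::runif(1, bw_range[1], bw_range[2]),
                dsi_target = stats::runif(1, dsi_range[1], dsi_range[2]),
                peak_rate_hz = stats::runif(1, rate_range[1], rate_range[2]),
                anti_pref_speed_deg_s = pref * 2^-stats::runif(1, 0, 1))
    })
  })
}

#' Apply the cell-selection filter
#'
#' Keeps cells with (i) mean rate over all speeds in the preferred
#' direction strictly above `min_rate_hz`, (ii) steady-state DSI
#' strictly above `min_dsi`, and (iii) preferred speed inside
#' `pref_range`. All three predicates are evaluated on the realized rate
#' matrices, using the steady-state (last-bin) responses for the
#' indices.
#'
#' @param specs List of [cell_spec()].
#' @param rates List of matrices from [generate_cell_response()],
#'   parallel to `specs`. Generated noise-free when omitted.
#' @param min_rate_hz,min_dsi,pref_range Selection thresholds.
#' @param speeds Speed levels the rates were generated at.
#' @return List with elements `specs`, `rates` (the retained subset) and
#'   `keep` (logical index into the input).
#' @export
select_cells <- function(specs, rates = NULL, min_rate_hz = 7,
                         min_dsi = 0.1, pref_range = c(8, 32),
                         speeds = training_speeds()) {
  stopifnot(length(specs) >= 1)
  if (is.null(rates))
    rates <- lapply(specs, generate_cell_response, speeds = speeds)
  stopifnot(length(rates) == length(specs))
  ns <- length(speeds)
  keep <- vapply(seq_along(specs), function(i) {
    r <- rates[[i]]
    pref <- r[seq_len(ns), , drop = FALSE]
    anti <- r[ns + seq_len(ns), , drop = FALSE]
    mean_rate <- mean(pref)
    ss_pref <- pref[, ncol(pref)]
    ss_anti <- anti[, ncol(anti)]
    best <- which.max(ss_pref)
    d <- dsi(ss_pref, ss_anti)
    pref_speed <- speeds[best]
    isTRUE(mean_rate > min_rate_hz) && isTRUE(d > min_dsi) &&
      pref_speed >= pref_range[1] && pref_speed <= pref_range[2]
  }, logical(1))
  list(specs = specs[keep], rates = rates[keep], keep = keep)
}

#' Assemble the normalized target response set
#'
#' Stacks the per-cell rate matrices into a `cell x condition x bin`
#' array and normalizes by the single global maximum over all cells,
#' conditions and bins, producing values in `[0, 1]` with global max 1 --
#' a suitable range for the sigmoid output units.
#'
#' @param rates List of matrices from [generate_cell_response()].
#' @param speeds Speed levels.
#' @return An object of class `target_response_set` with fields `rates`
#'   (normalized array), `peak_rate_hz` (the raw global maximum in Hz),
#'   `speeds_deg_s`, `directions` and `bin_centers_ms`.
#' @export
assemble_target_set <- function(rates, speeds = training_speeds()) {
  stopifnot(length(rates) >= 1)
  arr <- aperm(simplify2array(rates), c(3L, 1L, 2L))
  peak <- max(arr)
  if (peak <= 0) stop("all-zero rates: normalization undefined")
  structure(list(rates = arr / peak,
                 peak_rate_hz = peak,
                 speeds_deg_s = speeds,
                 directions = rep(c(1, -1), each = length(speeds)),
                 condition_speeds = rep(speeds, 2L),
                 bin_centers_ms = target_bin_centers_ms()),
            class = "target_response_set")
}

#' Generate a complete synthetic target set in one call
#'
#' Draws a population, applies the selection filter, and keeps drawing
#' further candidate cells (advancing the seed) until `n_cells` pass, so
#' the returned set always has exactly `n_cells` cells, all satisfying
#' the selection criteria.
#'
#' @param n_cells Number of cells in the returned set.
#' @param seed Integer seed.
#' @param noise_sd Multiplicative noise SD passed to the generator.
#' @param ... Passed to [mt_population()].
#' @return List with `target_set` (a `target_response_set`) and `specs`.
#' @export
make_synthetic_targets <- function(n_cells = 26L, seed = 1L,
                                   noise_sd = 0, ...) {
  specs <- list(); rates <- list(); draw_seed <- seed; round <- 0L
  while (length(specs) < n_cells && round < 50L) {
    pop <- mt_population(n_cells, seed = draw_seed, ...)
    pr <- lapply(seq_along(pop), function(i)
      generate_cell_response(pop[[i]], seed = draw_seed * 1000L + i,
                             noise_sd = noise_sd))
    sel <- select_cells(pop, pr)
    specs <- c(specs, sel$specs)
    rates <- c(rates, sel$rates)
    draw_seed <- draw_seed + 7919L
    round <- round + 1L
  }
  if (length(specs) < n_cells)
    stop("could not realize the requested number of selectable cells")
  specs <- specs[seq_len(n_cells)]
  rates <- rates[seq_len(n_cells)]
  list(target_set = assemble_target_set(rates), specs = specs)
}

#' @export
print.target_response_set <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("<target_response_set> %d cells x %d conditions x %d bins, global max %.3g (normalized to 1)\n",
              d[1], d[2], d[3], max(x$rates)))
  invisible(x)
}
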