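#' Resolve an experiment configuration
#'
#' Bundles every stage's settings and seeds into one structure. Presets:
#' `"full"` is the published-scale configuration (750 inputs / 300
#' hidden / 26 cells, 5e6 training epochs, 2e6 reverse-correlation
#' frames); `"desk"` is a single-CPU configuration with the same
#' spatial resolution (150 inputs / 60 hidden / 6 cells, 2e5 epochs,
#' 2e5 frames); `"tiny"` is a seconds-scale smoke configuration.
#' Every random stage derives its own sub-seed from `seed`.
#'
#' @param scale `"desk"`, `"full"` or `"tiny"`.
#' @param seed Master integer seed.
#' @param ... Named overrides of individual fields.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scale = c("desk", "full", "tiny"),
                              seed = 1L, ...) {
  scale <- match.arg(scale)
  base <- switch(scale,
    full = list(n_input = 750L, n_hidden = 300L, n_cells = 26L,
                span_deg = 10, n_epochs = 5e6, revcorr_frames = 2e6,
                revcorr_frames_hidden = 1e6, n_patterns = 1000L),
    desk = list(n_input = 150L, n_hidden = 60L, n_cells = 6L,
                span_deg = 2, n_epochs = 2e5, revcorr_frames = 2e5,
                revcorr_frames_hidden = 1e5, n_patterns = 1000L),
    tiny = list(n_input = 40L, n_hidden = 12L, n_cells = 3L,
                span_deg = 40 / 75, n_epochs = 2000, revcorr_frames = 5000,
                revcorr_frames_hidden = 5000, n_patterns = 20L))
  cfg <- utils::modifyList(c(base, list(
    scale = scale,
    seed = as.integer(seed),
    learning_rate = 0.01, momentum = 0.9,
    sequence_length = 5L,
    bar_width_output = 2L, bar_width_hidden = 3L,
    history = 5L,
    sf_cpd = 0.5,
    noise = noise_config())), list(...))
  cfg$grid <- spatial_grid(cfg$n_input, cfg$span_deg)
  structure(cfg, class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> scale=%s: %d/%d/%d net, %g epochs, seed %d\n",
              x$scale, x$n_input, x$n_hidden, x$n_cells, x$n_epochs,
              x$seed))
  invisible(x)
}

# %.17g guarantees an exact double round trip, so resumed runs see
# bit-identical parameters
write_matrix_csv <- function(m, path) {
  ch <- matrix(sprintf("%.17g", m), nrow(m))
  utils::write.table(ch, path, sep = ",", row.names = FALSE,
                     col.names = paste0("V", seq_len(ncol(m))),
                     quote = FALSE)
}
read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Serialize network parameters to a directory of CSV files
#'
#' Writes `D.csv`, `M.csv`, `W_out.csv`, `biases.csv` and a `meta.json`
#' with the shapes, as plain-text interchange.
#'
#' @param params A [network_params()].
#' @param dir Output directory (created if missing).
#' @export
save_network_params <- function(params, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_csv(params$D, file.path(dir, "D.csv"))
  write_matrix_csv(params$M, file.path(dir, "M.csv"))
  write_matrix_csv(params$W_out, file.path(dir, "W_out.csv"))
  nmax <- max(length(params$b_hidden), length(params$b_out))
  pad <- function(v) sprintf("%.17g", c(v, rep(NA, nmax - length(v))))
  utils::write.table(data.frame(b_hidden = pad(params$b_hidden),
                                b_out = pad(params$b_out)),
                     file.path(dir, "biases.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(n_input = ncol(params$D),
                            n_hidden = nrow(params$D),
                            n_output = nrow(params$W_out)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load network parameters saved by [save_network_params()]
#' @param dir Directory containing the CSV files.
#' @return A [network_params()].
#' @export
load_network_params <- function(dir) {
  b <- utils::read.csv(file.path(dir, "biases.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  network_params(read_matrix_csv(file.path(dir, "D.csv")),
                 read_matrix_csv(file.path(dir, "M.csv")),
                 read_matrix_csv(file.path(dir, "W_out.csv")),
                 b$b_hidden[seq_len(meta$n_hidden)],
                 b$b_out[seq_len(meta$n_output)])
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- synthetic targets, network training,
#' tuning measurement (noise and gratings), reverse correlation of the
#' output units, connectivity analyses -- writing each stage's artifacts
#' as CSV/JSON under `out_dir`. Reruns with the same configuration are
#' bit-identical. With `resume = TRUE`, stages whose artifacts already
#' exist are skipped and only missing (downstream) stages are
#' recomputed.
#'
#' @param config An [experiment_config()].
#' @param out_dir Artifact directory.
#' @param resume Skip stages whose outputs already exist.
#' @param revcorr_units_n Number of output units to reverse-correlate
#'   (counted from unit 1); defaults to all.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE,
                         revcorr_units_n = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- config$grid
  done <- function(...) all(file.exists(file.path(out_dir, c(...))))
  res <- list(config = config)

  # stage 1: synthetic targets
  if (!(resume && done("targets.csv", "cell_specs.json"))) {
    syn <- make_synthetic_targets(config$n_cells, seed = config$seed)
    tgt_df <- target_set_to_df(syn$target_set)
    utils::write.csv(tgt_df, file.path(out_dir, "targets.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(syn$specs, unclass),
                         file.path(out_dir, "cell_specs.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    syn <- list(target_set = df_to_target_set(
      utils::read.csv(file.path(out_dir, "targets.csv"))))
  }
  res$target_set <- syn$target_set

  # stage 2: training
  if (!(resume && done("model/meta.json", "loss.csv"))) {
    init <- init_nguyen_widrow(config$n_input, config$n_hidden,
                               config$n_cells, seed = config$seed + 1L)
    tr <- train_rmm(init, syn$target_set, grid,
                    training_config(n_epochs = config$n_epochs,
                                    learning_rate = config$learning_rate,
                                    momentum = config$momentum,
                                    sequence_length = config$sequence_length,
                                    seed = config$seed + 2L))
    save_network_params(tr$params, file.path(out_dir, "model"))
    utils::write.csv(data.frame(epoch = tr$loss_epoch,
                                sum_squared_error = tr$loss),
                     file.path(out_dir, "loss.csv"), row.names = FALSE)
    params <- tr$params
  } else {
    params <- load_network_params(file.path(out_dir, "model"))
  }
  res$params <- params

  # stage 3: tuning (noise and gratings)
  if (!(resume && done("tuning_noise.csv", "tuning_gratings.csv",
                       "tuning_summary.json"))) {
    tun <- measure_network_tuning(params, grid,
                                  n_patterns = config$n_patterns,
                                  seed = config$seed + 3L)
    grat <- measure_grating_tuning(params, grid, sf_cpd = config$sf_cpd,
                                   seed = config$seed + 4L)
    utils::write.csv(tuning_to_df(tun), file.path(out_dir, "tuning_noise.csv"),
                     row.names = FALSE)
    utils::write.csv(tuning_to_df(grat),
                     file.path(out_dir, "tuning_gratings.csv"),
                     row.names = FALSE)
    summ <- lapply(seq_along(tun$summaries), function(u) {
      s <- tun$summaries[[u]]
      list(unit = u, dsi = s$dsi, si = s$si,
           pref_speed_deg_s = s$pref_speed_deg_s,
           per_step_dsi = as.list(s$per_step_dsi),
           pattern_invariance_r2 = pattern_invariance_r2(
             tun$summaries[[u]]$curve, grat$summaries[[u]]$curve))
    })
    pooled <- pattern_invariance_r2(
      do.call(cbind, lapply(tun$summaries, `[[`, "curve")),
      do.call(cbind, lapply(grat$summaries, `[[`, "curve")))
    jsonlite::write_json(list(units = summ, pooled_r2 = pooled),
                         file.path(out_dir, "tuning_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    res$tuning <- tun; res$grating <- grat; res$pooled_r2 <- pooled
  }

  # stage 4: reverse correlation of output units
  if (!(resume && done("filters_info.csv"))) {
    nu <- if (is.null(revcorr_units_n)) config$n_cells
          else min(revcorr_units_n, config$n_cells)
    banks <- revcorr_units(params, grid, seq_len(nu), "output",
                           n_frames = config$revcorr_frames,
                           bar_width_units = config$bar_width_output,
                           history = config$history,
                           seed = config$seed + 5L)
    info <- do.call(rbind, lapply(banks, function(b)
      data.frame(unit = b$unit, rank = seq_along(b$info_bits),
                 info_bits = b$info_bits,
                 sign = vapply(b$filters, `[[`, "", "sign"))))
    utils::write.csv(info, file.path(out_dir, "filters_info.csv"),
                     row.names = FALSE)
    res$banks <- banks
  }

  # stage 5: connectivity
  if (!(resume && done("connectivity.csv", "input_pca.csv"))) {
    htun <- measure_network_tuning(params, grid, n_patterns = 50L,
                                   units = "hidden",
                                   seed = config$seed + 6L)
    pref_dir <- vapply(htun$summaries, `[[`, numeric(1), "pref_direction")
    f1f0 <- classify_hidden_units(params, grid, pref_dir,
                                  sf_cpd = config$sf_cpd)
    I <- indirect_input(params$M, params$D)
    shifts <- lapply(seq_len(config$n_hidden), function(u)
      estimate_shift(params$D[u, ], I[u, ], config$noise, grid))
    conn <- data.frame(
      unit = seq_len(config$n_hidden),
      pref_speed = vapply(htun$summaries, `[[`, numeric(1),
                          "pref_speed_deg_s"),
      f1f0 = f1f0$ratio, label = f1f0$label,
      dx_units = vapply(shifts, `[[`, numeric(1), "dx_units"),
      peak_correlation = vapply(shifts, `[[`, numeric(1),
                                "peak_correlation"),
      valid = vapply(shifts, `[[`, logical(1), "valid"))
    conn$predicted_speed <- ifelse(
      conn$valid, conn$dx_units * grid$delta_deg / grid$frame_dt_s, NA)
    utils::write.csv(conn, file.path(out_dir, "connectivity.csv"),
                     row.names = FALSE)
    pca <- input_weight_pca(params$D)
    utils::write.csv(data.frame(component = seq_along(pca$variance_fraction),
                                variance_fraction = pca$variance_fraction),
                     file.path(out_dir, "input_pca.csv"), row.names = FALSE)
    res$connectivity <- conn
  }

  jsonlite::write_json(list(scale = config$scale, seed = config$seed,
                            n_input = config$n_input,
                            n_hidden = config$n_hidden,
                            n_cells = config$n_cells),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(res)
}

#' Summarize a pipeline artifact directory
#'
#' Reads the artifacts written by [run_pipeline()] and produces one
#' machine-readable summary (returned, and written as `report.json`):
#' per-unit tuning indices, the pooled noise/grating tuning R^2, filter
#' counts by sign, and connectivity agreement statistics. Missing
#' artifacts are listed explicitly in an error.
#'
#' @param out_dir Pipeline artifact directory.
#' @return The summary list, invisibly.
#' @export
pipeline_report <- function(out_dir) {
  need <- c("targets.csv", "loss.csv", "tuning_noise.csv",
            "tuning_gratings.csv", "tuning_summary.json",
            "filters_info.csv", "connectivity.csv", "input_pca.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing))
    stop("missing pipeline artifacts: ", paste(missing, collapse = ", "))
  summ <- jsonlite::read_json(file.path(out_dir, "tuning_summary.json"),
                              simplifyVector = TRUE)
  info <- utils::read.csv(file.path(out_dir, "filters_info.csv"))
  conn <- utils::read.csv(file.path(out_dir, "connectivity.csv"))
  loss <- utils::read.csv(file.path(out_dir, "loss.csv"))
  rep <- list(
    pooled_noise_grating_r2 = summ$pooled_r2,
    unit_indices = summ$units,
    final_loss = loss$sum_squared_error[nrow(loss)],
    filters_by_sign = as.list(table(info$sign)),
    n_valid_shifts = sum(conn$valid),
    sign_agreement = with(conn[conn$valid & !is.na(conn$pref_speed), ],
                          mean(sign(predicted_speed) == sign(pref_speed))))
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

# long-format data frame of a target set (cell, speed, direction, bin,
# normalized rate)
target_set_to_df <- function(ts) {
  d <- dim(ts$rates)
  expand <- expand.grid(cell = seq_len(d[1]),
                        condition = seq_len(d[2]),
                        bin = seq_len(d[3]))
  data.frame(expand,
             speed_deg_s = ts$condition_speeds[expand$condition],
             direction = ts$directions[expand$condition],
             bin_center_ms = ts$bin_centers_ms[expand$bin],
             rate = as.vector(ts$rates))
}

df_to_target_set <- function(df) {
  d <- c(max(df$cell), max(df$condition), max(df$bin))
  arr <- array(0, d)
  arr[cbind(df$cell, df$condition, df$bin)] <- df$rate
  speeds <- sort(unique(df$speed_deg_s))
  structure(list(rates = arr, peak_rate_hz = NA_real_,
                 speeds_deg_s = speeds,
                 directions = rep(c(1, -1), each = length(speeds)),
                 condition_speeds = rep(speeds, 2L),
                 bin_centers_ms = sort(unique(df$bin_center_ms))),
            class = "target_response_set")
}

tuning_to_df <- function(tun) {
  do.call(rbind, lapply(seq_along(tun$summaries), function(u) {
    cv <- tun$summaries[[u]]$curve
    data.frame(unit = u,
               speed_deg_s = as.numeric(rownames(cv)),
               pref = cv[, "pref"], anti = cv[, "anti"],
               row.names = NULL)
  }))
}
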