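#' Parameters of the Elman recurrent motion network
#'
#' A three-layer network: `n_input` input units sampling the stimulus,
#' `n_hidden` sigmoid hidden units that are all-to-all recurrently
#' connected, and `n_output` sigmoid output units, one per modeled cell.
#' `D` holds the direct (input -> hidden) weights, `M` the lateral /
#' recurrent (hidden -> hidden) weights, `W_out` the hidden -> output
#' weights; `b_hidden` and `b_out` are the biases.
#'
#' @param D,M,W_out,b_hidden,b_out Weight matrices and bias vectors with
#'   mutually consistent shapes.
#' @return An object of class `network_params`.
#' @export
network_params <- function(D, M, W_out, b_hidden, b_out) {
  D <- as.matrix(D); M <- as.matrix(M); W_out <- as.matrix(W_out)
  stopifnot(nrow(D) == nrow(M), nrow(M) == ncol(M),
            ncol(W_out) == nrow(D),
            length(b_hidden) == nrow(D), length(b_out) == nrow(W_out),
            all(is.finite(D)), all(is.finite(M)), all(is.finite(W_out)),
            all(is.finite(b_hidden)), all(is.finite(b_out)))
  structure(list(D = D, M = M, W_out = W_out,
                 b_hidden = as.numeric(b_hidden),
                 b_out = as.numeric(b_out)),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params> %d input -> %d hidden (recurrent) -> %d output\n",
              ncol(x$D), nrow(x$D), nrow(x$W_out)))
  invisible(x)
}

#' Nguyen-Widrow initialization
#'
#' Initializes each feedforward block so that the active regions of the
#' sigmoid units evenly tile the input space: rows are drawn uniformly
#' in `[-1, 1]` and rescaled to Euclidean norm
#' `beta = 0.7 * H^(1/N)` (H units in the layer, N inputs to the layer,
#' inputs assumed mapped to `[-1, 1]`); biases are uniform in
#' `[-beta, beta]`. The direct block `D` uses `N = n_input`, the
#' recurrent block `M` uses `N = n_hidden`, and the output layer uses
#' `N = n_hidden` with weights drawn uniformly in `out_range`.
#'
#' @param n_input,n_hidden,n_output Layer sizes.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param out_range Uniform range for the output-layer weights/biases.
#' @return A [network_params()].
#' @export
init_nguyen_widrow <- function(n_input, n_hidden, n_output, seed = 1L,
                               out_range = c(-0.5, 0.5)) {
  stopifnot(n_input >= 1, n_hidden >= 1, n_output >= 1)
  nw_block <- function(h, n) {
    beta <- 0.7 * h^(1 / n)
    w <- matrix(stats::runif(h * n, -1, 1), h, n)
    w * beta / sqrt(rowSums(w^2))
  }
  withr::with_seed(seed, {
    D <- nw_block(n_hidden, n_input)
    M <- nw_block(n_hidden, n_hidden)
    b_hidden <- stats::runif(n_hidden, -0.7 * n_hidden^(1 / n_input),
                             0.7 * n_hidden^(1 / n_input))
    W_out <- matrix(stats::runif(n_output * n_hidden,
                                 out_range[1], out_range[2]),
                    n_output, n_hidden)
    b_out <- stats::runif(n_output, out_range[1], out_range[2])
    network_params(D, M, W_out, b_hidden, b_out)
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One forward step of the recurrent network
#'
#' Every unit computes the weighted sum of its inputs plus its bias and
#' passes it through the logistic sigmoid: the hidden pre-activation is
#' `x = D u + M y_prev + b_hidden`, the hidden output `y = sigmoid(x)`,
#' and the output layer reads `sigmoid(W_out y + b_out)`.
#'
#' @param params A [network_params()].
#' @param state Hidden activity vector from the previous step (the Elman
#'   context), or `NULL` for the all-zero initial context.
#' @param input_frame Numeric input vector of length `n_input`.
#' @return List with `hidden` (new state) and `output`.
#' @export
forward_step <- function(params, state, input_frame) {
  if (is.null(state)) state <- numeric(nrow(params$D))
  stopifnot(length(input_frame) == ncol(params$D),
            length(state) == nrow(params$M))
  y <- sigmoid(drop(params$D %*% input_frame) +
                 drop(params$M %*% state) + params$b_hidden)
  o <- sigmoid(drop(params$W_out %*% y) + params$b_out)
  list(hidden = y, output = o)
}

#' Run the network over a stimulus sequence
#'
#' Iterates [forward_step()] frame by frame; the hidden state carries
#' across frames. Long streams are dispatched to a compiled loop.
#'
#' @param params A [network_params()].
#' @param frames A `stimulus_sequence` or a `time x n_input` matrix.
#' @param init_state Initial hidden context (default all zeros).
#' @return List with `outputs` (`time x n_output`) and `hidden`
#'   (`time x n_hidden`).
#' @export
run_sequence <- function(params, frames, init_state = NULL) {
  if (inherits(frames, "stimulus_sequence")) frames <- frames$frames
  frames <- as.matrix(frames)
  stopifnot(nrow(frames) >= 1, ncol(frames) == ncol(params$D))
  if (is.null(init_state)) init_state <- numeric(nrow(params$D))
  res <- cpp_run_stream(params$D, params$M, params$W_out,
                        params$b_hidden, params$b_out,
                        frames, init_state)
  list(outputs = res$outputs, hidden = res$hidden)
}

#' Exact backpropagation-through-time gradients
#'
#' Gradient of the sum-squared error `sum((outputs - targets)^2)` over
#' all steps and output units, unrolled over the full sequence with no
#' truncation. Pure R reference implementation used for gradient
#' checking; the training loop uses an equivalent compiled kernel.
#'
#' @param params A [network_params()].
#' @param frames `time x n_input` stimulus matrix.
#' @param targets `time x n_output` target matrix.
#' @param init_state Initial hidden context.
#' @return List with gradient arrays `D`, `M`, `W_out`, `b_hidden`,
#'   `b_out` and the scalar `loss`.
#' @export
bptt_gradients <- function(params, frames, targets, init_state = NULL) {
  if (inherits(frames, "stimulus_sequence")) frames <- frames$frames
  frames <- as.matrix(frames); targets <- as.matrix(targets)
  TT <- nrow(frames)
  stopifnot(nrow(targets) == TT, ncol(targets) == nrow(params$W_out))
  if (is.null(init_state)) init_state <- numeric(nrow(params$D))

  H <- nrow(params$D)
  ys <- matrix(0, TT, H); os <- matrix(0, TT, nrow(params$W_out))
  y_prev <- init_state
  for (t in seq_len(TT)) {
    st <- forward_step(params, y_prev, frames[t, ])
    ys[t, ] <- st$hidden; os[t, ] <- st$output
    y_prev <- st$hidden
  }
  err <- os - targets
  loss <- sum(err^2)

  gD <- matrix(0, nrow(params$D), ncol(params$D))
  gM <- matrix(0, H, H)
  gW <- matrix(0, nrow(params$W_out), ncol(params$W_out))
  gbh <- numeric(H); gbo <- numeric(nrow(params$W_out))
  dx_next <- numeric(H)   # dL/dx_{t+1} (hidden pre-activation)
  for (t in rev(seq_len(TT))) {
    do_t <- 2 * err[t, ] * os[t, ] * (1 - os[t, ])
    gW <- gW + tcrossprod(do_t, ys[t, ])
    gbo <- gbo + do_t
    dy <- drop(crossprod(params$W_out, do_t)) +
      drop(crossprod(params$M, dx_next))
    dx <- dy * ys[t, ] * (1 - ys[t, ])
    gD <- gD + tcrossprod(dx, frames[t, ])
    y_before <- if (t == 1L) init_state else ys[t - 1L, ]
    gM <- gM + tcrossprod(dx, y_before)
    gbh <- gbh + dx
    dx_next <- dx
  }
  list(D = gD, M = gM, W_out = gW, b_hidden = gbh, b_out = gbo,
       loss = loss)
}

#' Training configuration
#'
#' @param n_epochs Number of epochs; one epoch is one sequence
#'   presentation followed by one weight update.
#' @param learning_rate SGD learning rate.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param sequence_length Frames per training sequence (one per trained
#'   time bin).
#' @param seed Integer seed for condition sampling and fresh stimuli.
#' @param chunk_size Epochs dispatched per compiled call.
#' @return An object of class `training_config`.
#' @export
training_config <- function(n_epochs = 200000L, learning_rate = 0.1,
                            momentum = 0.9, sequence_length = 5L,
                            seed = 1L, chunk_size = 1000L) {
  stopifnot(n_epochs >= 1, learning_rate >= 0, momentum >= 0, momentum < 1,
            sequence_length >= 1)
  structure(list(n_epochs = as.integer(n_epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 sequence_length = as.integer(sequence_length),
                 seed = as.integer(seed),
                 chunk_size = as.integer(chunk_size)),
            class = "training_config")
}

#' Train the recurrent network on a target response set
#'
#' Per epoch: draw one of the 14 conditions uniformly at random,
#' synthesize a fresh moving-noise input sequence for that speed and
#' direction, reset the hidden context, run the sequence, compute the
#' sum-squared error between the outputs and that condition's
#' time-binned targets, and apply one gradient update (SGD with
#' momentum) computed by exact backpropagation-through-time. Input frame
#' `k` is aligned with target bin `k`; the response latency is absorbed
#' into this mapping.
#'
#' @param params Initial [network_params()] (e.g. from
#'   [init_nguyen_widrow()]).
#' @param target_set A `target_response_set`; its cell count must equal
#'   the network's output size.
#' @param grid A [spatial_grid()] matching the input size.
#' @param cfg A [training_config()].
#' @param noise_cfg A [noise_config()].
#' @param loss_every Record the loss every `loss_every` epochs.
#' @return List with trained `params`, `loss` (recorded losses),
#'   `loss_epoch` (their epoch indices) and `condition_counts`.
#' @export
train_rmm <- function(params, target_set, grid, cfg = training_config(),
                      noise_cfg = noise_config(), loss_every = 1000L) {
  stopifnot(inherits(target_set, "target_response_set"),
            dim(target_set$rates)[1] == nrow(params$W_out),
            ncol(params$D) == grid$n_units)
  n_cond <- dim(target_set$rates)[2]
  TT <- cfg$sequence_length
  stopifnot(dim(target_set$rates)[3] == TT)
  shifts <- speed_to_shift(target_set$condition_speeds, grid) *
    ifelse(target_set$directions > 0, 1L, -1L)
  # targets per condition: TT x n_output
  tgt <- lapply(seq_len(n_cond), function(ci)
    t(target_set$rates[, ci, , drop = TRUE]))
  env <- rf_envelope(noise_cfg, grid)
  sd_raw <- 1 / noise_cfg$amplitude_sd_clip

  n_in <- grid$n_units
  losses <- numeric(0); loss_epoch <- integer(0)
  cond_counts <- integer(n_cond)
  # momentum buffers
  vel <- list(D = matrix(0, nrow(params$D), ncol(params$D)),
              M = matrix(0, nrow(params$M), ncol(params$M)),
              W_out = matrix(0, nrow(params$W_out), ncol(params$W_out)),
              b_hidden = numeric(length(params$b_hidden)),
              b_out = numeric(length(params$b_out)))
  pD <- params$D; pM <- params$M; pW <- params$W_out
  pbh <- params$b_hidden; pbo <- params$b_out

  withr::with_seed(cfg$seed, {
    done <- 0L
    while (done < cfg$n_epochs) {
      nb <- min(cfg$chunk_size, cfg$n_epochs - done)
      conds <- sample.int(n_cond, nb, replace = TRUE)
      cond_counts <- cond_counts + tabulate(conds, n_cond)
      frames <- array(0, c(TT, n_in, nb))
      for (b in seq_len(nb)) {
        sh <- shifts[conds[b]]
        len <- n_in + (TT - 1L) * abs(sh)
        strip <- lowpass_strip(stats::rnorm(len, sd = sd_raw),
                               noise_cfg, grid)
        start0 <- if (sh >= 0L) (TT - 1L) * sh else 0L
        for (t in seq_len(TT))
          frames[t, , b] <- strip[start0 - (t - 1L) * sh + seq_len(n_in)] * env
      }
      tg <- array(0, c(TT, length(pbo), nb))
      for (b in seq_len(nb)) tg[, , b] <- tgt[[conds[b]]]
      res <- cpp_train_chunk(pD, pM, pW, pbh, pbo,
                             vel$D, vel$M, vel$W_out, vel$b_hidden, vel$b_out,
                             frames, tg, cfg$learning_rate, cfg$momentum)
      pD <- res$D; pM <- res$M; pW <- res$W_out
      pbh <- res$b_hidden; pbo <- res$b_out
      vel <- list(D = res$vD, M = res$vM, W_out = res$vW,
                  b_hidden = res$vbh, b_out = res$vbo)
      if (any(!is.finite(res$losses)))
        stop("training diverged: non-finite loss at epoch ", done + which(!is.finite(res$losses))[1])
      rec <- which((done + seq_len(nb)) %% loss_every == 0L | (done + seq_len(nb)) == 1L)
      losses <- c(losses, res$losses[rec])
      loss_epoch <- c(loss_epoch, done + rec)
      done <- done + nb
    }
  })
  list(params = network_params(pD, pM, pW, pbh, pbo),
       loss = losses, loss_epoch = loss_epoch,
       condition_counts = cond_counts)
}
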