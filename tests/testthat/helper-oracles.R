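# Independent oracles used across the suite.

# Central finite-difference gradient of the sequence sum-squared error
# with respect to every parameter, via loss evaluations only.
fd_gradients <- function(params, frames, targets, eps = 1e-5) {
  loss_of <- function(p) bptt_gradients(p, frames, targets)$loss
  grad_block <- function(get, set) {
    v <- get(params)
    g <- v
    for (i in seq_along(v)) {
      v1 <- v; v1[i] <- v1[i] + eps
      v2 <- v; v2[i] <- v2[i] - eps
      g[i] <- (loss_of(set(params, v1)) - loss_of(set(params, v2))) / (2 * eps)
    }
    g
  }
  list(
    D = grad_block(function(p) p$D,
                   function(p, v) { p$D <- matrix(v, nrow(p$D)); p }),
    M = grad_block(function(p) p$M,
                   function(p, v) { p$M <- matrix(v, nrow(p$M)); p }),
    W_out = grad_block(function(p) p$W_out,
                       function(p, v) { p$W_out <- matrix(v, nrow(p$W_out)); p }),
    b_hidden = grad_block(function(p) p$b_hidden,
                          function(p, v) { p$b_hidden <- v; p }),
    b_out = grad_block(function(p) p$b_out,
                       function(p, v) { p$b_out <- v; p }))
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(a) + abs(b), floor))
}

# Independent single-step (non-temporal) backprop for a one-frame
# sequence, written directly from the chain rule without any unrolling.
single_step_backprop <- function(params, u, target) {
  x <- drop(params$D %*% u) + params$b_hidden   # zero initial context
  y <- 1 / (1 + exp(-x))
  o <- 1 / (1 + exp(-(drop(params$W_out %*% y) + params$b_out)))
  do_ <- 2 * (o - target) * o * (1 - o)
  dy <- drop(crossprod(params$W_out, do_))
  dx <- dy * y * (1 - y)
  list(D = tcrossprod(dx, u), M = matrix(0, nrow(params$M), ncol(params$M)),
       W_out = tcrossprod(do_, y), b_hidden = dx, b_out = do_)
}

random_tiny_net <- function(seed) {
  withr::with_seed(seed, {
    n_in <- sample(2:4, 1); n_h <- sample(2:4, 1); n_o <- sample(1:3, 1)
    TT <- sample(2:4, 1)
    p <- network_params(matrix(rnorm(n_h * n_in), n_h),
                        matrix(rnorm(n_h * n_h, sd = 0.5), n_h),
                        matrix(rnorm(n_o * n_h), n_o),
                        rnorm(n_h), rnorm(n_o))
    list(params = p,
         frames = matrix(rnorm(TT * n_in), TT),
         targets = matrix(runif(TT * n_o), TT))
  })
}

# Space-time Gabor filter (history x space), unit Euclidean norm.
st_gabor <- function(n_space, n_hist, sf_cyc_per_unit, phase,
                     slant_units_per_bin = 2) {
  g <- outer(seq_len(n_hist), seq_len(n_space), function(t, x)
    exp(-((x - n_space / 2)^2) / (2 * (n_space / 6)^2)) *
      cos(2 * pi * sf_cyc_per_unit * (x - slant_units_per_bin * t) + phase))
  g / sqrt(sum(g^2))
}

# Largest principal angle (degrees) between the column spans of A and B.
principal_angle_deg <- function(A, B) {
  qa <- qr.Q(qr(as.matrix(A))); qb <- qr.Q(qr(as.matrix(B)))
  s <- svd(crossprod(qa, qb))$d
  acos(min(pmin(s, 1))) * 180 / pi
}

# Two-tap delay-line detector network: detector unit i samples position
# p0_i directly and, via a relay unit (one recurrent step), position
# p0_i - k_i. Biases put the conjunction (not either input alone) above
# threshold, so the unit prefers motion of +k_i units per frame.
make_delay_line_net <- function(ks, grid, gain = 14, c_rec = 6,
                                bias_det = -5, bias_rel = -3,
                                bump_sigma = 2) {
  n <- grid$n_units
  nd <- length(ks)
  H <- 2L * nd
  D <- matrix(0, H, n); M <- matrix(0, H, H)
  bump <- function(center) {
    x <- exp(-((seq_len(n) - center)^2) / (2 * bump_sigma^2))
    x / sum(x)
  }
  p0 <- round(n / 2 + 12 * (seq_len(nd) - (nd + 1) / 2))
  for (i in seq_len(nd)) {
    D[i, ] <- gain * bump(p0[i])
    D[i + nd, ] <- gain * bump(p0[i] - ks[i])
    M[i, i + nd] <- c_rec
  }
  network_params(D, M, matrix(0, 1, H),
                 rep(c(bias_det, bias_rel), each = nd), 0)
}
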