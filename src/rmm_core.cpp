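// Compiled kernels for the Elman recurrent motion network: a forward
// pass over long stimulus streams and a sequential batch of
// BPTT/SGD-momentum training epochs. The math mirrors the R reference
// implementations (forward_step, bptt_gradients) exactly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List cpp_run_stream(const arma::mat& D, const arma::mat& M, const arma::mat& W,
                          const arma::vec& bh, const arma::vec& bo,
                          const arma::mat& frames, const arma::vec& y0) {
  const uword T = frames.n_rows;
  const uword H = D.n_rows, O = W.n_rows;
  mat hidden(T, H), outputs(T, O);
  vec y = y0;
  for (uword t = 0; t < T; ++t) {
    y = sigmoid(D * frames.row(t).t() + M * y + bh);
    hidden.row(t) = y.t();
    outputs.row(t) = sigmoid(W * y + bo).t();
  }
  return Rcpp::List::create(Rcpp::Named("outputs") = outputs,
                            Rcpp::Named("hidden") = hidden);
}

// One chunk of training epochs. frames: T x n_in x n_seq cube;
// targets: T x n_out x n_seq cube. Parameters and momentum buffers are
// taken by value and returned updated; the loss of each epoch (before
// its update) is returned as well.
// [[Rcpp::export]]
Rcpp::List cpp_train_chunk(arma::mat D, arma::mat M, arma::mat W,
                           arma::vec bh, arma::vec bo,
                           arma::mat vD, arma::mat vM, arma::mat vW,
                           arma::vec vbh, arma::vec vbo,
                           const arma::cube& frames, const arma::cube& targets,
                           const double lr, const double momentum) {
  const uword T = frames.n_rows;
  const uword H = D.n_rows, O = W.n_rows, N = D.n_cols;
  const uword n_seq = frames.n_slices;
  vec losses(n_seq);

  mat ys(H, T), os(O, T);
  mat gD(H, N), gM(H, H), gW(O, H);
  vec gbh(H), gbo(O);

  for (uword s = 0; s < n_seq; ++s) {
    const mat& u = frames.slice(s);   // T x N
    const mat& tg = targets.slice(s); // T x O
    vec y = zeros<vec>(H);
    for (uword t = 0; t < T; ++t) {
      y = sigmoid(D * u.row(t).t() + M * y + bh);
      ys.col(t) = y;
      os.col(t) = sigmoid(W * y + bo);
    }
    mat err = os - tg.t();            // O x T
    losses(s) = accu(square(err));

    gD.zeros(); gM.zeros(); gW.zeros(); gbh.zeros(); gbo.zeros();
    vec dx_next = zeros<vec>(H);
    for (uword tt = T; tt-- > 0;) {
      vec ot = os.col(tt);
      vec do_t = 2.0 * err.col(tt) % ot % (1.0 - ot);
      gW += do_t * ys.col(tt).t();
      gbo += do_t;
      vec dy = W.t() * do_t + M.t() * dx_next;
      vec dx = dy % ys.col(tt) % (1.0 - ys.col(tt));
      gD += dx * u.row(tt);
      if (tt > 0) gM += dx * ys.col(tt - 1).t();
      gbh += dx;
      dx_next = dx;
    }
    // SGD with momentum
    vD = momentum * vD - lr * gD;  D += vD;
    vM = momentum * vM - lr * gM;  M += vM;
    vW = momentum * vW - lr * gW;  W += vW;
    vbh = momentum * vbh - lr * gbh;  bh += vbh;
    vbo = momentum * vbo - lr * gbo;  bo += vbo;
  }
  return Rcpp::List::create(
      Rcpp::Named("D") = D, Rcpp::Named("M") = M, Rcpp::Named("W_out") = W,
      Rcpp::Named("b_hidden") = bh, Rcpp::Named("b_out") = bo,
      Rcpp::Named("vD") = vD, Rcpp::Named("vM") = vM, Rcpp::Named("vW") = vW,
      Rcpp::Named("vbh") = vbh, Rcpp::Named("vbo") = vbo,
      Rcpp::Named("losses") = losses);
}
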