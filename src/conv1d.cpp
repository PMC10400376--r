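// Compute kernels for the 1-D sequence network: grouped 'same'-padding
// convolutions via shift-and-GEMM on batch-padded buffers, fused
// batch-norm + SiLU passes, and squeeze/broadcast helpers. Activations are
// (channels, length, batch) cubes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Copy a (C, L, B) cube into a (C, (L + 2*pad) * B) zero-padded matrix;
// sample b occupies columns [b*(L+2p)+pad, b*(L+2p)+pad+L).
static mat pad_acts(const cube& x, int pad) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int Lp = L + 2 * pad;
  mat Xp(C, (size_t)Lp * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    Xp.cols((size_t)b * Lp + pad, (size_t)b * Lp + pad + L - 1) = x.slice(b);
  return Xp;
}

// x: (Cin, L, B); W: (Cout, Cin/groups, K). Returns y: (Cout, L, B).
// Shift-and-GEMM: one full-width GEMM per (group, kernel offset), with
// uniform-shift accumulation into a padded output buffer, so no
// per-sample inner loops touch the hot path.
// [[Rcpp::export]]
arma::cube conv1d_fw(const arma::cube& x, const arma::cube& W,
                     const arma::vec& bias, int groups, bool has_bias) {
  const int Cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int Cout = W.n_rows, Cin_g = W.n_cols, K = W.n_slices;
  const int pad = (K - 1) / 2, Lp = L + 2 * pad;
  const size_t LpB = (size_t)Lp * B;
  const int Cout_g = Cout / groups;
  if (Cin_g * groups != Cin)
    Rcpp::stop("conv1d: input channels not divisible by groups");

  const mat Xp = pad_acts(x, pad);
  cube y(Cout, L, B);
  mat Ypad(Cout_g, LpB + 2 * pad);
  mat Wall(K * Cout_g, Cin_g);
  for (int g = 0; g < groups; ++g) {
    const mat Xg = Xp.rows(g * Cin_g, (g + 1) * Cin_g - 1);
    Ypad.zeros();
    for (int k = 0; k < K; ++k)
      for (int o = 0; o < Cout_g; ++o)
        for (int c = 0; c < Cin_g; ++c)
          Wall(k * Cout_g + o, c) = W(g * Cout_g + o, c, k);
    const mat Yall = Wall * Xg;  // one GEMM for all kernel taps
    for (int k = 0; k < K; ++k) {
      Ypad.cols(2 * pad - k, 2 * pad - k + LpB - 1) +=
        Yall.rows(k * Cout_g, (k + 1) * Cout_g - 1);
    }
    for (int b = 0; b < B; ++b)
      y.slice(b).rows(g * Cout_g, (g + 1) * Cout_g - 1) =
        Ypad.cols((size_t)b * Lp + 2 * pad, (size_t)b * Lp + 2 * pad + L - 1);
  }
  if (has_bias)
    for (int b = 0; b < B; ++b) y.slice(b).each_col() += bias;
  return y;
}

// Gradients of conv1d_fw. Returns list(dx, dW, db). Both incoming
// gradients and inputs are kept in the batch-padded layout so the kernel
// loop reduces to full-width GEMMs and uniform-shift adds; the zero
// padding of Dp makes the clipped column ranges exact.
// [[Rcpp::export]]
Rcpp::List conv1d_bw(const arma::cube& x, const arma::cube& W,
                     const arma::cube& dy, int groups, bool has_bias,
                     bool need_dx) {
  const int Cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int Cout = W.n_rows, Cin_g = W.n_cols, K = W.n_slices;
  const int pad = (K - 1) / 2, Lp = L + 2 * pad;
  const size_t LpB = (size_t)Lp * B;
  const int Cout_g = Cout / groups;

  const mat Xp = pad_acts(x, pad);
  const mat Dp = pad_acts(dy, pad);
  cube dW(Cout, Cin_g, K);
  cube dx(Cin, L, need_dx ? B : 0);
  mat dXpad;
  if (need_dx) dXpad.set_size(Cin_g, LpB + 2 * pad);

  for (int g = 0; g < groups; ++g) {
    const mat Xg = Xp.rows(g * Cin_g, (g + 1) * Cin_g - 1);
    const mat Dg = Dp.rows(g * Cout_g, (g + 1) * Cout_g - 1);
    if (need_dx) dXpad.zeros();
    mat WallT(K * Cin_g, Cout_g);
    for (int k = 0; k < K; ++k) {
      const int sh = k - pad;
      const size_t a = sh < 0 ? (size_t)(-sh) : 0;
      const size_t b2 = LpB - 1 - (sh > 0 ? (size_t)sh : 0);
      const mat dWk = Dg.cols(a, b2) * Xg.cols(a + sh, b2 + sh).t();
      for (int o = 0; o < Cout_g; ++o)
        for (int c = 0; c < Cin_g; ++c) {
          dW(g * Cout_g + o, c, k) = dWk(o, c);
          WallT(k * Cin_g + c, o) = W(g * Cout_g + o, c, k);
        }
    }
    if (need_dx) {
      const mat Tall = WallT * Dg;  // one GEMM for all kernel taps
      for (int k = 0; k < K; ++k)
        dXpad.cols(k, k + LpB - 1) +=
          Tall.rows(k * Cin_g, (k + 1) * Cin_g - 1);
    }
    if (need_dx)
      for (int b = 0; b < B; ++b)
        dx.slice(b).rows(g * Cin_g, (g + 1) * Cin_g - 1) =
          dXpad.cols((size_t)b * Lp + 2 * pad,
                     (size_t)b * Lp + 2 * pad + L - 1);
  }
  vec db(has_bias ? Cout : 0, fill::zeros);
  if (has_bias)
    for (int b = 0; b < B; ++b) db += sum(dy.slice(b), 1);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Fused batch-norm (+ optional SiLU) forward. Returns the activated
// output, the pre-activation (batch-norm output) and the normalized
// input, plus the batch statistics when training.
// [[Rcpp::export]]
Rcpp::List bn_act_fw(const arma::cube& x, const arma::vec& gamma,
                     const arma::vec& beta, const arma::vec& run_mean,
                     const arma::vec& run_var, double eps, bool training,
                     bool act) {
  const int C = x.n_rows;
  const size_t n = (size_t)x.n_cols * x.n_slices;
  vec mu(C), v(C);
  if (training) {
    mu.zeros(); v.zeros();
    for (size_t s = 0; s < x.n_slices; ++s) {
      mu += sum(x.slice(s), 1);
      v += sum(square(x.slice(s)), 1);
    }
    mu /= (double)n;
    v = v / (double)n - square(mu);
    v.transform([](double a) { return a < 0 ? 0 : a; });
  } else {
    mu = run_mean; v = run_var;
  }
  const vec inv_sd = 1.0 / sqrt(v + eps);
  cube xhat(x.n_rows, x.n_cols, x.n_slices);
  cube pre(x.n_rows, x.n_cols, x.n_slices);
  cube y(x.n_rows, x.n_cols, x.n_slices);
  const double* px = x.memptr();
  double* ph = xhat.memptr();
  double* pp = pre.memptr();
  double* py = y.memptr();
  const size_t total = x.n_elem;
  for (size_t i = 0; i < total; ++i) {
    const int c = i % C;
    const double h = (px[i] - mu[c]) * inv_sd[c];
    ph[i] = h;
    const double p = gamma[c] * h + beta[c];
    pp[i] = p;
    py[i] = act ? p / (1.0 + std::exp(-p)) : p;
  }
  return Rcpp::List::create(
    Rcpp::Named("y") = y, Rcpp::Named("pre") = pre,
    Rcpp::Named("xhat") = xhat, Rcpp::Named("mu") = mu,
    Rcpp::Named("var") = v, Rcpp::Named("inv_sd") = inv_sd);
}

// Fused backward of (optional SiLU) + batch-norm.
// [[Rcpp::export]]
Rcpp::List bn_act_bw(const arma::cube& dy, const arma::cube& pre,
                     const arma::cube& xhat, const arma::vec& gamma,
                     const arma::vec& inv_sd, bool training, bool act) {
  const int C = dy.n_rows;
  const size_t total = dy.n_elem;
  const double n = (double)dy.n_cols * dy.n_slices;
  const double* pd = dy.memptr();
  const double* pp = pre.memptr();
  const double* ph = xhat.memptr();
  // first pass: dpre (stored in dx buffer), accumulate sums
  cube dx(dy.n_rows, dy.n_cols, dy.n_slices);
  double* px = dx.memptr();
  vec dgamma(C, fill::zeros), dbeta(C, fill::zeros);
  vec s1(C, fill::zeros), s2(C, fill::zeros);  // sums of dxhat, dxhat*xhat
  for (size_t i = 0; i < total; ++i) {
    const int c = i % C;
    double d = pd[i];
    if (act) {
      const double s = 1.0 / (1.0 + std::exp(-pp[i]));
      d *= s * (1.0 + pp[i] * (1.0 - s));
    }
    dgamma[c] += d * ph[i];
    dbeta[c] += d;
    const double dh = d * gamma[c];
    px[i] = dh;
    s1[c] += dh;
    s2[c] += dh * ph[i];
  }
  s1 /= n; s2 /= n;
  for (size_t i = 0; i < total; ++i) {
    const int c = i % C;
    px[i] = training ? inv_sd[c] * (px[i] - s1[c] - ph[i] * s2[c])
                     : inv_sd[c] * px[i];
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// Mean over the length axis: (C, L, B) -> (C, B).
// [[Rcpp::export]]
arma::mat seq_mean_len(const arma::cube& x) {
  mat out(x.n_rows, x.n_slices);
  for (size_t b = 0; b < x.n_slices; ++b) out.col(b) = mean(x.slice(b), 1);
  return out;
}

// Multiply each (C, L) slice by a per-(channel, sample) gate g: (C, B).
// [[Rcpp::export]]
arma::cube scale_by_gate(const arma::cube& x, const arma::mat& g) {
  cube y(x.n_rows, x.n_cols, x.n_slices);
  for (size_t b = 0; b < x.n_slices; ++b)
    y.slice(b) = x.slice(b).each_col() % g.col(b);
  return y;
}

// sum over length of x .* y per (channel, sample): used for gate grads.
// [[Rcpp::export]]
arma::mat gate_grad(const arma::cube& x, const arma::cube& y) {
  mat out(x.n_rows, x.n_slices);
  for (size_t b = 0; b < x.n_slices; ++b)
    out.col(b) = sum(x.slice(b) % y.slice(b), 1);
  return out;
}

// y = x scaled by gate g plus a broadcast per-(channel,sample) addend a/L.
// [[Rcpp::export]]
arma::cube gate_dx(const arma::cube& dy, const arma::mat& g,
                   const arma::mat& ds_over_L) {
  cube y(dy.n_rows, dy.n_cols, dy.n_slices);
  for (size_t b = 0; b < dy.n_slices; ++b) {
    y.slice(b) = dy.slice(b).each_col() % g.col(b);
    y.slice(b).each_col() += ds_over_L.col(b);
  }
  return y;
}

// SiLU forward / gradient multiplier over a full cube.
// [[Rcpp::export]]
arma::cube silu_fw_cpp(const arma::cube& x) {
  cube y(x.n_rows, x.n_cols, x.n_slices);
  const double* px = x.memptr();
  double* py = y.memptr();
  for (size_t i = 0; i < x.n_elem; ++i)
    py[i] = px[i] / (1.0 + std::exp(-px[i]));
  return y;
}

// [[Rcpp::export]]
arma::cube silu_bw_cpp(const arma::cube& dy, const arma::cube& x) {
  cube g(x.n_rows, x.n_cols, x.n_slices);
  const double* px = x.memptr();
  const double* pd = dy.memptr();
  double* pg = g.memptr();
  for (size_t i = 0; i < x.n_elem; ++i) {
    const double s = 1.0 / (1.0 + std::exp(-px[i]));
    pg[i] = pd[i] * s * (1.0 + px[i] * (1.0 - s));
  }
  return g;
}
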