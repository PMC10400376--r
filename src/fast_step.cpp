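// Single-call training/inference step for the standard network topology
// (stem -> N blocks with expansion conv, grouped spatial conv, standard
// SE, projection conv, channel concatenation, resize conv -> pointwise
// head). The whole forward + backward runs in single precision inside one
// C++ call, which keeps all activations out of R and feeds BLAS sgemm;
// the R layer-by-layer implementation is the double-precision reference
// this path is tested against. Covers the KL soft-classification head,
// the direct-regression (MSE) head and the per-position cross-entropy
// generator head.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvP {
  fcube W;       // (Cout, Cin/groups, K)
  int groups;
  fvec bias;     // empty if none
};

struct BnP {
  fvec gamma, beta, run_mean, run_var;
  // caches
  fvec mu, var, inv_sd;
};

struct SeP {
  fmat W1, W2;
  fvec b1, b2;
};

fcube as_fcube(SEXP s) {
  Rcpp::NumericVector v(s);
  Rcpp::IntegerVector d = v.attr("dim");
  fcube out(d[0], d[1], d.size() > 2 ? d[2] : 1);
  const double* p = v.begin();
  float* q = out.memptr();
  for (R_xlen_t i = 0; i < v.size(); ++i) q[i] = (float)p[i];
  return out;
}

fmat as_fmat(SEXP s) {
  Rcpp::NumericMatrix v(s);
  fmat out(v.nrow(), v.ncol());
  const double* p = v.begin();
  float* q = out.memptr();
  for (R_xlen_t i = 0; i < (R_xlen_t)v.nrow() * v.ncol(); ++i)
    q[i] = (float)p[i];
  return out;
}

fvec as_fvec(SEXP s) {
  Rcpp::NumericVector v(s);
  fvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

template <class A> SEXP to_r(const A& x, Rcpp::IntegerVector dim) {
  Rcpp::NumericVector out(x.n_elem);
  const float* p = x.memptr();
  for (size_t i = 0; i < x.n_elem; ++i) out[i] = (double)p[i];
  out.attr("dim") = dim;
  return out;
}

SEXP vec_to_r(const fvec& x) {
  Rcpp::NumericVector out(x.n_elem);
  for (size_t i = 0; i < x.n_elem; ++i) out[i] = (double)x[i];
  return out;
}

// ---- float conv (shift-and-GEMM, 'same' padding, stride 1) ----------------

fmat pad_acts_f(const fcube& x, int pad) {
  const int L = x.n_cols, B = x.n_slices;
  const int Lp = L + 2 * pad;
  fmat Xp(x.n_rows, (size_t)Lp * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    Xp.cols((size_t)b * Lp + pad, (size_t)b * Lp + pad + L - 1) = x.slice(b);
  return Xp;
}

fcube conv_fw_f(const ConvP& cv, const fcube& x) {
  const int Cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int Cout = cv.W.n_rows, Cin_g = cv.W.n_cols, K = cv.W.n_slices;
  const int groups = cv.groups;
  const int Cout_g = Cout / groups;
  fcube y(Cout, L, B);
  if (K == 1 && groups == 1) {
    fmat Wm(Cout, Cin);
    for (int o = 0; o < Cout; ++o)
      for (int c = 0; c < Cin; ++c) Wm(o, c) = cv.W(o, c, 0);
    const fmat xm(const_cast<float*>(x.memptr()), Cin, (size_t)L * B,
                  false, true);
    fmat ym(y.memptr(), Cout, (size_t)L * B, false, true);
    ym = Wm * xm;
  } else {
    const int pad = (K - 1) / 2, Lp = L + 2 * pad;
    const size_t LpB = (size_t)Lp * B;
    const fmat Xp = pad_acts_f(x, pad);
    fmat Ypad(Cout_g, LpB + 2 * pad);
    fmat Wall(K * Cout_g, Cin_g);
    for (int g = 0; g < groups; ++g) {
      const fmat Xg = Xp.rows(g * Cin_g, (g + 1) * Cin_g - 1);
      Ypad.zeros();
      for (int k = 0; k < K; ++k)
        for (int o = 0; o < Cout_g; ++o)
          for (int c = 0; c < Cin_g; ++c)
            Wall(k * Cout_g + o, c) = cv.W(g * Cout_g + o, c, k);
      const fmat Yall = Wall * Xg;
      for (int k = 0; k < K; ++k)
        Ypad.cols(2 * pad - k, 2 * pad - k + LpB - 1) +=
          Yall.rows(k * Cout_g, (k + 1) * Cout_g - 1);
      for (int b = 0; b < B; ++b)
        y.slice(b).rows(g * Cout_g, (g + 1) * Cout_g - 1) =
          Ypad.cols((size_t)b * Lp + 2 * pad,
                    (size_t)b * Lp + 2 * pad + L - 1);
    }
  }
  if (!cv.bias.empty())
    for (int b = 0; b < B; ++b) y.slice(b).each_col() += cv.bias;
  return y;
}

// dy -> (dx if need_dx), dW, db accumulated into grads.
fcube conv_bw_f(const ConvP& cv, const fcube& x, const fcube& dy,
                fcube& dW, fvec& db, bool need_dx) {
  const int Cin = x.n_rows, L = x.n_cols, B = x.n_slices;
  const int Cout = cv.W.n_rows, Cin_g = cv.W.n_cols, K = cv.W.n_slices;
  const int groups = cv.groups;
  const int Cout_g = Cout / groups;
  dW.set_size(Cout, Cin_g, K);
  fcube dx(Cin, L, need_dx ? B : 0);
  if (K == 1 && groups == 1) {
    const fmat xm(const_cast<float*>(x.memptr()), Cin, (size_t)L * B,
                  false, true);
    const fmat dym(const_cast<float*>(dy.memptr()), Cout, (size_t)L * B,
                   false, true);
    fmat dWm = dym * xm.t();
    for (int o = 0; o < Cout; ++o)
      for (int c = 0; c < Cin; ++c) dW(o, c, 0) = dWm(o, c);
    if (need_dx) {
      fmat Wm(Cout, Cin);
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c) Wm(o, c) = cv.W(o, c, 0);
      fmat dxm(dx.memptr(), Cin, (size_t)L * B, false, true);
      dxm = Wm.t() * dym;
    }
  } else {
    const int pad = (K - 1) / 2, Lp = L + 2 * pad;
    const size_t LpB = (size_t)Lp * B;
    const fmat Xp = pad_acts_f(x, pad);
    const fmat Dp = pad_acts_f(dy, pad);
    fmat dXpad;
    if (need_dx) dXpad.set_size(Cin_g, LpB + 2 * pad);
    for (int g = 0; g < groups; ++g) {
      const fmat Xg = Xp.rows(g * Cin_g, (g + 1) * Cin_g - 1);
      const fmat Dg = Dp.rows(g * Cout_g, (g + 1) * Cout_g - 1);
      if (need_dx) dXpad.zeros();
      fmat WallT(K * Cin_g, Cout_g);
      for (int k = 0; k < K; ++k) {
        const int sh = k - pad;
        const size_t a = sh < 0 ? (size_t)(-sh) : 0;
        const size_t b2 = LpB - 1 - (sh > 0 ? (size_t)sh : 0);
        const fmat dWk = Dg.cols(a, b2) * Xg.cols(a + sh, b2 + sh).t();
        for (int o = 0; o < Cout_g; ++o)
          for (int c = 0; c < Cin_g; ++c) {
            dW(g * Cout_g + o, c, k) = dWk(o, c);
            WallT(k * Cin_g + c, o) = cv.W(g * Cout_g + o, c, k);
          }
      }
      if (need_dx) {
        const fmat Tall = WallT * Dg;
        for (int k = 0; k < K; ++k)
          dXpad.cols(k, k + LpB - 1) +=
            Tall.rows(k * Cin_g, (k + 1) * Cin_g - 1);
        for (int b = 0; b < B; ++b)
          dx.slice(b).rows(g * Cin_g, (g + 1) * Cin_g - 1) =
            dXpad.cols((size_t)b * Lp + 2 * pad,
                       (size_t)b * Lp + 2 * pad + L - 1);
      }
    }
  }
  if (!cv.bias.empty()) {
    db.zeros(Cout);
    for (int b = 0; b < B; ++b) db += sum(dy.slice(b), 1);
  }
  return dx;
}

// ---- fused bn (+ optional SiLU) -------------------------------------------

// Forward; fills bn caches (mu, var, inv_sd) and writes xhat and pre.
fcube bn_act_fw_f(BnP& bn, const fcube& x, bool training, bool act,
                  fcube& xhat, fcube& pre, float eps = 1e-5f) {
  const int C = x.n_rows;
  const size_t n = (size_t)x.n_cols * x.n_slices;
  if (training) {
    bn.mu.zeros(C); bn.var.zeros(C);
    for (size_t s = 0; s < x.n_slices; ++s) {
      bn.mu += sum(x.slice(s), 1);
      bn.var += sum(square(x.slice(s)), 1);
    }
    bn.mu /= (float)n;
    bn.var = bn.var / (float)n - square(bn.mu);
    bn.var.transform([](float a) { return a < 0 ? 0.0f : a; });
  } else {
    bn.mu = bn.run_mean; bn.var = bn.run_var;
  }
  bn.inv_sd = 1.0f / sqrt(bn.var + eps);
  xhat.set_size(x.n_rows, x.n_cols, x.n_slices);
  pre.set_size(x.n_rows, x.n_cols, x.n_slices);
  fcube y(x.n_rows, x.n_cols, x.n_slices);
  const float* px = x.memptr();
  float* ph = xhat.memptr();
  float* pp = pre.memptr();
  float* py = y.memptr();
  const size_t cols = x.n_elem / C;
  size_t i = 0;
  for (size_t j = 0; j < cols; ++j)
    for (int c = 0; c < C; ++c, ++i) {
      const float h = (px[i] - bn.mu[c]) * bn.inv_sd[c];
      ph[i] = h;
      const float p = bn.gamma[c] * h + bn.beta[c];
      pp[i] = p;
      py[i] = act ? p / (1.0f + std::exp(-p)) : p;
    }
  return y;
}

fcube bn_act_bw_f(const BnP& bn, const fcube& dy, const fcube& pre,
                  const fcube& xhat, bool act, fvec& dgamma, fvec& dbeta) {
  const int C = dy.n_rows;
  const float n = (float)dy.n_cols * dy.n_slices;
  fcube dx(dy.n_rows, dy.n_cols, dy.n_slices);
  const float* pd = dy.memptr();
  const float* pp = pre.memptr();
  const float* ph = xhat.memptr();
  float* px = dx.memptr();
  dgamma.zeros(C); dbeta.zeros(C);
  fvec s1(C, fill::zeros), s2(C, fill::zeros);
  const size_t cols = dy.n_elem / C;
  size_t i = 0;
  for (size_t j = 0; j < cols; ++j)
    for (int c = 0; c < C; ++c, ++i) {
      float d = pd[i];
      if (act) {
        const float s = 1.0f / (1.0f + std::exp(-pp[i]));
        d *= s * (1.0f + pp[i] * (1.0f - s));
      }
      dgamma[c] += d * ph[i];
      dbeta[c] += d;
      const float dh = d * bn.gamma[c];
      px[i] = dh;
      s1[c] += dh;
      s2[c] += dh * ph[i];
    }
  s1 /= n; s2 /= n;
  i = 0;
  for (size_t j = 0; j < cols; ++j)
    for (int c = 0; c < C; ++c, ++i)
      px[i] = bn.inv_sd[c] * (px[i] - s1[c] - ph[i] * s2[c]);
  return dx;
}

// ---- standard SE -----------------------------------------------------------

struct SeCache {
  fmat s, u1, a1, g;
  fcube x;
};

fcube se_fw_f(const SeP& se, const fcube& x, SeCache& cc) {
  const int L = x.n_cols, B = x.n_slices;
  cc.s.set_size(x.n_rows, B);
  for (int b = 0; b < B; ++b) cc.s.col(b) = mean(x.slice(b), 1);
  cc.u1 = se.W1 * cc.s;
  cc.u1.each_col() += se.b1;
  cc.a1 = cc.u1 / (1.0f + exp(-cc.u1));
  fmat u2 = se.W2 * cc.a1;
  u2.each_col() += se.b2;
  cc.g = 1.0f / (1.0f + exp(-u2));
  cc.x = x;
  fcube y(x.n_rows, L, B);
  for (int b = 0; b < B; ++b)
    y.slice(b) = x.slice(b).each_col() % cc.g.col(b);
  return y;
}

fcube se_bw_f(const SeP& se, const SeCache& cc, const fcube& dy,
              fmat& dW1, fvec& db1, fmat& dW2, fvec& db2) {
  const int B = dy.n_slices;
  const float L = (float)dy.n_cols;
  fmat dg(dy.n_rows, B);
  for (int b = 0; b < B; ++b)
    dg.col(b) = sum(dy.slice(b) % cc.x.slice(b), 1);
  fmat du2 = dg % cc.g % (1.0f - cc.g);
  dW2 = du2 * cc.a1.t();
  db2 = sum(du2, 1);
  fmat da1 = se.W2.t() * du2;
  fmat sig = 1.0f / (1.0f + exp(-cc.u1));
  fmat du1 = da1 % (sig % (1.0f + cc.u1 % (1.0f - sig)));
  dW1 = du1 * cc.s.t();
  db1 = sum(du1, 1);
  fmat ds = (se.W1.t() * du1) / L;
  fcube dx(dy.n_rows, dy.n_cols, B);
  for (int b = 0; b < B; ++b) {
    dx.slice(b) = dy.slice(b).each_col() % cc.g.col(b);
    dx.slice(b).each_col() += ds.col(b);
  }
  return dx;
}

// ---- whole-model step ------------------------------------------------------

struct StageP {
  ConvP conv;
  BnP bn;
  bool act;
};

struct StageCache {
  fcube x, xhat, pre;
};

struct BlockP {
  StageP expand, spatial, project, resize;
  SeP se;
  int c_in, c_out;
};

StageP read_stage(const Rcpp::List& params, int& i, int groups, bool bias) {
  StageP st;
  st.conv.W = as_fcube(params[i++]);
  st.conv.groups = groups;
  if (bias) st.conv.bias = as_fvec(params[i++]);
  st.bn.gamma = as_fvec(params[i++]);
  st.bn.beta = as_fvec(params[i++]);
  st.bn.run_mean = as_fvec(params[i++]);
  st.bn.run_var = as_fvec(params[i++]);
  st.act = true;
  return st;
}

fcube stage_fw(StageP& st, const fcube& x, bool training, StageCache& cc) {
  cc.x = x;
  fcube y = conv_fw_f(st.conv, x);
  return bn_act_fw_f(st.bn, y, training, st.act, cc.xhat, cc.pre);
}


}  // namespace

// One fused training/inference step. `params` is a flat list in the fixed
// order produced by the R wrapper (stem stage, then per block: expand,
// spatial, se, project, resize; then head W, head b); each bn stage
// contributes gamma, beta, running mean, running var. Returns the loss,
// the output probabilities, gradients (same order as params; running
// stats get NULL) and the per-bn batch statistics for the running-stat
// update.  head_type: 0 pooled bins, 1 per-position. loss_type: 0 KL,
// 1 MSE on soft-argmax, 2 per-position cross-entropy, -1 forward only.
// [[Rcpp::export]]
Rcpp::List fast_step(Rcpp::List params, Rcpp::IntegerVector groups_per_block,
                     int n_blocks, SEXP x_r, SEXP target_r, int head_type,
                     int loss_type, bool training, bool final_act,
                     bool want_grads) {
  fcube x = as_fcube(x_r);
  const int L = x.n_cols, B = x.n_slices;
  int pi = 0;
  StageP stem = read_stage(params, pi, 1, false);
  std::vector<BlockP> blocks((size_t)n_blocks);
  for (int i = 0; i < n_blocks; ++i) {
    BlockP& bl = blocks[i];
    bl.expand = read_stage(params, pi, 1, false);
    bl.spatial = read_stage(params, pi, groups_per_block[i], false);
    bl.se.W1 = as_fmat(params[pi++]);
    bl.se.b1 = as_fvec(params[pi++]);
    bl.se.W2 = as_fmat(params[pi++]);
    bl.se.b2 = as_fvec(params[pi++]);
    bl.project = read_stage(params, pi, 1, false);
    bl.resize = read_stage(params, pi, 1, false);
    bl.c_in = bl.expand.conv.W.n_cols;
    bl.c_out = bl.project.conv.W.n_rows;
  }
  ConvP head;
  head.W = as_fcube(params[pi++]);
  head.groups = 1;
  head.bias = as_fvec(params[pi++]);
  const int n_out = head.W.n_rows;

  // ---- forward ----
  StageCache stem_cc;
  fcube h = stage_fw(stem, x, training, stem_cc);
  std::vector<StageCache> e_cc(n_blocks), s_cc(n_blocks), p_cc(n_blocks),
      r_cc(n_blocks);
  std::vector<SeCache> se_cc(n_blocks);
  for (int i = 0; i < n_blocks; ++i) {
    BlockP& bl = blocks[i];
    fcube e = stage_fw(bl.expand, h, training, e_cc[i]);
    fcube s = stage_fw(bl.spatial, e, training, s_cc[i]);
    fcube z = se_fw_f(bl.se, s, se_cc[i]);
    fcube p = stage_fw(bl.project, z, training, p_cc[i]);
    fcube cc(bl.c_in + bl.c_out, L, B);
    cc.rows(0, bl.c_in - 1) = h;
    cc.rows(bl.c_in, bl.c_in + bl.c_out - 1) = p;
    h = stage_fw(bl.resize, cc, training, r_cc[i]);
  }
  fcube hd = conv_fw_f(head, h);
  fcube head_act;
  fmat probs_m;   // pooled head: (n_out, B)
  fcube probs_c;  // per-position head
  double loss = NA_REAL;
  fmat dz_m;
  fcube dz_c;
  if (head_type == 0) {
    head_act = hd;
    if (final_act) {
      float* p = head_act.memptr();
      for (size_t i = 0; i < head_act.n_elem; ++i)
        p[i] = p[i] / (1.0f + std::exp(-p[i]));
    }
    fmat z(n_out, B);
    for (int b = 0; b < B; ++b) z.col(b) = mean(head_act.slice(b), 1);
    z.each_row() -= max(z, 0);
    probs_m = exp(z);
    probs_m.each_row() /= sum(probs_m, 0);
    if (loss_type == 0) {
      const fmat target = as_fmat(target_r);
      double acc = 0;
      for (size_t i = 0; i < target.n_elem; ++i) {
        const float t = target[i];
        if (t > 0)
          acc += (double)t *
                 (std::log((double)t) -
                  std::log(std::max((double)probs_m[i], 1e-12)));
      }
      loss = acc / B;
      dz_m = (probs_m - target) / (float)B;
    } else if (loss_type == 1) {
      const fvec target = as_fvec(target_r);  // expressions, length B
      fvec bins = linspace<fvec>(0, n_out - 1, n_out);
      fvec pred = probs_m.t() * bins;
      fvec err = pred - target;
      loss = (double)mean(square(err));
      dz_m.set_size(n_out, B);
      for (int b = 0; b < B; ++b)
        dz_m.col(b) = probs_m.col(b) % (bins - pred[b]) *
                      (2.0f * err[b] / (float)B);
    }
  } else {
    // per-position softmax over the 4 nucleotide channels
    probs_c.set_size(n_out, L, B);
    const size_t cols = hd.n_elem / n_out;
    const float* ph = hd.memptr();
    float* pq = probs_c.memptr();
    for (size_t j = 0; j < cols; ++j) {
      const size_t off = j * n_out;
      float mx = ph[off];
      for (int c = 1; c < n_out; ++c) mx = std::max(mx, ph[off + c]);
      float sum = 0;
      for (int c = 0; c < n_out; ++c) {
        const float e = std::exp(ph[off + c] - mx);
        pq[off + c] = e;
        sum += e;
      }
      for (int c = 0; c < n_out; ++c) pq[off + c] /= sum;
    }
    if (loss_type == 2) {
      const fcube target = as_fcube(target_r);
      double acc = 0;
      for (size_t i = 0; i < target.n_elem; ++i)
        if (target[i] > 0)
          acc -= std::log(std::max((double)probs_c[i], 1e-12));
      loss = acc / cols;
      dz_c = (probs_c - target) / (float)cols;
    }
  }

  Rcpp::List out;
  if (head_type == 0)
    out["probs"] = to_r(probs_m, Rcpp::IntegerVector::create(n_out, B));
  else
    out["probs"] = to_r(probs_c, Rcpp::IntegerVector::create(n_out, L, B));
  out["loss"] = loss;
  if (loss_type < 0 || !want_grads) return out;

  // ---- backward ----
  // gradients are collected stage by stage (reverse order), then the R
  // wrapper reorders them to match the parameter list.
  Rcpp::List grads(params.size());
  int gi_head_W, gi_head_b;
  fcube dhd;
  if (head_type == 0) {
    fcube dact(n_out, L, B);
    for (int b = 0; b < B; ++b) {
      fmat d = repmat(dz_m.col(b) / (float)L, 1, L);
      dact.slice(b) = d;
    }
    if (final_act) {
      const float* pp = hd.memptr();
      float* pd = dact.memptr();
      for (size_t i = 0; i < dact.n_elem; ++i) {
        const float s = 1.0f / (1.0f + std::exp(-pp[i]));
        pd[i] *= s * (1.0f + pp[i] * (1.0f - s));
      }
    }
    dhd = dact;
  } else {
    dhd = dz_c;
  }
  // head conv backward (input is h, the final trunk activation)
  fcube dW_head;
  fvec db_head;
  fcube dh = conv_bw_f(head, h, dhd, dW_head, db_head, true);
  // walk blocks backward; store grads positionally from the end
  int gi = params.size();
  grads[--gi] = vec_to_r(db_head);
  grads[--gi] = to_r(dW_head,
                     Rcpp::IntegerVector::create(dW_head.n_rows,
                                                 dW_head.n_cols,
                                                 dW_head.n_slices));
  Rcpp::List bn_mu(1 + 4 * n_blocks), bn_var(1 + 4 * n_blocks);
  auto put_stage_grads = [&](const StageP& st, const StageCache& cc,
                             const fcube& dy, bool need_dx) {
    // returns dx; fills grads at [gi-4..gi-1] order W, gamma, beta
    fvec dgamma, dbeta, db;
    fcube dconv = bn_act_bw_f(st.bn, dy, cc.pre, cc.xhat, st.act, dgamma,
                              dbeta);
    fcube dW;
    fcube dx = conv_bw_f(st.conv, cc.x, dconv, dW, db, need_dx);
    grads[--gi] = Rcpp::NumericVector();  // run_var placeholder
    grads[--gi] = Rcpp::NumericVector();  // run_mean placeholder
    grads[--gi] = vec_to_r(dbeta);
    grads[--gi] = vec_to_r(dgamma);
    grads[--gi] = to_r(dW, Rcpp::IntegerVector::create(dW.n_rows, dW.n_cols,
                                                       dW.n_slices));
    return dx;
  };
  int bn_i = 1 + 4 * n_blocks;
  auto put_bn_stats = [&](const StageP& st) {
    --bn_i;
    bn_mu[bn_i] = vec_to_r(st.bn.mu);
    bn_var[bn_i] = vec_to_r(st.bn.var);
  };
  for (int i = n_blocks - 1; i >= 0; --i) {
    BlockP& bl = blocks[i];
    put_bn_stats(bl.resize);
    fcube dcc = put_stage_grads(bl.resize, r_cc[i], dh, true);
    fcube dinp = dcc.rows(0, bl.c_in - 1);
    fcube dp = dcc.rows(bl.c_in, bl.c_in + bl.c_out - 1);
    put_bn_stats(bl.project);
    fcube dse = put_stage_grads(bl.project, p_cc[i], dp, true);
    fmat dW1, dW2;
    fvec db1, db2;
    fcube dsp = se_bw_f(bl.se, se_cc[i], dse, dW1, db1, dW2, db2);
    grads[--gi] = vec_to_r(db2);
    grads[--gi] = to_r(dW2, Rcpp::IntegerVector::create(dW2.n_rows,
                                                        dW2.n_cols));
    grads[--gi] = vec_to_r(db1);
    grads[--gi] = to_r(dW1, Rcpp::IntegerVector::create(dW1.n_rows,
                                                        dW1.n_cols));
    put_bn_stats(bl.spatial);
    fcube de = put_stage_grads(bl.spatial, s_cc[i], dsp, true);
    put_bn_stats(bl.expand);
    fcube dh2 = put_stage_grads(bl.expand, e_cc[i], de, true);
    dh = dinp + dh2;
  }
  put_bn_stats(stem);
  put_stage_grads(stem, stem_cc, dh, false);
  out["grads"] = grads;
  out["bn_mu"] = bn_mu;
  out["bn_var"] = bn_var;
  return out;
}
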