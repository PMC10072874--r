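// Batched forward / backward passes for the network families.
// Per-example state loops (the modulation state is example-specific, n x d),
// gradients accumulated across the batch. Pure deterministic: all randomness
// (inits, task draws) lives on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// modulation rules
static const int RULE_ASSOC = 0;
static const int RULE_PRE   = 1;
static const int RULE_POST  = 2;
static const int RULE_ADD   = 3;  // additive hidden map, associative update

static inline vec act_fun(const vec& a, int act) {
  if (act == 0) return tanh(a);
  return clamp(a, 0.0, datum::inf);  // relu
}

// derivative expressed through the activation value h
static inline vec act_deriv(const vec& h, int act) {
  if (act == 0) return 1.0 - square(h);
  return conv_to<vec>::from(h > 0);
}

static inline vec softmax_vec(const vec& y) {
  vec z = exp(y - y.max());
  return z / accu(z);
}

// One modulation-state update, shared by forward and backward recomputation.
static inline void m_update(mat& M, const vec& h, const vec& x,
                            double eta, double lam, int rule, double mb,
                            int n, int d) {
  switch (rule) {
  case RULE_ASSOC:
  case RULE_ADD:
    M = lam * M + eta * (h * x.t());
    break;
  case RULE_PRE:
    M = lam * M + (eta / n) * repmat(x.t(), n, 1);
    break;
  case RULE_POST:
    M = lam * M + (eta / d) * repmat(h, 1, d);
    break;
  }
  if (mb > 0) M = clamp(M, -mb, mb);
}

// Forward pass for the MPN family (also covers the plain feedforward network
// via eta = 0). X: cube d x T x B. m_times: 0-based snapshot times in 0..T
// (state index: M_t). Returns final outputs and the requested records.
// Hot loops are fused over raw column pointers: the modulation state M is
// n x d per example and every temporary would be that size too.
// [[Rcpp::export]]
List mpn_forward_cpp(const arma::mat& W, const arma::vec& b,
                     const arma::mat& Wro, const arma::vec& bro,
                     double eta, double lam,
                     const arma::cube& X, int rule, double mb, int act,
                     bool ret_H, bool ret_Yall,
                     const arma::ivec& m_times,
                     bool ret_go, const arma::vec& x_go) {
  const int n = W.n_rows, d = W.n_cols, N = Wro.n_rows;
  const int T = X.n_cols, B = X.n_slices;
  const int nm = m_times.n_elem;

  mat Y(N, B);
  cube H, Yall, Mrec, Hgo;
  if (ret_H)    H.set_size(n, T, B);
  if (ret_Yall) Yall.set_size(N, T, B);
  if (nm > 0)   Mrec.set_size(n * (size_t)d, nm, B);
  if (ret_go)   Hgo.set_size(n, T + 1, B);

  const vec wgo = ret_go ? vec(W * x_go) : vec();
  mat M(n, d);
  vec a(n), h(n);

  for (int bb = 0; bb < B; ++bb) {
    M.zeros();
    const mat Xb = X.slice(bb);
    const mat WX = W * Xb;  // n x T, unmodulated drive
    for (int t = 0; t < T; ++t) {
      if (t == 0) {
        for (int k = 0; k < nm; ++k)
          if (m_times[k] == 0) Mrec.slice(bb).col(k) = vectorise(M);
        if (ret_go)
          Hgo.slice(bb).col(0) = act_fun((M % W) * x_go + wgo + b, act);
      }
      const double* x = Xb.colptr(t);
      a = WX.col(t) + b;
      double* ap = a.memptr();
      if (rule == RULE_ADD) {
        for (int I = 0; I < d; ++I) {
          const double xi = x[I];
          const double* mp = M.colptr(I);
          for (int i = 0; i < n; ++i) ap[i] += mp[i] * xi;
        }
      } else {
        for (int I = 0; I < d; ++I) {
          const double xi = x[I];
          const double* mp = M.colptr(I);
          const double* wp = W.colptr(I);
          for (int i = 0; i < n; ++i) ap[i] += mp[i] * wp[i] * xi;
        }
      }
      h = act_fun(a, act);
      if (ret_H) H.slice(bb).col(t) = h;
      // modulation update, in place
      const double* hp = h.memptr();
      if (rule == RULE_PRE) {
        for (int I = 0; I < d; ++I) {
          const double inc = (eta / n) * x[I];
          double* mp = M.colptr(I);
          for (int i = 0; i < n; ++i) mp[i] = lam * mp[i] + inc;
        }
      } else if (rule == RULE_POST) {
        for (int I = 0; I < d; ++I) {
          double* mp = M.colptr(I);
          for (int i = 0; i < n; ++i) mp[i] = lam * mp[i] + (eta / d) * hp[i];
        }
      } else {
        for (int I = 0; I < d; ++I) {
          const double exi = eta * x[I];
          double* mp = M.colptr(I);
          for (int i = 0; i < n; ++i) mp[i] = lam * mp[i] + exi * hp[i];
        }
      }
      if (mb > 0) M = clamp(M, -mb, mb);
      for (int k = 0; k < nm; ++k)
        if (m_times[k] == t + 1) Mrec.slice(bb).col(k) = vectorise(M);
      if (ret_go)
        Hgo.slice(bb).col(t + 1) = act_fun((M % W) * x_go + wgo + b, act);
      if (ret_Yall) Yall.slice(bb).col(t) = Wro * h + bro;
    }
    Y.col(bb) = Wro * h + bro;
  }

  List out = List::create(_["Y"] = Y);
  if (ret_H)    out["H"] = H;
  if (ret_Yall) out["Yall"] = Yall;
  if (nm > 0)   out["M"] = Mrec;
  if (ret_go)   out["Hgo"] = Hgo;
  return out;
}

// Cross-entropy loss (softmax over final outputs) + gradients for the MPN
// family. labels: 1-based class indices. Returns mean loss, accuracy and
// gradients w.r.t. every parameter (the R side masks non-trainable ones).
// Backward is fused column-wise: two passes per step, the first collecting
// the modulation-to-hidden backflow, the second writing dM_{t-1} and gW.
// [[Rcpp::export]]
List mpn_grad_cpp(const arma::mat& W, const arma::vec& b,
                  const arma::mat& Wro, const arma::vec& bro,
                  double eta, double lam,
                  const arma::cube& X, const arma::ivec& labels,
                  int rule, double mb, int act) {
  const int n = W.n_rows, d = W.n_cols, N = Wro.n_rows;
  const int T = X.n_cols, B = X.n_slices;

  mat gW(n, d, fill::zeros), gWro(N, n, fill::zeros);
  vec gb(n, fill::zeros), gbro(N, fill::zeros);
  double geta = 0.0, glam = 0.0, loss = 0.0;
  int ncorrect = 0;
  const double invB = 1.0 / B;

  cube Mh(n, d, T + 1);   // modulation history for one example
  mat Hh(n, T);
  mat dM(n, d), dMprev(n, d);
  vec a(n), dh(n), da(n), gx(n);

  for (int bb = 0; bb < B; ++bb) {
    const mat Xb = X.slice(bb);
    const mat WX = W * Xb;
    // ---- forward, recording state history ----
    Mh.slice(0).zeros();
    for (int t = 0; t < T; ++t) {
      const double* x = Xb.colptr(t);
      const mat& M = Mh.slice(t);
      a = WX.col(t) + b;
      double* ap = a.memptr();
      if (rule == RULE_ADD) {
        for (int I = 0; I < d; ++I) {
          const double xi = x[I];
          const double* mp = M.colptr(I);
          for (int i = 0; i < n; ++i) ap[i] += mp[i] * xi;
        }
      } else {
        for (int I = 0; I < d; ++I) {
          const double xi = x[I];
          const double* mp = M.colptr(I);
          const double* wp = W.colptr(I);
          for (int i = 0; i < n; ++i) ap[i] += mp[i] * wp[i] * xi;
        }
      }
      Hh.col(t) = act_fun(a, act);
      const double* hp = Hh.colptr(t);
      mat& Mn = Mh.slice(t + 1);
      if (rule == RULE_PRE) {
        for (int I = 0; I < d; ++I) {
          const double inc = (eta / n) * x[I];
          const double* mp = M.colptr(I);
          double* mq = Mn.colptr(I);
          for (int i = 0; i < n; ++i) mq[i] = lam * mp[i] + inc;
        }
      } else if (rule == RULE_POST) {
        for (int I = 0; I < d; ++I) {
          const double* mp = M.colptr(I);
          double* mq = Mn.colptr(I);
          for (int i = 0; i < n; ++i) mq[i] = lam * mp[i] + (eta / d) * hp[i];
        }
      } else {
        for (int I = 0; I < d; ++I) {
          const double exi = eta * x[I];
          const double* mp = M.colptr(I);
          double* mq = Mn.colptr(I);
          for (int i = 0; i < n; ++i) mq[i] = lam * mp[i] + exi * hp[i];
        }
      }
      if (mb > 0) Mn = clamp(Mn, -mb, mb);
    }
    const vec hT = Hh.col(T - 1);
    const vec y = Wro * hT + bro;
    const vec p = softmax_vec(y);
    const int lab = labels[bb] - 1;
    if (lab < 0 || lab >= N) Rcpp::stop("label out of range");
    loss += -std::log(std::max(p[lab], 1e-300)) * invB;
    if (y.index_max() == (uword)lab) ++ncorrect;

    vec dy = p * invB;
    dy[lab] -= invB;
    gWro += dy * hT.t();
    gbro += dy;

    // ---- backward through time ----
    dh = Wro.t() * dy;            // gradient w.r.t. h_t (only t = T seeded)
    dM.zeros();                   // gradient w.r.t. M_t
    for (int t = T - 1; t >= 0; --t) {
      const double* x = Xb.colptr(t);
      const double* hp = Hh.colptr(t);
      const mat& Mprev = Mh.slice(t);
      const mat& Mcur = Mh.slice(t + 1);
      const bool clip = mb > 0;
      // pass 1: modulation-update backflow (mask clipped elements)
      gx.zeros();
      double* gxp = gx.memptr();
      double gs_pre = 0.0;
      for (int I = 0; I < d; ++I) {
        double* gp = dM.colptr(I);
        const double* mc = Mcur.colptr(I);
        const double* mp = Mprev.colptr(I);
        const double xi = x[I];
        if (clip) {
          for (int i = 0; i < n; ++i)
            if (std::abs(mc[i]) >= mb) gp[i] = 0.0;
        }
        if (rule == RULE_PRE) {
          for (int i = 0; i < n; ++i) {
            gs_pre += gp[i] * xi;
            glam += gp[i] * mp[i];
          }
        } else if (rule == RULE_POST) {
          for (int i = 0; i < n; ++i) {
            gxp[i] += gp[i];
            glam += gp[i] * mp[i];
          }
        } else {
          for (int i = 0; i < n; ++i) {
            gxp[i] += gp[i] * xi;
            glam += gp[i] * mp[i];
          }
        }
      }
      if (rule == RULE_PRE) {
        geta += gs_pre / n;
      } else if (rule == RULE_POST) {
        geta += dot(gx, Hh.col(t)) / d;
        dh += (eta / d) * gx;
      } else {
        geta += dot(gx, Hh.col(t));
        dh += eta * gx;
      }
      da = dh % act_deriv(Hh.col(t), act);
      const double* dap = da.memptr();
      // pass 2: dM_{t-1} and gW
      for (int I = 0; I < d; ++I) {
        const double xi = x[I];
        const double* gp = dM.colptr(I);
        const double* mp = Mprev.colptr(I);
        const double* wp = W.colptr(I);
        double* dq = dMprev.colptr(I);
        double* gwp = gW.colptr(I);
        if (rule == RULE_ADD) {
          for (int i = 0; i < n; ++i) {
            const double o = dap[i] * xi;
            dq[i] = lam * gp[i] + o;
            gwp[i] += o;
          }
        } else {
          for (int i = 0; i < n; ++i) {
            const double o = dap[i] * xi;
            dq[i] = lam * gp[i] + o * wp[i];
            gwp[i] += o * (mp[i] + 1.0);
          }
        }
      }
      gb += da;
      dM.swap(dMprev);
      dh.zeros();  // h only feeds forward through M
    }
  }

  return List::create(_["loss"] = loss, _["acc"] = ncorrect * invB,
                      _["gW_inp"] = gW, _["gb"] = gb,
                      _["gW_RO"] = gWro, _["gb_RO"] = gbro,
                      _["geta"] = geta, _["glam"] = glam);
}

// ---------------- Vanilla RNN ----------------

// [[Rcpp::export]]
List rnn_forward_cpp(const arma::mat& W, const arma::mat& Wrec,
                     const arma::vec& b, const arma::mat& Wro,
                     const arma::vec& bro, const arma::cube& X, int act,
                     bool ret_H, bool ret_Yall) {
  const int n = W.n_rows, N = Wro.n_rows, T = X.n_cols, B = X.n_slices;
  mat Y(N, B);
  cube H, Yall;
  if (ret_H)    H.set_size(n, T, B);
  if (ret_Yall) Yall.set_size(N, T, B);
  for (int bb = 0; bb < B; ++bb) {
    const mat WX = W * X.slice(bb);
    vec h(n, fill::zeros);
    for (int t = 0; t < T; ++t) {
      h = act_fun(Wrec * h + WX.col(t) + b, act);
      if (ret_H) H.slice(bb).col(t) = h;
      if (ret_Yall) Yall.slice(bb).col(t) = Wro * h + bro;
    }
    Y.col(bb) = Wro * h + bro;
  }
  List out = List::create(_["Y"] = Y);
  if (ret_H)    out["H"] = H;
  if (ret_Yall) out["Yall"] = Yall;
  return out;
}

// [[Rcpp::export]]
List rnn_grad_cpp(const arma::mat& W, const arma::mat& Wrec,
                  const arma::vec& b, const arma::mat& Wro,
                  const arma::vec& bro, const arma::cube& X,
                  const arma::ivec& labels, int act) {
  const int n = W.n_rows, d = W.n_cols, N = Wro.n_rows;
  const int T = X.n_cols, B = X.n_slices;
  mat gW(n, d, fill::zeros), gWrec(n, n, fill::zeros), gWro(N, n, fill::zeros);
  vec gb(n, fill::zeros), gbro(N, fill::zeros);
  double loss = 0.0;
  int ncorrect = 0;
  const double invB = 1.0 / B;
  mat Hh(n, T);

  for (int bb = 0; bb < B; ++bb) {
    const mat Xb = X.slice(bb);
    const mat WX = W * Xb;
    vec h(n, fill::zeros);
    for (int t = 0; t < T; ++t) {
      h = act_fun(Wrec * h + WX.col(t) + b, act);
      Hh.col(t) = h;
    }
    const vec y = Wro * h + bro;
    const vec p = softmax_vec(y);
    const int lab = labels[bb] - 1;
    if (lab < 0 || lab >= N) Rcpp::stop("label out of range");
    loss += -std::log(std::max(p[lab], 1e-300)) * invB;
    if (y.index_max() == (uword)lab) ++ncorrect;
    vec dy = p * invB;
    dy[lab] -= invB;
    gWro += dy * h.t();
    gbro += dy;

    vec dh = Wro.t() * dy;
    mat DA(n, T);
    for (int t = T - 1; t >= 0; --t) {
      const vec da = dh % act_deriv(Hh.col(t), act);
      DA.col(t) = da;
      dh = Wrec.t() * da;
    }
    // accumulate weight gradients with single GEMMs over the sequence
    mat Hprev(n, T, fill::zeros);
    if (T > 1) Hprev.cols(1, T - 1) = Hh.cols(0, T - 2);
    gWrec += DA * Hprev.t();
    gW += DA * Xb.t();
    gb += sum(DA, 1);
  }
  return List::create(_["loss"] = loss, _["acc"] = ncorrect * invB,
                      _["gW_inp"] = gW, _["gW_rec"] = gWrec, _["gb"] = gb,
                      _["gW_RO"] = gWro, _["gb_RO"] = gbro);
}

// ---------------- GRU ----------------

static inline vec sigmoid_vec(const vec& a) { return 1.0 / (1.0 + exp(-a)); }

// [[Rcpp::export]]
List gru_forward_cpp(const arma::mat& Wu, const arma::mat& Vu, const arma::vec& bu,
                     const arma::mat& Wr, const arma::mat& Vr, const arma::vec& br,
                     const arma::mat& Wc, const arma::mat& Vc, const arma::vec& bc,
                     const arma::mat& Wro, const arma::vec& bro,
                     const arma::cube& X, int act, bool ret_H, bool ret_Yall) {
  // Wu/Wr/Wc: recurrent (n x n); Vu/Vr/Vc: input (n x d)
  const int n = Wu.n_rows, N = Wro.n_rows, T = X.n_cols, B = X.n_slices;
  mat Y(N, B);
  cube H, Yall;
  if (ret_H)    H.set_size(n, T, B);
  if (ret_Yall) Yall.set_size(N, T, B);
  for (int bb = 0; bb < B; ++bb) {
    const mat Xb = X.slice(bb);
    const mat VuX = Vu * Xb, VrX = Vr * Xb, VcX = Vc * Xb;
    vec h(n, fill::zeros);
    for (int t = 0; t < T; ++t) {
      const vec u = sigmoid_vec(Wu * h + VuX.col(t) + bu);
      const vec r = sigmoid_vec(Wr * h + VrX.col(t) + br);
      const vec hc = act_fun(Wc * (h % r) + VcX.col(t) + bc, act);
      h = (1.0 - u) % hc + u % h;
      if (ret_H) H.slice(bb).col(t) = h;
      if (ret_Yall) Yall.slice(bb).col(t) = Wro * h + bro;
    }
    Y.col(bb) = Wro * h + bro;
  }
  List out = List::create(_["Y"] = Y);
  if (ret_H)    out["H"] = H;
  if (ret_Yall) out["Yall"] = Yall;
  return out;
}

// [[Rcpp::export]]
List gru_grad_cpp(const arma::mat& Wu, const arma::mat& Vu, const arma::vec& bu,
                  const arma::mat& Wr, const arma::mat& Vr, const arma::vec& br,
                  const arma::mat& Wc, const arma::mat& Vc, const arma::vec& bc,
                  const arma::mat& Wro, const arma::vec& bro,
                  const arma::cube& X, const arma::ivec& labels, int act) {
  const int n = Wu.n_rows, d = Vu.n_cols, N = Wro.n_rows;
  const int T = X.n_cols, B = X.n_slices;
  mat gWu(n, n, fill::zeros), gWr(n, n, fill::zeros), gWc(n, n, fill::zeros);
  mat gVu(n, d, fill::zeros), gVr(n, d, fill::zeros), gVc(n, d, fill::zeros);
  vec gbu(n, fill::zeros), gbr(n, fill::zeros), gbc(n, fill::zeros);
  mat gWro(N, n, fill::zeros);
  vec gbro(N, fill::zeros);
  double loss = 0.0;
  int ncorrect = 0;
  const double invB = 1.0 / B;
  mat Uh(n, T), Rh(n, T), Ch(n, T), Hh(n, T);

  for (int bb = 0; bb < B; ++bb) {
    const mat Xb = X.slice(bb);
    const mat VuX = Vu * Xb, VrX = Vr * Xb, VcX = Vc * Xb;
    vec h(n, fill::zeros);
    for (int t = 0; t < T; ++t) {
      const vec u = sigmoid_vec(Wu * h + VuX.col(t) + bu);
      const vec r = sigmoid_vec(Wr * h + VrX.col(t) + br);
      const vec hc = act_fun(Wc * (h % r) + VcX.col(t) + bc, act);
      Uh.col(t) = u; Rh.col(t) = r; Ch.col(t) = hc;
      h = (1.0 - u) % hc + u % h;
      Hh.col(t) = h;
    }
    const vec y = Wro * h + bro;
    const vec p = softmax_vec(y);
    const int lab = labels[bb] - 1;
    if (lab < 0 || lab >= N) Rcpp::stop("label out of range");
    loss += -std::log(std::max(p[lab], 1e-300)) * invB;
    if (y.index_max() == (uword)lab) ++ncorrect;
    vec dy = p * invB;
    dy[lab] -= invB;
    gWro += dy * h.t();
    gbro += dy;

    vec dh = Wro.t() * dy;
    mat DAu(n, T), DAr(n, T), DAc(n, T), Hprev(n, T, fill::zeros), HR(n, T);
    if (T > 1) Hprev.cols(1, T - 1) = Hh.cols(0, T - 2);
    for (int t = T - 1; t >= 0; --t) {
      const vec u = Uh.col(t), r = Rh.col(t), hc = Ch.col(t);
      const vec hprev = Hprev.col(t);
      HR.col(t) = hprev % r;
      const vec du = dh % (hprev - hc);
      const vec dhc = dh % (1.0 - u);
      vec dhprev = dh % u;
      const vec dac = dhc % act_deriv(hc, act);
      DAc.col(t) = dac;
      const vec back_c = Wc.t() * dac;
      dhprev += back_c % r;
      const vec dr = back_c % hprev;
      const vec dau = du % u % (1.0 - u);
      const vec dar = dr % r % (1.0 - r);
      DAu.col(t) = dau;
      DAr.col(t) = dar;
      dhprev += Wu.t() * dau + Wr.t() * dar;
      dh = dhprev;
    }
    gWc += DAc * HR.t();    gVc += DAc * Xb.t();    gbc += sum(DAc, 1);
    gWu += DAu * Hprev.t(); gVu += DAu * Xb.t();    gbu += sum(DAu, 1);
    gWr += DAr * Hprev.t(); gVr += DAr * Xb.t();    gbr += sum(DAr, 1);
  }
  return List::create(_["loss"] = loss, _["acc"] = ncorrect * invB,
                      _["gW_rec_u"] = gWu, _["gW_inp_u"] = gVu, _["gb_u"] = gbu,
                      _["gW_rec_r"] = gWr, _["gW_inp_r"] = gVr, _["gb_r"] = gbr,
                      _["gW_rec"] = gWc, _["gW_inp"] = gVc, _["gb"] = gbc,
                      _["gW_RO"] = gWro, _["gb_RO"] = gbro);
}
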