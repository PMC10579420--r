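#include <Rcpp.h>
using namespace Rcpp;

// Leaky-integrator rate network used throughout the package.
//
// Context units:  u_i(t) = (1-1/tau) u_i(t-1)
//                          + (1/tau) [ sum_j Wcx_ij x_j(t) + sum_k Wcc_ik c_k(t-1) ]
//                 c_i(t) = f(u_i(t)),  f(u) = 1/(1+exp(-a u))
// Output units:   o_i(t) = f( sum_j Woc_ij c_j(t-1) )
//
// Lesion kinds (applied only at run time, never during training):
//   0 none
//   1 td_context : recurrent read c_k(t-1-D_i), D_i ~ Bern(delta_prob) per
//                  receiving context unit per step
//   2 noise      : u_i(t) <- u_i(t) * (1 + eta_i(t)); eta uniform on
//                  [-level, level] (or N(0, level) when noise_gauss)
//   3 td_output  : only the SoA output unit reads c_j(t-1-D), one D per step
//   4 td_input   : x_j(t-D_j), D_j ~ Bern(delta_prob) per input unit per step
//
// Histories before the first step are fixed at c = f(0) = 0.5, x = 0.1
// (channel baseline) and u = 0, so delayed reads at the sequence start are
// well defined. All randomness goes through R's RNG.

static inline double sigmoid(double u, double gain) {
  return 1.0 / (1.0 + std::exp(-gain * u));
}

// [[Rcpp::export]]
List ctrnn_forward_cpp(NumericMatrix W_cx, NumericMatrix W_cc,
                       NumericMatrix W_oc, double tau, double gain,
                       NumericMatrix X, int lesion_kind,
                       double delta_prob, double noise_level,
                       bool noise_gauss, int soa_index) {
  const int T = X.nrow();
  const int n_in = X.ncol();
  const int n_c = W_cc.nrow();
  const int n_out = W_oc.nrow();
  if (T < 1) stop("sequence must have at least one step");

  NumericMatrix U(T, n_c), C(T, n_c), O(T, n_out);

  std::vector<double> u_prev(n_c, 0.0);
  std::vector<double> c_tm1(n_c, 0.5), c_tm2(n_c, 0.5);
  std::vector<double> x_tm1(n_in, 0.1);
  std::vector<double> x_src(n_in), c_t(n_c);

  const double leak = 1.0 - 1.0 / tau;
  const double gate = 1.0 / tau;

  for (int t = 0; t < T; ++t) {
    // outputs read context activations from the previous step
    int d_out = 0;
    if (lesion_kind == 3) d_out = (unif_rand() < delta_prob) ? 1 : 0;
    for (int i = 0; i < n_out; ++i) {
      const std::vector<double> &src =
          (lesion_kind == 3 && i == soa_index && d_out == 1) ? c_tm2 : c_tm1;
      double s = 0.0;
      for (int j = 0; j < n_c; ++j) s += W_oc(i, j) * src[j];
      O(t, i) = sigmoid(s, gain);
    }

    // input source, possibly delayed per input unit
    for (int j = 0; j < n_in; ++j) {
      if (lesion_kind == 4 && unif_rand() < delta_prob)
        x_src[j] = x_tm1[j];
      else
        x_src[j] = X(t, j);
    }

    // context update
    for (int i = 0; i < n_c; ++i) {
      const std::vector<double> &rec =
          (lesion_kind == 1 && unif_rand() < delta_prob) ? c_tm2 : c_tm1;
      double s = 0.0;
      for (int j = 0; j < n_in; ++j) s += W_cx(i, j) * x_src[j];
      for (int k = 0; k < n_c; ++k) s += W_cc(i, k) * rec[k];
      double u = leak * u_prev[i] + gate * s;
      if (lesion_kind == 2 && noise_level > 0.0) {
        double eta = noise_gauss ? norm_rand() * noise_level
                                 : (2.0 * unif_rand() - 1.0) * noise_level;
        u *= (1.0 + eta);
      }
      U(t, i) = u;
      c_t[i] = sigmoid(u, gain);
    }

    for (int i = 0; i < n_c; ++i) {
      u_prev[i] = U(t, i);
      C(t, i) = c_t[i];
      c_tm2[i] = c_tm1[i];
      c_tm1[i] = c_t[i];
    }
    for (int j = 0; j < n_in; ++j) x_tm1[j] = X(t, j);
  }

  return List::create(_["U"] = U, _["C"] = C, _["O"] = O);
}

// ---------------------------------------------------------------------------
// Training support. Sequences are copied once into flat column-major
// buffers; all per-epoch work runs on preallocated workspace so the epoch
// loop does no allocation.

struct BatchData {
  int n_in, n_out, n_c, n_seq;
  long n_terms;
  std::vector<int> T;                       // steps per sequence
  std::vector<std::vector<double>> X;       // T x n_in, column-major
  std::vector<std::vector<double>> Y;       // T x n_out, column-major
  int maxT;
};

static BatchData make_batch(const List &X_list, const List &Y_list,
                            int n_c) {
  BatchData b;
  b.n_seq = X_list.size();
  b.n_c = n_c;
  b.n_terms = 0;
  b.maxT = 0;
  b.T.resize(b.n_seq);
  b.X.resize(b.n_seq);
  b.Y.resize(b.n_seq);
  for (int s = 0; s < b.n_seq; ++s) {
    NumericMatrix X = X_list[s];
    NumericMatrix Y = Y_list[s];
    if (s == 0) {
      b.n_in = X.ncol();
      b.n_out = Y.ncol();
    }
    if (X.ncol() != b.n_in || Y.ncol() != b.n_out || Y.nrow() != X.nrow())
      stop("sequences do not share a common channel layout");
    b.T[s] = X.nrow();
    b.n_terms += b.T[s];
    b.maxT = std::max(b.maxT, b.T[s]);
    b.X[s].assign(X.begin(), X.end());
    b.Y[s].assign(Y.begin(), Y.end());
  }
  if (b.n_terms == 0) stop("empty batch");
  return b;
}

struct Workspace {
  std::vector<double> C;    // (maxT+1) x n_c, row 0 = pre-sequence history
  std::vector<double> U, O, dO;
  std::vector<double> r, r_next;
  Workspace(const BatchData &b) {
    C.resize((b.maxT + 1) * b.n_c);
    U.resize(b.maxT * b.n_c);
    O.resize(b.maxT * b.n_out);
    dO.resize(b.maxT * b.n_out);
    r.resize(b.n_c);
    r_next.resize(b.n_c);
  }
};

// Loss is the mean over sequences and steps of the weighted squared output
// error: E = 1/(N T) * sum_{s,t} sum_i lw_i (o_i(t) - y_i(t))^2 / 2.
// NA targets contribute nothing (channels without supervision).
// Templated on the unit counts so the standard 10/3/4 architecture is fully
// unrolled by the compiler; NC = 0 selects the runtime-sized fallback.
template <int NC, int NI, int NO>
static double batch_loss_grad_impl(const double *Wcx, const double *Wcc,
                                   const double *Woc, double tau, double gain,
                                   const BatchData &b, const double *lw,
                                   Workspace &ws, double *Gcx, double *Gcc,
                                   double *Goc) {
  const int n_c = NC ? NC : b.n_c;
  const int n_in = NC ? NI : b.n_in;
  const int n_out = NC ? NO : b.n_out;
  const double leak = 1.0 - 1.0 / tau;
  const double gate = 1.0 / tau;

  std::fill(Gcx, Gcx + n_c * n_in, 0.0);
  std::fill(Gcc, Gcc + n_c * n_c, 0.0);
  std::fill(Goc, Goc + n_out * n_c, 0.0);

  double loss = 0.0;

  for (int s = 0; s < b.n_seq; ++s) {
    const int T = b.T[s];
    const double *X = b.X[s].data();
    const double *Y = b.Y[s].data();
    double *C = ws.C.data();      // C[t*n_c + i] = c_i(t-1); row 0 history
    double *U = ws.U.data();
    double *O = ws.O.data();
    double *dO = ws.dO.data();

    for (int i = 0; i < n_c; ++i) C[i] = 0.5;

    // forward; matrix-vector products are organised as column sweeps so the
    // inner loops run with unit stride
    for (int t = 0; t < T; ++t) {
      const double *c_prev = C + t * n_c;
      double *c_cur = C + (t + 1) * n_c;
      double o_su[16];
      std::fill(o_su, o_su + n_out, 0.0);
      for (int j = 0; j < n_c; ++j) {
        const double cj = c_prev[j];
        const double *col = Woc + n_out * j;
        for (int i = 0; i < n_out; ++i) o_su[i] += col[i] * cj;
      }
      for (int i = 0; i < n_out; ++i) {
        double o = sigmoid(o_su[i], gain);
        O[i * b.maxT + t] = o;
        double y = Y[i * T + t];
        if (ISNAN(y)) {
          dO[i * b.maxT + t] = 0.0;
        } else {
          double e = o - y;
          loss += 0.5 * lw[i] * e * e;
          dO[i * b.maxT + t] = lw[i] * e * gain * o * (1.0 - o);
        }
      }
      double *u_cur = U + t * n_c;
      const double *u_prev = (t == 0) ? nullptr : U + (t - 1) * n_c;
      for (int i = 0; i < n_c; ++i) u_cur[i] = 0.0;
      for (int j = 0; j < n_in; ++j) {
        const double xj = X[j * T + t];
        const double *col = Wcx + n_c * j;
        for (int i = 0; i < n_c; ++i) u_cur[i] += col[i] * xj;
      }
      for (int k = 0; k < n_c; ++k) {
        const double ck = c_prev[k];
        const double *col = Wcc + n_c * k;
        for (int i = 0; i < n_c; ++i) u_cur[i] += col[i] * ck;
      }
      for (int i = 0; i < n_c; ++i) {
        double u = gate * u_cur[i] + (u_prev ? leak * u_prev[i] : 0.0);
        u_cur[i] = u;
        c_cur[i] = sigmoid(u, gain);
      }
    }

    // backward through time: r[i] = dE/du_c_i(t)
    std::fill(ws.r_next.begin(), ws.r_next.end(), 0.0);
    double *r = ws.r.data();
    double *r_next = ws.r_next.data();
    for (int t = T - 1; t >= 0; --t) {
      const double *c_row = C + (t + 1) * n_c;  // c(t)
      for (int i = 0; i < n_c; ++i) {
        double dc = 0.0;
        if (t + 1 < T) {
          const double *wcol = Woc + n_out * i;  // column i, unit stride
          for (int o = 0; o < n_out; ++o)
            dc += wcol[o] * dO[o * b.maxT + (t + 1)];
          const double *ccol = Wcc + n_c * i;
          double rec = 0.0;
          for (int k = 0; k < n_c; ++k) rec += ccol[k] * r_next[k];
          dc += gate * rec;
        }
        double slope = gain * c_row[i] * (1.0 - c_row[i]);
        double acc = dc * slope;
        if (t + 1 < T) acc += leak * r_next[i];
        r[i] = acc;
      }
      const double *c_prev = C + t * n_c;       // c(t-1)
      for (int j = 0; j < n_in; ++j) {
        const double xg = gate * X[j * T + t];
        double *col = Gcx + n_c * j;
        for (int i = 0; i < n_c; ++i) col[i] += r[i] * xg;
      }
      for (int k = 0; k < n_c; ++k) {
        const double cg = gate * c_prev[k];
        double *col = Gcc + n_c * k;
        for (int i = 0; i < n_c; ++i) col[i] += r[i] * cg;
      }
      for (int j = 0; j < n_c; ++j) {
        const double cj = c_prev[j];
        double *col = Goc + n_out * j;
        for (int o = 0; o < n_out; ++o) col[o] += dO[o * b.maxT + t] * cj;
      }
      std::swap(r, r_next);
    }
  }

  const double scale = 1.0 / double(b.n_terms);
  for (int i = 0; i < n_c * n_in; ++i) Gcx[i] *= scale;
  for (int i = 0; i < n_c * n_c; ++i) Gcc[i] *= scale;
  for (int i = 0; i < n_out * n_c; ++i) Goc[i] *= scale;
  return loss * scale;
}

static double batch_loss_grad(const double *Wcx, const double *Wcc,
                              const double *Woc, double tau, double gain,
                              const BatchData &b, const double *lw,
                              Workspace &ws, double *Gcx, double *Gcc,
                              double *Goc) {
  if (b.n_c == 10 && b.n_in == 3 && b.n_out == 4)
    return batch_loss_grad_impl<10, 3, 4>(Wcx, Wcc, Woc, tau, gain, b, lw,
                                          ws, Gcx, Gcc, Goc);
  return batch_loss_grad_impl<0, 0, 0>(Wcx, Wcc, Woc, tau, gain, b, lw, ws,
                                       Gcx, Gcc, Goc);
}

// [[Rcpp::export]]
List ctrnn_loss_grad_cpp(NumericMatrix W_cx, NumericMatrix W_cc,
                         NumericMatrix W_oc, double tau, double gain,
                         List X_list, List Y_list,
                         NumericVector loss_weights) {
  BatchData b = make_batch(X_list, Y_list, W_cc.nrow());
  Workspace ws(b);
  NumericMatrix G_cx(W_cx.nrow(), W_cx.ncol());
  NumericMatrix G_cc(W_cc.nrow(), W_cc.ncol());
  NumericMatrix G_oc(W_oc.nrow(), W_oc.ncol());
  double loss = batch_loss_grad(
      REAL(SEXP(W_cx)), REAL(SEXP(W_cc)), REAL(SEXP(W_oc)), tau, gain, b,
      REAL(SEXP(loss_weights)), ws, REAL(SEXP(G_cx)), REAL(SEXP(G_cc)),
      REAL(SEXP(G_oc)));
  return List::create(_["loss"] = loss, _["G_cx"] = G_cx, _["G_cc"] = G_cc,
                      _["G_oc"] = G_oc);
}

// Full-batch training. optimizer 0: gradient descent with classical
// momentum (velocity v = m v - lr g). optimizer 1: iRprop- (sign-based
// per-weight step sizes, eta+ = 1.2, eta- = 0.5, steps clipped to
// [1e-8, 1]; lr is the initial step size), which is robust for full-batch
// schedules. optimizer 2: Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
// with bias correction.
// [[Rcpp::export]]
List ctrnn_train_cpp(NumericMatrix W_cx, NumericMatrix W_cc,
                     NumericMatrix W_oc, double tau, double gain,
                     List X_list, List Y_list, NumericVector loss_weights,
                     double lr, double momentum, int epochs,
                     int record_every, int optimizer,
                     double rprop_step_max) {
  BatchData b = make_batch(X_list, Y_list, W_cc.nrow());
  Workspace ws(b);
  NumericMatrix Wcx = clone(W_cx), Wcc = clone(W_cc), Woc = clone(W_oc);
  const int ncx = Wcx.size(), ncc = Wcc.size(), noc = Woc.size();
  const int ntot = ncx + ncc + noc;
  std::vector<double> G(ntot), V(ntot, 0.0), Gprev(ntot, 0.0);
  std::vector<double> step(ntot, lr);
  double *w[3] = {REAL(SEXP(Wcx)), REAL(SEXP(Wcc)), REAL(SEXP(Woc))};
  const int sizes[3] = {ncx, ncc, noc};
  const double *lw = REAL(SEXP(loss_weights));

  std::vector<double> history;
  history.reserve(epochs / std::max(record_every, 1) + 2);

  for (int ep = 0; ep < epochs; ++ep) {
    double loss = batch_loss_grad(w[0], w[1], w[2], tau, gain, b, lw, ws,
                                  G.data(), G.data() + ncx,
                                  G.data() + ncx + ncc);
    if (!std::isfinite(loss))
      stop("training diverged (non-finite loss) at epoch %d", ep + 1);
    if (record_every > 0 && ep % record_every == 0) history.push_back(loss);
    int off = 0;
    for (int m = 0; m < 3; ++m) {
      double *wm = w[m];
      for (int i = 0; i < sizes[m]; ++i) {
        const int k = off + i;
        if (optimizer == 1) {
          const double prod = G[k] * Gprev[k];
          if (prod > 0.0)
            step[k] = std::min(step[k] * 1.2, rprop_step_max);
          else if (prod < 0.0) {
            step[k] = std::max(step[k] * 0.5, 1e-8);
            G[k] = 0.0;  // iRprop-: skip the update after a sign flip
          }
          if (G[k] > 0.0) wm[i] -= step[k];
          else if (G[k] < 0.0) wm[i] += step[k];
          Gprev[k] = G[k];
        } else if (optimizer == 2) {
          // V holds the first moment, step the second
          V[k] = 0.9 * V[k] + 0.1 * G[k];
          if (ep == 0) step[k] = 0.0;  // step doubles as the 2nd moment
          step[k] = 0.999 * step[k] + 0.001 * G[k] * G[k];
          const double mhat = V[k] / (1.0 - std::pow(0.9, ep + 1));
          const double vhat = step[k] / (1.0 - std::pow(0.999, ep + 1));
          wm[i] -= lr * mhat / (std::sqrt(vhat) + 1e-8);
        } else {
          V[k] = momentum * V[k] - lr * G[k];
          wm[i] += V[k];
        }
      }
      off += sizes[m];
    }
    if (ep % 256 == 0) Rcpp::checkUserInterrupt();
  }
  double final_loss = batch_loss_grad(w[0], w[1], w[2], tau, gain, b, lw,
                                      ws, G.data(), G.data() + ncx,
                                      G.data() + ncx + ncc);
  history.push_back(final_loss);

  return List::create(_["W_cx"] = Wcx, _["W_cc"] = Wcc, _["W_oc"] = Woc,
                      _["loss"] = final_loss,
                      _["loss_history"] = NumericVector(history.begin(),
                                                        history.end()));
}
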