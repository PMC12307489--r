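// Hot numerical kernels for the network: temporal / depthwise / spatial
// convolutions and a fused LSTM layer, each with a hand-written backward pass.
// Tensor layout is column-major (B, D, C, T): batch fastest, time slowest, so
// the innermost loops below run over contiguous memory.
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& B, int& D, int& C, int& T) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d tensor (B, D, C, T)");
  B = dm[0]; D = dm[1]; C = dm[2]; T = dm[3];
}

// Repack (B, D, C, T) -> N x D matrix with rows ordered (b, c, t), b fastest.
// With t slowest, a temporal shift by delta is a contiguous row shift of
// B*C*delta, which lets the convolution run as one BLAS GEMM per kernel tap.
static arma::mat repack_bct(const double* xp, int B, int D, int C, int T) {
  const R_xlen_t N = (R_xlen_t)B * C * T;
  arma::mat out((arma::uword)N, (arma::uword)D);
  for (int d = 0; d < D; ++d) {
    double* op = out.colptr(d);
    for (int t = 0; t < T; ++t)
      for (int c = 0; c < C; ++c) {
        const double* src = xp + (R_xlen_t)B * (d + (R_xlen_t)D * (c + (R_xlen_t)C * t));
        std::memcpy(op + (R_xlen_t)B * (c + (R_xlen_t)C * t), src,
                    sizeof(double) * B);
      }
  }
  return out;
}

static void unpack_bct(const arma::mat& m, double* yp, int B, int D, int C, int T) {
  for (int d = 0; d < D; ++d) {
    const double* ip = m.colptr(d);
    for (int t = 0; t < T; ++t)
      for (int c = 0; c < C; ++c) {
        double* dst = yp + (R_xlen_t)B * (d + (R_xlen_t)D * (c + (R_xlen_t)C * t));
        std::memcpy(dst, ip + (R_xlen_t)B * (c + (R_xlen_t)C * t),
                    sizeof(double) * B);
      }
  }
}

// Temporal convolution, zero-padded to preserve T ("same").
// x: (B, Din, C, T); w: (Dout, Din, K); bias: length Dout or NULL.
// y[b,do,c,t] = bias[do] + sum_{di,k} w[do,di,k] * x[b,di,c,t+k-pad]
// [[Rcpp::export]]
NumericVector cpp_conv_t_fw(const NumericVector& x, const NumericVector& w,
                            const Nullable<NumericVector>& bias) {
  int B, Din, C, T;
  get_dims4(x, B, Din, C, T);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 3 || wd[1] != Din) stop("weight must be (Dout, Din, K) with Din matching x");
  const int Dout = wd[0], K = wd[2];
  const int pad = (K - 1) / 2;
  const R_xlen_t N = (R_xlen_t)B * C * T;
  const R_xlen_t BC = (R_xlen_t)B * C;
  NumericVector y(N * Dout);
  y.attr("dim") = IntegerVector::create(B, Dout, C, T);
  arma::mat X2 = repack_bct(x.begin(), B, Din, C, T);
  arma::mat Y2((arma::uword)N, (arma::uword)Dout, arma::fill::zeros);
  const double* wp = w.begin();
  const int iN = (int)N;
  const double one = 1.0;
  for (int k = 0; k < K; ++k) {
    const int delta = k - pad;
    const int t0 = std::max(0, -delta), t1 = std::min(T - 1, T - 1 - delta);
    if (t0 > t1) continue;
    arma::mat Wk(Din, Dout);
    for (int dout = 0; dout < Dout; ++dout)
      for (int din = 0; din < Din; ++din)
        Wk(din, dout) = wp[dout + (R_xlen_t)Dout * (din + (R_xlen_t)Din * k)];
    const R_xlen_t r0 = BC * t0;
    const R_xlen_t s0 = BC * (t0 + delta);
    const int M = (int)(BC * (t1 - t0 + 1));
    // strided submatrix GEMM: rows are contiguous blocks inside X2/Y2
    F77_CALL(dgemm)("N", "N", &M, &Dout, &Din, &one,
                    X2.memptr() + s0, &iN, Wk.memptr(), &Din, &one,
                    Y2.memptr() + r0, &iN FCONE FCONE);
  }
  if (bias.isNotNull()) {
    NumericVector bb(bias);
    if (bb.size() != Dout) stop("bias length must equal Dout");
    for (int d = 0; d < Dout; ++d) Y2.col(d) += bb[d];
  }
  unpack_bct(Y2, y.begin(), B, Dout, C, T);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_t_bw(const NumericVector& x, const NumericVector& w,
                   const NumericVector& gy, bool has_bias) {
  int B, Din, C, T;
  get_dims4(x, B, Din, C, T);
  IntegerVector wd = w.attr("dim");
  const int Dout = wd[0], K = wd[2];
  const int pad = (K - 1) / 2;
  const R_xlen_t N = (R_xlen_t)B * C * T;
  const R_xlen_t BC = (R_xlen_t)B * C;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(has_bias ? Dout : 0);
  arma::mat X2 = repack_bct(x.begin(), B, Din, C, T);
  arma::mat G2 = repack_bct(gy.begin(), B, Dout, C, T);
  arma::mat GX2((arma::uword)N, (arma::uword)Din, arma::fill::zeros);
  double* gwp = gw.begin();
  const int iN = (int)N;
  const double one = 1.0, zero = 0.0;
  for (int k = 0; k < K; ++k) {
    const int delta = k - pad;
    const int t0 = std::max(0, -delta), t1 = std::min(T - 1, T - 1 - delta);
    if (t0 > t1) continue;
    const R_xlen_t r0 = BC * t0;
    const R_xlen_t s0 = BC * (t0 + delta);
    const int M = (int)(BC * (t1 - t0 + 1));
    arma::mat GWk(Din, Dout);
    F77_CALL(dgemm)("T", "N", &Din, &Dout, &M, &one,
                    X2.memptr() + s0, &iN, G2.memptr() + r0, &iN, &zero,
                    GWk.memptr(), &Din FCONE FCONE);
    arma::mat Wk(Din, Dout);
    const double* wp = w.begin();
    for (int dout = 0; dout < Dout; ++dout)
      for (int din = 0; din < Din; ++din) {
        Wk(din, dout) = wp[dout + (R_xlen_t)Dout * (din + (R_xlen_t)Din * k)];
        gwp[dout + (R_xlen_t)Dout * (din + (R_xlen_t)Din * k)] = GWk(din, dout);
      }
    F77_CALL(dgemm)("N", "T", &M, &Din, &Dout, &one,
                    G2.memptr() + r0, &iN, Wk.memptr(), &Din, &one,
                    GX2.memptr() + s0, &iN FCONE FCONE);
  }
  if (has_bias)
    for (int d = 0; d < Dout; ++d) gb[d] = arma::accu(G2.col(d));
  unpack_bct(GX2, gx.begin(), B, Din, C, T);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---- broadcasting / reduction helpers over <= 4-d arrays ----------------------

static void bcast_dims(const NumericVector& x, int dims[4]) {
  dims[0] = dims[1] = dims[2] = dims[3] = 1;
  SEXP da = x.attr("dim");
  if (Rf_isNull(da)) { dims[0] = x.size(); return; }
  IntegerVector d(da);
  if (d.size() > 4) stop("broadcast kernels support up to 4 axes");
  for (int i = 0; i < d.size(); ++i) dims[i] = d[i];
}

// Element-wise binary op with singleton-axis broadcasting.
// op: 0 add, 1 mul, 2 sub.
// [[Rcpp::export]]
NumericVector cpp_bin_bcast(const NumericVector& a, const NumericVector& b,
                            int op, const IntegerVector& out_dim) {
  int da[4], db[4];
  bcast_dims(a, da); bcast_dims(b, db);
  int dn = out_dim.size();
  int od[4] = {1, 1, 1, 1};
  for (int i = 0; i < dn; ++i) od[i] = out_dim[i];
  R_xlen_t n = (R_xlen_t)od[0] * od[1] * od[2] * od[3];
  NumericVector out(n);
  out.attr("dim") = out_dim;
  // strides (0 where broadcast)
  R_xlen_t sa[4], sb[4];
  R_xlen_t ca = 1, cb = 1;
  for (int i = 0; i < 4; ++i) {
    sa[i] = (da[i] == od[i]) ? ca : 0;
    sb[i] = (db[i] == od[i]) ? cb : 0;
    if (da[i] != od[i] && da[i] != 1) stop("broadcast shape mismatch (a)");
    if (db[i] != od[i] && db[i] != 1) stop("broadcast shape mismatch (b)");
    ca *= da[i]; cb *= db[i];
  }
  const double* ap = a.begin();
  const double* bp = b.begin();
  double* op_ = out.begin();
  R_xlen_t idx = 0;
  for (int i3 = 0; i3 < od[3]; ++i3)
    for (int i2 = 0; i2 < od[2]; ++i2)
      for (int i1 = 0; i1 < od[1]; ++i1) {
        const double* aa = ap + i1 * sa[1] + i2 * sa[2] + i3 * sa[3];
        const double* bb = bp + i1 * sb[1] + i2 * sb[2] + i3 * sb[3];
        if (sa[0] && sb[0]) {
          switch (op) {
          case 0: for (int i0 = 0; i0 < od[0]; ++i0) op_[idx++] = aa[i0] + bb[i0]; break;
          case 1: for (int i0 = 0; i0 < od[0]; ++i0) op_[idx++] = aa[i0] * bb[i0]; break;
          default: for (int i0 = 0; i0 < od[0]; ++i0) op_[idx++] = aa[i0] - bb[i0];
          }
        } else {
          for (int i0 = 0; i0 < od[0]; ++i0) {
            const double av = aa[i0 * sa[0]], bv = bb[i0 * sb[0]];
            op_[idx++] = (op == 0) ? av + bv : (op == 1) ? av * bv : av - bv;
          }
        }
      }
  return out;
}

// Sum `x` down to `target_dim` (each target axis equals x's or is 1).
// [[Rcpp::export]]
NumericVector cpp_sum_to(const NumericVector& x, const IntegerVector& target_dim) {
  int dx[4];
  bcast_dims(x, dx);
  int dn = target_dim.size();
  int td[4] = {1, 1, 1, 1};
  for (int i = 0; i < dn; ++i) td[i] = target_dim[i];
  R_xlen_t n = (R_xlen_t)td[0] * td[1] * td[2] * td[3];
  NumericVector out(n);
  out.attr("dim") = target_dim;
  R_xlen_t st[4];
  R_xlen_t c = 1;
  for (int i = 0; i < 4; ++i) {
    if (td[i] != dx[i] && td[i] != 1) stop("reduction shape mismatch");
    st[i] = (td[i] == dx[i]) ? c : 0;
    c *= td[i];
  }
  const double* xp = x.begin();
  double* op_ = out.begin();
  R_xlen_t idx = 0;
  for (int i3 = 0; i3 < dx[3]; ++i3)
    for (int i2 = 0; i2 < dx[2]; ++i2)
      for (int i1 = 0; i1 < dx[1]; ++i1) {
        double* oo = op_ + i1 * st[1] + i2 * st[2] + i3 * st[3];
        if (st[0]) {
          for (int i0 = 0; i0 < dx[0]; ++i0) oo[i0] += xp[idx++];
        } else {
          double s = 0.0;
          for (int i0 = 0; i0 < dx[0]; ++i0) s += xp[idx++];
          *oo += s;
        }
      }
  return out;
}

// Depth-axis concatenation of 4-d tensors sharing (B, C, T).
// [[Rcpp::export]]
NumericVector cpp_concat_depth(const List& xs) {
  const int m = xs.size();
  std::vector<const double*> ptrs(m);
  std::vector<int> depths(m);
  int B = 0, C = 0, T = 0, Dtot = 0;
  for (int i = 0; i < m; ++i) {
    NumericVector xi(xs[i]);
    int b, d, c, t;
    get_dims4(xi, b, d, c, t);
    if (i == 0) { B = b; C = c; T = t; }
    else if (b != B || c != C || t != T) stop("concat shapes differ");
    ptrs[i] = REAL(xs[i]);
    depths[i] = d;
    Dtot += d;
  }
  NumericVector out((R_xlen_t)B * Dtot * C * T);
  out.attr("dim") = IntegerVector::create(B, Dtot, C, T);
  double* op = out.begin();
  const R_xlen_t ct = (R_xlen_t)C * T;
  for (R_xlen_t j = 0; j < ct; ++j) {
    double* oj = op + (R_xlen_t)B * Dtot * j;
    R_xlen_t off = 0;
    for (int i = 0; i < m; ++i) {
      std::memcpy(oj + off, ptrs[i] + (R_xlen_t)B * depths[i] * j,
                  sizeof(double) * B * depths[i]);
      off += (R_xlen_t)B * depths[i];
    }
  }
  return out;
}

// Split gradient of a depth concatenation back into parts.
// [[Rcpp::export]]
List cpp_split_depth(const NumericVector& g, const IntegerVector& depths) {
  int B, Dtot, C, T;
  get_dims4(g, B, Dtot, C, T);
  const int m = depths.size();
  List out(m);
  std::vector<double*> ptrs(m);
  for (int i = 0; i < m; ++i) {
    NumericVector gi((R_xlen_t)B * depths[i] * C * T);
    gi.attr("dim") = IntegerVector::create(B, depths[i], C, T);
    out[i] = gi;
    ptrs[i] = REAL(out[i]);
  }
  const double* gp = g.begin();
  const R_xlen_t ct = (R_xlen_t)C * T;
  for (R_xlen_t j = 0; j < ct; ++j) {
    const double* gj = gp + (R_xlen_t)B * Dtot * j;
    R_xlen_t off = 0;
    for (int i = 0; i < m; ++i) {
      std::memcpy(ptrs[i] + (R_xlen_t)B * depths[i] * j, gj + off,
                  sizeof(double) * B * depths[i]);
      off += (R_xlen_t)B * depths[i];
    }
  }
  return out;
}

// Broadcast x up to out_dim (singleton axes replicated).
// [[Rcpp::export]]
NumericVector cpp_expand(const NumericVector& x, const IntegerVector& out_dim) {
  NumericVector zero(1);
  return cpp_bin_bcast(x, zero, 0, out_dim);
}

// Depthwise temporal convolution: one 1 x K kernel per depth map.
// x: (B, D, C, T); w: (D, K).
// [[Rcpp::export]]
NumericVector cpp_dwconv_t_fw(const NumericVector& x, const NumericMatrix& w) {
  int B, D, C, T;
  get_dims4(x, B, D, C, T);
  if (w.nrow() != D) stop("depthwise weight must have D rows");
  const int K = w.ncol();
  const int pad = (K - 1) / 2;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      const int tin = t + k - pad;
      if (tin < 0 || tin >= T) continue;
      for (int c = 0; c < C; ++c)
        for (int d = 0; d < D; ++d) {
          const double wv = w(d, k);
          const double* xi = xp + (R_xlen_t)B * (d + (R_xlen_t)D * (c + (R_xlen_t)C * tin));
          double* yo = yp + (R_xlen_t)B * (d + (R_xlen_t)D * (c + (R_xlen_t)C * t));
          for (int b = 0; b < B; ++b) yo[b] += wv * xi[b];
        }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_t_bw(const NumericVector& x, const NumericMatrix& w,
                     const NumericVector& gy) {
  int B, D, C, T;
  get_dims4(x, B, D, C, T);
  const int K = w.ncol();
  const int pad = (K - 1) / 2;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericMatrix gw(D, K);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      const int tin = t + k - pad;
      if (tin < 0 || tin >= T) continue;
      for (int c = 0; c < C; ++c)
        for (int d = 0; d < D; ++d) {
          const double wv = w(d, k);
          const double* xi = xp + (R_xlen_t)B * (d + (R_xlen_t)D * (c + (R_xlen_t)C * tin));
          double* gxi = gxp + (R_xlen_t)B * (d + (R_xlen_t)D * (c + (R_xlen_t)C * tin));
          const double* go = gp + (R_xlen_t)B * (d + (R_xlen_t)D * (c + (R_xlen_t)C * t));
          double s = 0.0;
          for (int b = 0; b < B; ++b) {
            s += go[b] * xi[b];
            gxi[b] += wv * go[b];
          }
          gw(d, k) += s;
        }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Axial spatial convolution: a C x 1 kernel per depth map collapses the
// channel axis. x: (B, D, C, T); w: (D, C); y: (B, D, 1, T).
// [[Rcpp::export]]
NumericVector cpp_spconv_fw(const NumericVector& x, const NumericMatrix& w,
                            const Nullable<NumericVector>& bias) {
  int B, D, C, T;
  get_dims4(x, B, D, C, T);
  if (w.nrow() != D || w.ncol() != C) stop("spatial weight must be (D, C)");
  NumericVector y(static_cast<R_xlen_t>(B) * D * T);
  y.attr("dim") = IntegerVector::create(B, D, 1, T);
  const double* xp = x.begin();
  double* yp = y.begin();
  if (bias.isNotNull()) {
    NumericVector bb(bias);
    for (int t = 0; t < T; ++t)
      for (int d = 0; d < D; ++d) {
        double* yo = yp + (R_xlen_t)B * (d + (R_xlen_t)D * t);
        for (int b = 0; b < B; ++b) yo[b] = bb[d];
      }
  }
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < C; ++c)
      for (int d = 0; d < D; ++d) {
        const double wv = w(d, c);
        const double* xi = xp + (R_xlen_t)B * (d + (R_xlen_t)D * (c + (R_xlen_t)C * t));
        double* yo = yp + (R_xlen_t)B * (d + (R_xlen_t)D * t);
        for (int b = 0; b < B; ++b) yo[b] += wv * xi[b];
      }
  return y;
}

// [[Rcpp::export]]
List cpp_spconv_bw(const NumericVector& x, const NumericMatrix& w,
                   const NumericVector& gy, bool has_bias) {
  int B, D, C, T;
  get_dims4(x, B, D, C, T);
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericMatrix gw(D, C);
  NumericVector gb(has_bias ? D : 0);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* gxp = gx.begin();
  for (int t = 0; t < T; ++t) {
    for (int d = 0; d < D; ++d) {
      const double* go = gp + (R_xlen_t)B * (d + (R_xlen_t)D * t);
      if (has_bias) {
        double s = 0.0;
        for (int b = 0; b < B; ++b) s += go[b];
        gb[d] += s;
      }
      for (int c = 0; c < C; ++c) {
        const double wv = w(d, c);
        const double* xi = xp + (R_xlen_t)B * (d + (R_xlen_t)D * (c + (R_xlen_t)C * t));
        double* gxi = gxp + (R_xlen_t)B * (d + (R_xlen_t)D * (c + (R_xlen_t)C * t));
        double s = 0.0;
        for (int b = 0; b < B; ++b) {
          s += go[b] * xi[b];
          gxi[b] += wv * go[b];
        }
        gw(d, c) += s;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Fused single-layer LSTM over T steps with zero initial state.
// x: (B, Cin, T); wx: (Cin, 4H); wh: (H, 4H); b: (4H). Gate order i, f, g, o
// (activated gates are cached for the backward pass).
// [[Rcpp::export]]
List cpp_lstm_fw(const NumericVector& x, const arma::mat& wx,
                 const arma::mat& wh, const arma::rowvec& b) {
  int B, Cin, C1, T;
  {
    IntegerVector dm = x.attr("dim");
    if (dm.size() != 3) stop("LSTM input must be (B, Cin, T)");
    B = dm[0]; Cin = dm[1]; T = dm[2]; C1 = 0; (void)C1;
  }
  const int H4 = wx.n_cols;
  const int H = H4 / 4;
  if ((int)wx.n_rows != Cin || (int)wh.n_rows != H || (int)wh.n_cols != H4)
    stop("inconsistent LSTM weight shapes");
  NumericVector y(static_cast<R_xlen_t>(B) * H * T);
  y.attr("dim") = IntegerVector::create(B, H, T);
  NumericVector gates(static_cast<R_xlen_t>(B) * H4 * T);
  gates.attr("dim") = IntegerVector::create(B, H4, T);
  NumericVector cseq(static_cast<R_xlen_t>(B) * H * T);
  cseq.attr("dim") = IntegerVector::create(B, H, T);
  arma::mat h(B, H, arma::fill::zeros), cprev(B, H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    const arma::mat Xt(const_cast<double*>(x.begin()) + (R_xlen_t)B * Cin * t,
                       B, Cin, false, true);
    arma::mat G = Xt * wx + h * wh;
    G.each_row() += b;
    arma::mat i = 1.0 / (1.0 + arma::exp(-G.cols(0, H - 1)));
    arma::mat f = 1.0 / (1.0 + arma::exp(-G.cols(H, 2 * H - 1)));
    arma::mat g = arma::tanh(G.cols(2 * H, 3 * H - 1));
    arma::mat o = 1.0 / (1.0 + arma::exp(-G.cols(3 * H, 4 * H - 1)));
    arma::mat cc = f % cprev + i % g;
    h = o % arma::tanh(cc);
    double* gt = gates.begin() + (R_xlen_t)B * H4 * t;
    std::memcpy(gt, i.memptr(), sizeof(double) * B * H);
    std::memcpy(gt + (R_xlen_t)B * H, f.memptr(), sizeof(double) * B * H);
    std::memcpy(gt + (R_xlen_t)B * 2 * H, g.memptr(), sizeof(double) * B * H);
    std::memcpy(gt + (R_xlen_t)B * 3 * H, o.memptr(), sizeof(double) * B * H);
    std::memcpy(cseq.begin() + (R_xlen_t)B * H * t, cc.memptr(), sizeof(double) * B * H);
    std::memcpy(y.begin() + (R_xlen_t)B * H * t, h.memptr(), sizeof(double) * B * H);
    cprev = cc;
  }
  return List::create(_["y"] = y, _["gates"] = gates, _["c"] = cseq);
}

// [[Rcpp::export]]
List cpp_lstm_bw(const NumericVector& x, const arma::mat& wx, const arma::mat& wh,
                 const NumericVector& gates, const NumericVector& cseq,
                 const NumericVector& y, const NumericVector& gy) {
  IntegerVector dm = x.attr("dim");
  const int B = dm[0], Cin = dm[1], T = dm[2];
  const int H4 = wx.n_cols, H = H4 / 4;
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  arma::mat gwx(Cin, H4, arma::fill::zeros), gwh(H, H4, arma::fill::zeros);
  arma::rowvec gb(H4, arma::fill::zeros);
  arma::mat dh_next(B, H, arma::fill::zeros), dc(B, H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const double* gt = gates.begin() + (R_xlen_t)B * H4 * t;
    const arma::mat i(const_cast<double*>(gt), B, H, false, true);
    const arma::mat f(const_cast<double*>(gt + (R_xlen_t)B * H), B, H, false, true);
    const arma::mat g(const_cast<double*>(gt + (R_xlen_t)B * 2 * H), B, H, false, true);
    const arma::mat o(const_cast<double*>(gt + (R_xlen_t)B * 3 * H), B, H, false, true);
    const arma::mat cc(const_cast<double*>(cseq.begin() + (R_xlen_t)B * H * t), B, H, false, true);
    arma::mat dh(const_cast<double*>(gy.begin()) + (R_xlen_t)B * H * t, B, H, false, true);
    arma::mat dht = dh + dh_next;
    arma::mat tc = arma::tanh(cc);
    arma::mat dcc = dc + dht % o % (1.0 - tc % tc);
    arma::mat cprev(B, H, arma::fill::zeros);
    if (t > 0)
      cprev = arma::mat(const_cast<double*>(cseq.begin()) + (R_xlen_t)B * H * (t - 1),
                        B, H, false, true);
    arma::mat dG(B, H4);
    dG.cols(0, H - 1) = (dcc % g) % i % (1.0 - i);
    dG.cols(H, 2 * H - 1) = (dcc % cprev) % f % (1.0 - f);
    dG.cols(2 * H, 3 * H - 1) = (dcc % i) % (1.0 - g % g);
    dG.cols(3 * H, 4 * H - 1) = (dht % tc) % o % (1.0 - o);
    dc = dcc % f;
    const arma::mat Xt(const_cast<double*>(x.begin()) + (R_xlen_t)B * Cin * t,
                       B, Cin, false, true);
    gwx += Xt.t() * dG;
    if (t > 0) {
      const arma::mat Hprev(const_cast<double*>(y.begin()) + (R_xlen_t)B * H * (t - 1),
                            B, H, false, true);
      gwh += Hprev.t() * dG;
      dh_next = dG * wh.t();
    } else {
      dh_next.zeros();
    }
    gb += arma::sum(dG, 0);
    arma::mat gXt = dG * wx.t();
    std::memcpy(gx.begin() + (R_xlen_t)B * Cin * t, gXt.memptr(), sizeof(double) * B * Cin);
  }
  return List::create(_["gx"] = gx, _["gwx"] = wrap(gwx), _["gwh"] = wrap(gwh),
                      _["gb"] = wrap(gb));
}

// Exact GELU x * Phi(x) and its derivative.
// [[Rcpp::export]]
NumericVector cpp_gelu_fw(const NumericVector& x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double s = M_SQRT1_2;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = 0.5 * x[i] * (1.0 + std::erf(x[i] * s));
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_gelu_bw(const NumericVector& x, const NumericVector& gy) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  const double s = M_SQRT1_2;
  const double inv_sqrt_2pi = 0.3989422804014327;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double phi = 0.5 * (1.0 + std::erf(x[i] * s));
    const double dens = inv_sqrt_2pi * std::exp(-0.5 * x[i] * x[i]);
    gx[i] = gy[i] * (phi + x[i] * dens);
  }
  return gx;
}
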