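// Compiled hot paths: the residual dilated LSTM recurrence (forward and
// backward-through-time) and the per-sample multi-head mutual attention.
// Pure-R reference implementations of both kernels live in the package and
// the test suite checks exact agreement.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// x: [B x Din x L]; Wall [4H x Din], Rall [4H x H], ball [4H]
// returns h plus the gate caches needed for BPTT
// [[Rcpp::export]]
Rcpp::List rdlstm_fwd_cpp(const arma::cube& x, const arma::mat& Wall,
                          const arma::mat& Rall, const arma::vec& ball,
                          int dilation, bool shortcut) {
  const uword B = x.n_rows, Din = x.n_cols, L = x.n_slices;
  const uword H = Rall.n_cols;
  // Xm rows are (b, t)-major
  mat Xm(B * L, Din);
  for (uword t = 0; t < L; ++t)
    for (uword c = 0; c < Din; ++c)
      for (uword b = 0; b < B; ++b)
        Xm(t * B + b, c) = x(b, c, t);
  mat Ain = Xm * Wall.t();
  Ain.each_row() += ball.t();
  mat tRall = Rall.t();
  cube hs(B, H, L), cs(B, H, L), zs(B, H, L), is(B, H, L),
       fs(B, H, L), os(B, H, L), tcs(B, H, L);
  const int dd = dilation;
  for (uword t = 0; t < L; ++t) {
    mat A = Ain.rows(t * B, t * B + B - 1);
    mat cd(B, H, fill::zeros);
    if ((int)t >= dd) {
      A += hs.slice(t - dd) * tRall;
      cd = cs.slice(t - dd);
    }
    mat z = tanh(A.cols(0, H - 1));
    mat i = sigmoid(A.cols(H, 2 * H - 1));
    mat f = sigmoid(A.cols(2 * H, 3 * H - 1));
    mat o = sigmoid(A.cols(3 * H, 4 * H - 1));
    mat cc = f % cd + i % z;
    mat tc = tanh(cc);
    mat ht;
    if (shortcut) {
      ht = o % (tc + Xm.rows(t * B, t * B + B - 1));
    } else {
      ht = o % tc;
    }
    hs.slice(t) = ht; cs.slice(t) = cc;
    zs.slice(t) = z; is.slice(t) = i; fs.slice(t) = f; os.slice(t) = o;
    tcs.slice(t) = tc;
  }
  // back to [B x H x L]
  cube h(B, H, L);
  for (uword t = 0; t < L; ++t) h.slice(t) = hs.slice(t);
  return Rcpp::List::create(
      Rcpp::Named("h") = h, Rcpp::Named("c") = cs, Rcpp::Named("z") = zs,
      Rcpp::Named("i") = is, Rcpp::Named("f") = fs, Rcpp::Named("o") = os,
      Rcpp::Named("tc") = tcs, Rcpp::Named("Xm") = Xm);
}

// [[Rcpp::export]]
Rcpp::List rdlstm_bwd_cpp(const arma::cube& gy, const arma::mat& Xm,
                          const arma::mat& Wall, const arma::mat& Rall,
                          const arma::cube& hs, const arma::cube& cs,
                          const arma::cube& zs, const arma::cube& is,
                          const arma::cube& fs, const arma::cube& os,
                          const arma::cube& tcs,
                          int dilation, bool shortcut) {
  const uword B = gy.n_rows, H = gy.n_cols, L = gy.n_slices;
  const uword Din = Wall.n_cols;
  const int dd = dilation;
  cube GhAcc(B, H, L, fill::zeros), GcAcc(B, H, L, fill::zeros);
  mat GA(B * L, 4 * H);
  mat gR_all(4 * H, H, fill::zeros);
  mat gx_short;
  if (shortcut) gx_short.zeros(B * L, Din);
  for (int t = (int)L - 1; t >= 0; --t) {
    mat gh = gy.slice(t) + GhAcc.slice(t);
    mat gc = GcAcc.slice(t);
    const mat& o = os.slice(t); const mat& tc = tcs.slice(t);
    const mat& z = zs.slice(t); const mat& i = is.slice(t);
    const mat& f = fs.slice(t);
    mat cd(B, H, fill::zeros);
    if (t >= dd) cd = cs.slice(t - dd);
    mat go;
    if (shortcut) {
      go = gh % (tc + Xm.rows(t * B, t * B + B - 1));
      gx_short.rows(t * B, t * B + B - 1) = gh % o;
    } else {
      go = gh % tc;
    }
    gc += gh % o % (1.0 - tc % tc);
    mat ga(B, 4 * H);
    ga.cols(0, H - 1)         = gc % i % (1.0 - z % z);
    ga.cols(H, 2 * H - 1)     = gc % z % i % (1.0 - i);
    ga.cols(2 * H, 3 * H - 1) = gc % cd % f % (1.0 - f);
    ga.cols(3 * H, 4 * H - 1) = go % o % (1.0 - o);
    GA.rows(t * B, t * B + B - 1) = ga;
    if (t >= dd) {
      gR_all += ga.t() * hs.slice(t - dd);
      GhAcc.slice(t - dd) += ga * Rall;
      GcAcc.slice(t - dd) += gc % f;
    }
  }
  mat gW_all = GA.t() * Xm;
  vec gb_all = sum(GA, 0).t();
  mat gXm = GA * Wall;
  if (shortcut) gXm += gx_short;
  cube gx(B, Din, L);
  for (uword t = 0; t < L; ++t)
    for (uword c = 0; c < Din; ++c)
      for (uword b = 0; b < B; ++b)
        gx(b, c, t) = gXm(t * B + b, c);
  return Rcpp::List::create(
      Rcpp::Named("gW_all") = gW_all, Rcpp::Named("gR_all") = gR_all,
      Rcpp::Named("gb_all") = gb_all, Rcpp::Named("gx") = gx);
}

static void softmax_rows_inplace(mat& A) {
  for (uword i = 0; i < A.n_rows; ++i) {
    double m = A.row(i).max();
    rowvec e = exp(A.row(i) - m);
    A.row(i) = e / accu(e);
  }
}

// Q, K, C: [B x F x L]; per sample/head: softmax_rows(Qs' Ks / S), rows are
// time positions, aggregated over the columns of Cs.
// [[Rcpp::export]]
arma::cube mh_attn_fwd_cpp(const arma::cube& Q, const arma::cube& K,
                           const arma::cube& C, double S, int heads) {
  const uword B = Q.n_rows, F = Q.n_cols, L = Q.n_slices;
  const uword Fh = F / heads;
  cube O(B, F, L);
  mat Qs(Fh, L), Ks(Fh, L), Cs(Fh, L);
  for (uword b = 0; b < B; ++b) {
    for (int h = 0; h < heads; ++h) {
      const uword f0 = h * Fh;
      for (uword l = 0; l < L; ++l)
        for (uword f = 0; f < Fh; ++f) {
          Qs(f, l) = Q(b, f0 + f, l);
          Ks(f, l) = K(b, f0 + f, l);
          Cs(f, l) = C(b, f0 + f, l);
        }
      mat A = Qs.t() * Ks / S;
      softmax_rows_inplace(A);
      mat Ob = Cs * A.t();
      for (uword l = 0; l < L; ++l)
        for (uword f = 0; f < Fh; ++f) O(b, f0 + f, l) = Ob(f, l);
    }
  }
  return O;
}

// [[Rcpp::export]]
Rcpp::List mh_attn_bwd_cpp(const arma::cube& gO, const arma::cube& Q,
                           const arma::cube& K, const arma::cube& C,
                           double S, int heads) {
  const uword B = Q.n_rows, F = Q.n_cols, L = Q.n_slices;
  const uword Fh = F / heads;
  cube gQ(B, F, L, fill::zeros), gK(B, F, L, fill::zeros),
       gC(B, F, L, fill::zeros);
  mat Qs(Fh, L), Ks(Fh, L), Cs(Fh, L), G(Fh, L);
  for (uword b = 0; b < B; ++b) {
    for (int h = 0; h < heads; ++h) {
      const uword f0 = h * Fh;
      for (uword l = 0; l < L; ++l)
        for (uword f = 0; f < Fh; ++f) {
          Qs(f, l) = Q(b, f0 + f, l);
          Ks(f, l) = K(b, f0 + f, l);
          Cs(f, l) = C(b, f0 + f, l);
          G(f, l) = gO(b, f0 + f, l);
        }
      mat A = Qs.t() * Ks / S;
      softmax_rows_inplace(A);
      mat gCb = G * A;
      mat gA = G.t() * Cs;
      vec rs = sum(gA % A, 1);
      mat gSc = A % (gA.each_col() - rs);
      mat gQb = Ks * gSc.t() / S;
      mat gKb = Qs * gSc / S;
      for (uword l = 0; l < L; ++l)
        for (uword f = 0; f < Fh; ++f) {
          gQ(b, f0 + f, l) = gQb(f, l);
          gK(b, f0 + f, l) = gKb(f, l);
          gC(b, f0 + f, l) = gCb(f, l);
        }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gQ") = gQ, Rcpp::Named("gK") = gK,
                            Rcpp::Named("gC") = gC);
}

// 1D cross-correlation over [B x Ci x L] with kernel [Co x Ci x K].
// padding: 0 = valid, 1 = same (zero-padded, odd K).
// [[Rcpp::export]]
arma::cube conv1d_fwd_cpp(const arma::cube& x, const arma::cube& w,
                          const arma::vec& b, int same) {
  const uword B = x.n_rows, Ci = x.n_cols, L = x.n_slices;
  const uword Co = w.n_rows, K = w.n_slices;
  const int P = same ? (int)(K - 1) / 2 : 0;
  const int Lout = same ? (int)L : (int)L - (int)K + 1;
  // unfold to [Ci*K x B*Lout], time-major columns per sample
  mat Xu(Ci * K, (uword)B * Lout, fill::zeros);
  for (uword k = 0; k < K; ++k)
    for (int t = 0; t < Lout; ++t) {
      int src = t + (int)k - P;
      if (src < 0 || src >= (int)L) continue;
      for (uword c = 0; c < Ci; ++c)
        for (uword bb = 0; bb < B; ++bb)
          Xu(k * Ci + c, (uword)t * B + bb) = x(bb, c, src);
    }
  mat Wu(Co, Ci * K);
  for (uword k = 0; k < K; ++k)
    for (uword c = 0; c < Ci; ++c)
      Wu.col(k * Ci + c) = w.slice(k).col(c);
  mat Y = Wu * Xu;
  Y.each_col() += b;
  cube y(B, Co, (uword)Lout);
  for (int t = 0; t < Lout; ++t)
    for (uword c = 0; c < Co; ++c)
      for (uword bb = 0; bb < B; ++bb)
        y(bb, c, t) = Y(c, (uword)t * B + bb);
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::cube& gy, const arma::cube& x,
                          const arma::cube& w, int same) {
  const uword B = x.n_rows, Ci = x.n_cols, L = x.n_slices;
  const uword Co = w.n_rows, K = w.n_slices;
  const int P = same ? (int)(K - 1) / 2 : 0;
  const int Lout = (int)gy.n_slices;
  mat Xu(Ci * K, (uword)B * Lout, fill::zeros);
  for (uword k = 0; k < K; ++k)
    for (int t = 0; t < Lout; ++t) {
      int src = t + (int)k - P;
      if (src < 0 || src >= (int)L) continue;
      for (uword c = 0; c < Ci; ++c)
        for (uword bb = 0; bb < B; ++bb)
          Xu(k * Ci + c, (uword)t * B + bb) = x(bb, c, src);
    }
  mat Gm(Co, (uword)B * Lout);
  for (int t = 0; t < Lout; ++t)
    for (uword c = 0; c < Co; ++c)
      for (uword bb = 0; bb < B; ++bb)
        Gm(c, (uword)t * B + bb) = gy(bb, c, t);
  vec gb = sum(Gm, 1);
  mat gWu = Gm * Xu.t();
  cube gw(Co, Ci, K);
  for (uword k = 0; k < K; ++k)
    for (uword c = 0; c < Ci; ++c)
      gw.slice(k).col(c) = gWu.col(k * Ci + c);
  mat Wu(Co, Ci * K);
  for (uword k = 0; k < K; ++k)
    for (uword c = 0; c < Ci; ++c)
      Wu.col(k * Ci + c) = w.slice(k).col(c);
  mat gXu = Wu.t() * Gm;
  cube gx(B, Ci, L, fill::zeros);
  for (uword k = 0; k < K; ++k)
    for (int t = 0; t < Lout; ++t) {
      int src = t + (int)k - P;
      if (src < 0 || src >= (int)L) continue;
      for (uword c = 0; c < Ci; ++c)
        for (uword bb = 0; bb < B; ++bb)
          gx(bb, c, src) += gXu(k * Ci + c, (uword)t * B + bb);
    }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// non-overlapping max pool over time; returns pooled values and argmax
// offsets (1-based within each window)
// [[Rcpp::export]]
Rcpp::List maxpool_fwd_cpp(const arma::cube& x, int window) {
  const uword B = x.n_rows, C = x.n_cols, L = x.n_slices;
  const uword Lout = L / window;
  arma::cube y(B, C, Lout);
  arma::icube idx(B, C, Lout);
  for (uword t = 0; t < Lout; ++t)
    for (uword c = 0; c < C; ++c)
      for (uword b = 0; b < B; ++b) {
        double best = x(b, c, t * window);
        int bi = 1;
        for (int s = 1; s < window; ++s) {
          double v = x(b, c, t * window + s);
          if (v > best) { best = v; bi = s + 1; }
        }
        y(b, c, t) = best;
        idx(b, c, t) = bi;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bwd_cpp(const arma::cube& gy, const arma::icube& idx,
                           int window, int L) {
  const uword B = gy.n_rows, C = gy.n_cols, Lout = gy.n_slices;
  arma::cube gx(B, C, (uword)L, fill::zeros);
  for (uword t = 0; t < Lout; ++t)
    for (uword c = 0; c < C; ++c)
      for (uword b = 0; b < B; ++b)
        gx(b, c, t * window + idx(b, c, t) - 1) += gy(b, c, t);
  return gx;
}
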