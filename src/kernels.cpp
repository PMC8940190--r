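// Compiled kernels for the sequential inner loops: time-varying formant
// resonators for the synthesizer, and LSTM/GRU forward + backward-through-time
// passes for the recurrent classifiers. Everything batch-level (minibatching,
// Adam, loss) stays in R; these functions are deterministic and RNG-free.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Exponentially scaled modified Bessel functions I0(x)e^-x and I1(x)e^-x via
// the classical Abramowitz & Stegun polynomial approximations (9.8.1-9.8.4,
// absolute error < 2e-7); the VAD evaluates these for every bin of every
// frame, where calling R's besselI dominates runtime.
static inline double i0e(double x) {
  if (x < 3.75) {
    const double t = (x / 3.75) * (x / 3.75);
    const double p = 1.0 + t * (3.5156229 + t * (3.0899424 + t * (1.2067492 +
      t * (0.2659732 + t * (0.0360768 + t * 0.0045813)))));
    return p * std::exp(-x);
  }
  const double t = 3.75 / x;
  const double p = 0.39894228 + t * (0.01328592 + t * (0.00225319 +
    t * (-0.00157565 + t * (0.00916281 + t * (-0.02057706 + t * (0.02635537 +
    t * (-0.01647633 + t * 0.00392377)))))));
  return p / std::sqrt(x);
}

static inline double i1e(double x) {
  if (x < 3.75) {
    const double t = (x / 3.75) * (x / 3.75);
    const double p = x * (0.5 + t * (0.87890594 + t * (0.51498869 +
      t * (0.15084934 + t * (0.02658733 + t * (0.00301532 + t * 0.00032411))))));
    return p * std::exp(-x);
  }
  const double t = 3.75 / x;
  const double p = 0.39894228 + t * (-0.03988024 + t * (-0.00362018 +
    t * (0.00163801 + t * (-0.01031555 + t * (0.02282967 + t * (-0.02895312 +
    t * (0.01787654 + t * (-0.00420059))))))));
  return p / std::sqrt(x);
}

// MMSE short-time spectral-amplitude gain, vectorized over bins.
// G = (sqrt(pi)/2) (sqrt(nu)/gamma) e^{-nu/2} [(1+nu) I0(nu/2) + nu I1(nu/2)]
// with nu = gamma xi / (1 + xi); the scaled Bessel forms keep the large-SNR
// limit G -> xi/(1+xi) stable.
// [[Rcpp::export]]
arma::vec mmse_stsa_gain_cpp(const arma::vec& xi, const arma::vec& gamma) {
  const uword n = xi.n_elem;
  vec g(n);
  const double c = std::sqrt(datum::pi) / 2.0;
  for (uword i = 0; i < n; ++i) {
    const double ga = std::max(gamma(i), 1e-12);
    const double nu = std::max(ga * xi(i) / (1.0 + xi(i)), 1e-300);
    double v = c * (std::sqrt(nu) / ga) *
      ((1.0 + nu) * i0e(nu / 2.0) + nu * i1e(nu / 2.0));
    if (!std::isfinite(v)) v = 1.0;
    g(i) = std::min(v, 1e6);
  }
  return g;
}

// Cascade of unity-DC-gain two-pole resonators with per-sample center
// frequencies (Klatt-style: y[n] = A x[n] + B y[n-1] + C y[n-2],
// C = -r^2, B = 2 r cos(2 pi F / fs), A = 1 - B - C).
// [[Rcpp::export]]
arma::vec resonator_sweep_cpp(const arma::vec& x, const arma::mat& freqs,
                              const arma::vec& bws, double fs) {
  const uword n = x.n_elem, k = freqs.n_cols;
  if (freqs.n_rows != n) Rcpp::stop("freqs must have one row per sample");
  if (bws.n_elem != k) Rcpp::stop("one bandwidth per formant required");
  vec y = x;
  for (uword j = 0; j < k; ++j) {
    const double r = std::exp(-datum::pi * bws(j) / fs);
    const double C = -r * r;
    vec out(n);
    double y1 = 0.0, y2 = 0.0;
    for (uword i = 0; i < n; ++i) {
      const double B = 2.0 * r * std::cos(2.0 * datum::pi * freqs(i, j) / fs);
      const double A = 1.0 - B - C;
      const double v = A * y(i) + B * y1 + C * y2;
      out(i) = v;
      y2 = y1; y1 = v;
    }
    y = out;
  }
  return y;
}

// ---- LSTM ------------------------------------------------------------------
// X: T x D, Wx: D x 4H, Wh: H x 4H, b: 4H. Gate order [i, f, g, o].
// Returns H (T x H), C (T x H) and the post-activation gates for backprop.
// [[Rcpp::export]]
Rcpp::List lstm_seq_forward_cpp(const arma::mat& X, const arma::mat& Wx,
                                const arma::mat& Wh, const arma::rowvec& b) {
  const uword T = X.n_rows, H = Wh.n_rows;
  mat A = X * Wx;
  A.each_row() += b;
  mat Hs(T, H), Cs(T, H), I(T, H), F(T, H), G(T, H), O(T, H);
  rowvec h(H, fill::zeros), c(H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    rowvec a = A.row(t) + h * Wh;
    rowvec i = 1.0 / (1.0 + exp(-a.cols(0, H - 1)));
    rowvec f = 1.0 / (1.0 + exp(-a.cols(H, 2 * H - 1)));
    rowvec g = tanh(a.cols(2 * H, 3 * H - 1));
    rowvec o = 1.0 / (1.0 + exp(-a.cols(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    h = o % tanh(c);
    I.row(t) = i; F.row(t) = f; G.row(t) = g; O.row(t) = o;
    Cs.row(t) = c; Hs.row(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hs, Rcpp::Named("C") = Cs,
                            Rcpp::Named("I") = I, Rcpp::Named("F") = F,
                            Rcpp::Named("G") = G, Rcpp::Named("O") = O);
}

// [[Rcpp::export]]
Rcpp::List lstm_seq_backward_cpp(const arma::mat& X, const arma::mat& Wx,
                                 const arma::mat& Wh, const arma::mat& Hs,
                                 const arma::mat& Cs, const arma::mat& I,
                                 const arma::mat& F, const arma::mat& G,
                                 const arma::mat& O, const arma::mat& dH) {
  const uword T = X.n_rows, H = Wh.n_rows, D = X.n_cols;
  mat dWx(D, 4 * H, fill::zeros), dWh(Wh.n_rows, 4 * H, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dX(T, D, fill::zeros);
  rowvec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    rowvec dh = dH.row(tt) + dh_next;
    rowvec c = Cs.row(tt);
    rowvec c_prev = (tt == 0) ? rowvec(H, fill::zeros) : rowvec(Cs.row(tt - 1));
    rowvec h_prev = (tt == 0) ? rowvec(H, fill::zeros) : rowvec(Hs.row(tt - 1));
    rowvec i = I.row(tt), f = F.row(tt), g = G.row(tt), o = O.row(tt);
    rowvec tc = tanh(c);
    rowvec dao = dh % tc % o % (1.0 - o);
    rowvec dc = dh % o % (1.0 - tc % tc) + dc_next;
    rowvec dai = dc % g % i % (1.0 - i);
    rowvec daf = dc % c_prev % f % (1.0 - f);
    rowvec dag = dc % i % (1.0 - g % g);
    rowvec da(4 * H);
    da.cols(0, H - 1) = dai;
    da.cols(H, 2 * H - 1) = daf;
    da.cols(2 * H, 3 * H - 1) = dag;
    da.cols(3 * H, 4 * H - 1) = dao;
    dWx += X.row(tt).t() * da;
    dWh += h_prev.t() * da;
    db += da;
    dX.row(tt) = da * Wx.t();
    dh_next = da * Wh.t();
    dc_next = dc % f;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db);
}

// ---- GRU -------------------------------------------------------------------
// Gate order [z, r, n]; reset gate applied to the hidden-side contribution of
// the candidate (m = h_prev Whn + bhn; n = tanh(x Wxn + bxn + r .* m);
// h = (1 - z) .* n + z .* h_prev).
// [[Rcpp::export]]
Rcpp::List gru_seq_forward_cpp(const arma::mat& X, const arma::mat& Wx,
                               const arma::mat& Wh, const arma::rowvec& bx,
                               const arma::rowvec& bh) {
  const uword T = X.n_rows, H = Wh.n_rows;
  mat A = X * Wx;
  A.each_row() += bx;
  mat Hs(T, H), Z(T, H), R(T, H), N(T, H), M(T, H);
  rowvec h(H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    rowvec ah = h * Wh + bh;
    rowvec z = 1.0 / (1.0 + exp(-(A.row(t).cols(0, H - 1) + ah.cols(0, H - 1))));
    rowvec r = 1.0 / (1.0 + exp(-(A.row(t).cols(H, 2 * H - 1) + ah.cols(H, 2 * H - 1))));
    rowvec m = ah.cols(2 * H, 3 * H - 1);
    rowvec n = tanh(A.row(t).cols(2 * H, 3 * H - 1) + r % m);
    h = (1.0 - z) % n + z % h;
    Z.row(t) = z; R.row(t) = r; N.row(t) = n; M.row(t) = m; Hs.row(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hs, Rcpp::Named("Z") = Z,
                            Rcpp::Named("R") = R, Rcpp::Named("N") = N,
                            Rcpp::Named("M") = M);
}

// [[Rcpp::export]]
Rcpp::List gru_seq_backward_cpp(const arma::mat& X, const arma::mat& Wx,
                                const arma::mat& Wh, const arma::mat& Hs,
                                const arma::mat& Z, const arma::mat& R,
                                const arma::mat& N, const arma::mat& M,
                                const arma::mat& dH) {
  const uword T = X.n_rows, H = Wh.n_rows, D = X.n_cols;
  mat dWx(D, 3 * H, fill::zeros), dWh(H, 3 * H, fill::zeros);
  rowvec dbx(3 * H, fill::zeros), dbh(3 * H, fill::zeros);
  mat dX(T, D, fill::zeros);
  rowvec dh_next(H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    rowvec dh = dH.row(tt) + dh_next;
    rowvec h_prev = (tt == 0) ? rowvec(H, fill::zeros) : rowvec(Hs.row(tt - 1));
    rowvec z = Z.row(tt), r = R.row(tt), n = N.row(tt), m = M.row(tt);
    rowvec dz = dh % (h_prev - n);
    rowvec daz = dz % z % (1.0 - z);
    rowvec dn = dh % (1.0 - z);
    rowvec dan = dn % (1.0 - n % n);
    rowvec dr = dan % m;
    rowvec dar = dr % r % (1.0 - r);
    rowvec dm = dan % r;
    rowvec dh_prev = dh % z;
    rowvec da(3 * H);
    da.cols(0, H - 1) = daz;
    da.cols(H, 2 * H - 1) = dar;
    da.cols(2 * H, 3 * H - 1) = dan;
    dWx += X.row(tt).t() * da;
    dbx += da;
    // hidden-side grads: z and r flow through ah directly, n through m
    rowvec dah(3 * H);
    dah.cols(0, H - 1) = daz;
    dah.cols(H, 2 * H - 1) = dar;
    dah.cols(2 * H, 3 * H - 1) = dm;
    dWh += h_prev.t() * dah;
    dbh += dah;
    dh_prev += dah * Wh.t();
    dX.row(tt) = da * Wx.t();
    dh_next = dh_prev;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh, Rcpp::Named("dbx") = dbx,
                            Rcpp::Named("dbh") = dbh);
}
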