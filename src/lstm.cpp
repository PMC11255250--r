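// LSTM cell recursion (i,f,o = sigmoid gates; g = tanh candidate;
// c_t = f*c_{t-1} + i*g; h_t = tanh(c_t)*o) with full backpropagation
// through time. The time loop lives here because an R-level loop over
// timesteps dominates training cost; everything around the LSTM stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Gate column layout in the 4H-wide weight matrices: [i | f | o | g]

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::rowvec& b) {
  const uword L = X.n_rows;
  const uword H = Wh.n_rows;
  mat h(L, H, fill::zeros), c(L, H, fill::zeros);
  mat gi(L, H), gf(L, H), go(L, H), gg(L, H), tc(L, H);
  rowvec hprev(H, fill::zeros), cprev(H, fill::zeros);
  for (uword t = 0; t < L; ++t) {
    rowvec z = X.row(t) * Wx + hprev * Wh + b;
    rowvec i = 1.0 / (1.0 + exp(-z.cols(0, H - 1)));
    rowvec f = 1.0 / (1.0 + exp(-z.cols(H, 2 * H - 1)));
    rowvec o = 1.0 / (1.0 + exp(-z.cols(2 * H, 3 * H - 1)));
    rowvec g = tanh(z.cols(3 * H, 4 * H - 1));
    rowvec ct = f % cprev + i % g;
    rowvec tct = tanh(ct);
    gi.row(t) = i; gf.row(t) = f; go.row(t) = o; gg.row(t) = g;
    c.row(t) = ct; tc.row(t) = tct;
    h.row(t) = tct % o;
    hprev = h.row(t); cprev = ct;
  }
  return Rcpp::List::create(
      Rcpp::Named("h") = h, Rcpp::Named("c") = c, Rcpp::Named("i") = gi,
      Rcpp::Named("f") = gf, Rcpp::Named("o") = go, Rcpp::Named("g") = gg,
      Rcpp::Named("tanh_c") = tc);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& X, const arma::mat& Wx,
                             const arma::mat& Wh, const arma::mat& h,
                             const arma::mat& c, const arma::mat& gi,
                             const arma::mat& gf, const arma::mat& go,
                             const arma::mat& gg, const arma::mat& tc,
                             const arma::mat& dH) {
  const uword L = X.n_rows;
  const uword H = Wh.n_rows;
  mat dX(L, X.n_cols, fill::zeros);
  mat dWx(Wx.n_rows, Wx.n_cols, fill::zeros);
  mat dWh(Wh.n_rows, Wh.n_cols, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  rowvec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (uword ti = L; ti-- > 0;) {
    rowvec dh = dH.row(ti) + dh_next;
    rowvec o = go.row(ti), i = gi.row(ti), f = gf.row(ti), g = gg.row(ti);
    rowvec tct = tc.row(ti);
    rowvec do_ = dh % tct;
    rowvec dc = dh % o % (1.0 - tct % tct) + dc_next;
    rowvec cprev = (ti == 0) ? rowvec(H, fill::zeros) : rowvec(c.row(ti - 1));
    rowvec di = dc % g;
    rowvec df = dc % cprev;
    rowvec dg = dc % i;
    dc_next = dc % f;
    rowvec dz(4 * H);
    dz.cols(0, H - 1) = di % i % (1.0 - i);
    dz.cols(H, 2 * H - 1) = df % f % (1.0 - f);
    dz.cols(2 * H, 3 * H - 1) = do_ % o % (1.0 - o);
    dz.cols(3 * H, 4 * H - 1) = dg % (1.0 - g % g);
    dX.row(ti) = dz * Wx.t();
    dWx += X.row(ti).t() * dz;
    rowvec hprev = (ti == 0) ? rowvec(H, fill::zeros) : rowvec(h.row(ti - 1));
    dWh += hprev.t() * dz;
    db += dz;
    dh_next = dz * Wh.t();
  }
  return Rcpp::List::create(
      Rcpp::Named("dX") = dX, Rcpp::Named("dWx") = dWx,
      Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db);
}
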