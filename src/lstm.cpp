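// LSTM recurrence forward/backward. The input projection (x_t W + b) is a
// single BLAS matmul done in R; only the sequential recurrent part lives
// here. Gate layout along columns: [input, forget, output, cell-update].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Xp: n x 4h precomputed input projections; U: h x 4h recurrent weights.
// Returns hidden states H (n x h) plus the caches backward needs.
// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& Xp, const arma::mat& U) {
  const uword n = Xp.n_rows;
  const uword h = U.n_rows;
  mat H(n, h), C(n, h), I(n, h), F(n, h), O(n, h), G(n, h);
  rowvec hprev(h, fill::zeros), cprev(h, fill::zeros);
  for (uword t = 0; t < n; ++t) {
    rowvec g = Xp.row(t) + hprev * U;
    rowvec i = 1.0 / (1.0 + exp(-g.cols(0, h - 1)));
    rowvec f = 1.0 / (1.0 + exp(-g.cols(h, 2 * h - 1)));
    rowvec o = 1.0 / (1.0 + exp(-g.cols(2 * h, 3 * h - 1)));
    rowvec u = tanh(g.cols(3 * h, 4 * h - 1));
    rowvec c = f % cprev + i % u;
    rowvec hh = o % tanh(c);
    I.row(t) = i; F.row(t) = f; O.row(t) = o; G.row(t) = u;
    C.row(t) = c; H.row(t) = hh;
    hprev = hh; cprev = c;
  }
  return Rcpp::List::create(
      Rcpp::Named("H") = H, Rcpp::Named("C") = C, Rcpp::Named("I") = I,
      Rcpp::Named("F") = F, Rcpp::Named("O") = O, Rcpp::Named("G") = G);
}

// Backward through time. dH: n x h upstream gradient on the hidden states.
// Returns dXp (n x 4h) and dU (h x 4h).
// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& dH, const arma::mat& U, const arma::mat& H,
                             const arma::mat& C, const arma::mat& I, const arma::mat& F,
                             const arma::mat& O, const arma::mat& G) {
  const uword n = dH.n_rows;
  const uword h = U.n_rows;
  mat dXp(n, 4 * h, fill::zeros);
  mat dU(h, 4 * h, fill::zeros);
  rowvec dh_next(h, fill::zeros), dc_next(h, fill::zeros);
  for (uword t = n; t-- > 0;) {
    rowvec dh = dH.row(t) + dh_next;
    rowvec tc = tanh(C.row(t));
    rowvec dodo = dh % tc;
    rowvec dc = dh % O.row(t) % (1.0 - tc % tc) + dc_next;
    rowvec cprev = (t == 0) ? rowvec(h, fill::zeros) : C.row(t - 1);
    rowvec di = dc % G.row(t);
    rowvec df = dc % cprev;
    rowvec dg = dc % I.row(t);
    dc_next = dc % F.row(t);
    rowvec dpre(4 * h);
    dpre.cols(0, h - 1) = di % I.row(t) % (1.0 - I.row(t));
    dpre.cols(h, 2 * h - 1) = df % F.row(t) % (1.0 - F.row(t));
    dpre.cols(2 * h, 3 * h - 1) = dodo % O.row(t) % (1.0 - O.row(t));
    dpre.cols(3 * h, 4 * h - 1) = dg % (1.0 - G.row(t) % G.row(t));
    dXp.row(t) = dpre;
    rowvec hprev = (t == 0) ? rowvec(h, fill::zeros) : H.row(t - 1);
    dU += hprev.t() * dpre;
    dh_next = dpre * U.t();
  }
  return Rcpp::List::create(Rcpp::Named("dXp") = dXp,
                            Rcpp::Named("dU") = dU);
}
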