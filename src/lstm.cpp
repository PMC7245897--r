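// Unidirectional LSTM forward pass and backpropagation-through-time.
// One sentence at a time: inputs are d x T, hidden states S x T.
// Gate layout in the stacked weight matrices is [input; forget; output; cell]
// blocks of S rows each. Initial h and c are zero.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::vec& b) {
  const uword T = X.n_cols;
  const uword S = Wh.n_cols;
  mat H(S, T), C(S, T), I(S, T), F(S, T), O(S, T), G(S, T), Ctan(S, T);
  vec hprev(S, fill::zeros), cprev(S, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    vec z = Wx * X.col(t) + Wh * hprev + b;
    vec i = 1.0 / (1.0 + exp(-z.subvec(0, S - 1)));
    vec f = 1.0 / (1.0 + exp(-z.subvec(S, 2 * S - 1)));
    vec o = 1.0 / (1.0 + exp(-z.subvec(2 * S, 3 * S - 1)));
    vec g = tanh(z.subvec(3 * S, 4 * S - 1));
    vec c = f % cprev + i % g;
    vec ct = tanh(c);
    vec h = o % ct;
    I.col(t) = i; F.col(t) = f; O.col(t) = o; G.col(t) = g;
    C.col(t) = c; Ctan.col(t) = ct; H.col(t) = h;
    hprev = h; cprev = c;
  }
  return Rcpp::List::create(
      Rcpp::Named("H") = H, Rcpp::Named("C") = C, Rcpp::Named("I") = I,
      Rcpp::Named("F") = F, Rcpp::Named("O") = O, Rcpp::Named("G") = G,
      Rcpp::Named("Ctan") = Ctan);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& dH, const arma::mat& X,
                             const arma::mat& Wx, const arma::mat& Wh,
                             const Rcpp::List& cache) {
  const mat H = cache["H"], C = cache["C"], I = cache["I"], F = cache["F"],
            O = cache["O"], G = cache["G"], Ctan = cache["Ctan"];
  const uword T = X.n_cols;
  const uword S = Wh.n_cols;
  mat dWx(size(Wx), fill::zeros), dWh(size(Wh), fill::zeros);
  vec db(4 * S, fill::zeros);
  mat dX(size(X), fill::zeros);
  vec dh_next(S, fill::zeros), dc_next(S, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    vec dh = dH.col(tt) + dh_next;
    vec i = I.col(tt), f = F.col(tt), o = O.col(tt), g = G.col(tt),
        ct = Ctan.col(tt);
    vec dc = dh % o % (1.0 - ct % ct) + dc_next;
    vec do_ = dh % ct;
    vec di = dc % g;
    vec dg = dc % i;
    vec cprev = (tt == 0) ? vec(S, fill::zeros) : vec(C.col(tt - 1));
    vec df = dc % cprev;
    vec dz(4 * S);
    dz.subvec(0, S - 1) = di % i % (1.0 - i);
    dz.subvec(S, 2 * S - 1) = df % f % (1.0 - f);
    dz.subvec(2 * S, 3 * S - 1) = do_ % o % (1.0 - o);
    dz.subvec(3 * S, 4 * S - 1) = dg % (1.0 - g % g);
    vec hprev = (tt == 0) ? vec(S, fill::zeros) : vec(H.col(tt - 1));
    dWx += dz * X.col(tt).t();
    dWh += dz * hprev.t();
    db += dz;
    dX.col(tt) = Wx.t() * dz;
    dh_next = Wh.t() * dz;
    dc_next = dc % f;
  }
  return Rcpp::List::create(Rcpp::Named("dWx") = dWx, Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("db") = db, Rcpp::Named("dX") = dX);
}
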