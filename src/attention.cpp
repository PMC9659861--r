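// Batched scaled-dot-product attention kernel.
//
// Rows of Q are grouped into G = nrow(Q)/nq independent attention problems
// (samples, windows, or sample x head groups); K and V are grouped the same
// way with nk rows per group.  `bias` (nq x nk) is shared across groups (the
// relative-position-bias matrix of one window); `mask` is an additive
// per-group term of size (G*nq) x nk (shifted-window masking), or empty.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List attn_forward_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                      int nq, int nk, double scale,
                      const arma::mat& bias, const arma::mat& mask) {
  const int G = Q.n_rows / nq;
  const int d = Q.n_cols;
  const bool has_bias = bias.n_elem > 0;
  const bool has_mask = mask.n_elem > 0;
  arma::mat out(Q.n_rows, V.n_cols);
  arma::mat P(Q.n_rows, nk);
  for (int g = 0; g < G; ++g) {
    const arma::mat Qg = Q.rows(g * nq, (g + 1) * nq - 1);
    const arma::mat Kg = K.rows(g * nk, (g + 1) * nk - 1);
    arma::mat S = (Qg * Kg.t()) * scale;
    if (has_bias) S += bias;
    if (has_mask) S += mask.rows(g * nq, (g + 1) * nq - 1);
    // row-wise stable softmax
    arma::vec m = arma::max(S, 1);
    S.each_col() -= m;
    S = arma::exp(S);
    arma::vec z = arma::sum(S, 1);
    S.each_col() /= z;
    P.rows(g * nq, (g + 1) * nq - 1) = S;
    out.rows(g * nq, (g + 1) * nq - 1) = S * V.rows(g * nk, (g + 1) * nk - 1);
  }
  (void)d;
  return List::create(_["out"] = out, _["probs"] = P);
}

// [[Rcpp::export]]
List attn_backward_cpp(const arma::mat& dOut, const arma::mat& P,
                       const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                       int nq, int nk, double scale, bool want_bias) {
  const int G = Q.n_rows / nq;
  arma::mat dQ(arma::size(Q), arma::fill::zeros);
  arma::mat dK(arma::size(K), arma::fill::zeros);
  arma::mat dV(arma::size(V), arma::fill::zeros);
  arma::mat dBias;
  if (want_bias) dBias.zeros(nq, nk);
  for (int g = 0; g < G; ++g) {
    const arma::mat Pg  = P.rows(g * nq, (g + 1) * nq - 1);
    const arma::mat dOg = dOut.rows(g * nq, (g + 1) * nq - 1);
    const arma::mat Vg  = V.rows(g * nk, (g + 1) * nk - 1);
    const arma::mat Kg  = K.rows(g * nk, (g + 1) * nk - 1);
    const arma::mat Qg  = Q.rows(g * nq, (g + 1) * nq - 1);
    dV.rows(g * nk, (g + 1) * nk - 1) = Pg.t() * dOg;
    arma::mat dP = dOg * Vg.t();
    // softmax Jacobian: dS = P .* (dP - rowsum(dP .* P))
    arma::vec r = arma::sum(dP % Pg, 1);
    arma::mat dS = Pg % (dP.each_col() - r);
    dQ.rows(g * nq, (g + 1) * nq - 1) = (dS * Kg) * scale;
    dK.rows(g * nk, (g + 1) * nk - 1) = (dS.t() * Qg) * scale;
    if (want_bias) dBias += dS;
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV, _["dBias"] = dBias);
}
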