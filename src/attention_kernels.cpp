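// Batched causal attention kernels. Row layout matches the R training
// engine: the flat state matrix has row (b-1)*T + t for sequence b,
// position t; heads are contiguous column blocks of width d/h.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// forward: returns concatenated head outputs Hf and the softmax weights
// (lower-triangular T x T per sequence/head, packed column-major)
// [[Rcpp::export(name = ".mg_attn_fwd_cpp")]]
Rcpp::List mg_attn_fwd(const arma::mat& Qf, const arma::mat& Kf,
                       const arma::mat& Vf, int B, int T, int h) {
  const int d = Qf.n_cols;
  const int dk = d / h;
  const double scale = 1.0 / std::sqrt((double)dk);
  mat Hf(B * T, d, fill::zeros);
  vec Abuf((size_t)B * h * T * T, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * T;
    for (int i = 0; i < h; ++i) {
      const int c0 = i * dk;
      mat Q = Qf.submat(r0, c0, r0 + T - 1, c0 + dk - 1);
      mat K = Kf.submat(r0, c0, r0 + T - 1, c0 + dk - 1);
      mat V = Vf.submat(r0, c0, r0 + T - 1, c0 + dk - 1);
      mat S = Q * K.t() * scale;
      mat A(T, T, fill::zeros);
      for (int t = 0; t < T; ++t) {
        rowvec s = S.row(t).cols(0, t);
        rowvec e = exp(s - s.max());
        A.row(t).cols(0, t) = e / accu(e);
      }
      Hf.submat(r0, c0, r0 + T - 1, c0 + dk - 1) = A * V;
      std::memcpy(Abuf.memptr() + (size_t)(b * h + i) * T * T, A.memptr(),
                  sizeof(double) * (size_t)T * T);
    }
  }
  return Rcpp::List::create(Rcpp::Named("Hf") = Hf,
                            Rcpp::Named("A") = Abuf);
}

// backward: gradients w.r.t. the projected queries/keys/values given the
// cached softmax weights and the gradient of the concatenated head outputs
// [[Rcpp::export(name = ".mg_attn_bwd_cpp")]]
Rcpp::List mg_attn_bwd(const arma::mat& Qf, const arma::mat& Kf,
                       const arma::mat& Vf, const arma::vec& Abuf,
                       const arma::mat& dHf, int B, int T, int h) {
  const int d = Qf.n_cols;
  const int dk = d / h;
  const double scale = 1.0 / std::sqrt((double)dk);
  mat dQf(B * T, d, fill::zeros), dKf(B * T, d, fill::zeros),
      dVf(B * T, d, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * T;
    for (int i = 0; i < h; ++i) {
      const int c0 = i * dk;
      const mat A(const_cast<double*>(Abuf.memptr()) +
                      (size_t)(b * h + i) * T * T,
                  T, T, false, true);
      mat Q = Qf.submat(r0, c0, r0 + T - 1, c0 + dk - 1);
      mat K = Kf.submat(r0, c0, r0 + T - 1, c0 + dk - 1);
      mat V = Vf.submat(r0, c0, r0 + T - 1, c0 + dk - 1);
      mat dH = dHf.submat(r0, c0, r0 + T - 1, c0 + dk - 1);
      mat dA = dH * V.t();
      vec rs = sum(A % dA, 1);
      mat dS = A % (dA.each_col() - rs);
      dQf.submat(r0, c0, r0 + T - 1, c0 + dk - 1) = dS * K * scale;
      dKf.submat(r0, c0, r0 + T - 1, c0 + dk - 1) = dS.t() * Q * scale;
      dVf.submat(r0, c0, r0 + T - 1, c0 + dk - 1) = A.t() * dH;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQf") = dQf,
                            Rcpp::Named("dKf") = dKf,
                            Rcpp::Named("dVf") = dVf);
}
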