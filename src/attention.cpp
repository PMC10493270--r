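// Batched multi-head locality self-attention (diagonal -inf masking,
// per-head temperature) forward and backward. Input X packs B sequences of
// T tokens as a (B*T) x D matrix, sample-major. The plain-R reference
// implementation in R/ttm.R is the oracle these kernels are tested against.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat softmax_rows_cpp(mat s) {
  s.each_col() -= max(s, 1);
  s = exp(s);
  s.each_col() /= sum(s, 1);
  return s;
}

// [[Rcpp::export(name = ".lsa_forward_cpp")]]
Rcpp::List lsa_forward_cpp(const arma::mat& X, const arma::mat& Wqkv, const arma::rowvec& bqkv,
                           const arma::mat& Wo, const arma::rowvec& bo, const arma::vec& tau,
                           bool mask, int T) {
  const int D = X.n_cols;
  const int B = X.n_rows / T;
  const int H = tau.n_elem;
  const int dh = D / H;
  mat QKV = X * Wqkv;
  QKV.each_row() += bqkv;
  mat M(X.n_rows, D);              // head-concatenated attention output
  mat Abig(X.n_rows, H * T);       // per-sample, per-head attention weights
  for (int b = 0; b < B; ++b) {
    const int r0 = b * T;
    for (int h = 0; h < H; ++h) {
      mat Q = QKV.submat(r0, h * dh, r0 + T - 1, (h + 1) * dh - 1);
      mat K = QKV.submat(r0, D + h * dh, r0 + T - 1, D + (h + 1) * dh - 1);
      mat V = QKV.submat(r0, 2 * D + h * dh, r0 + T - 1,
                         2 * D + (h + 1) * dh - 1);
      mat S = Q * K.t() / tau(h);
      if (mask) S.diag().fill(-datum::inf);
      mat A = softmax_rows_cpp(S);
      Abig.submat(r0, h * T, r0 + T - 1, (h + 1) * T - 1) = A;
      M.submat(r0, h * dh, r0 + T - 1, (h + 1) * dh - 1) = A * V;
    }
  }
  mat out = M * Wo;
  out.each_row() += bo;
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("QKV") = QKV,
                            Rcpp::Named("A") = Abig,
                            Rcpp::Named("M") = M);
}

// [[Rcpp::export(name = ".lsa_backward_cpp")]]
Rcpp::List lsa_backward_cpp(const arma::mat& dOut, const arma::mat& X, const arma::mat& QKV,
                            const arma::mat& Abig, const arma::mat& M, const arma::mat& Wqkv,
                            const arma::mat& Wo, const arma::vec& tau, bool mask, int T) {
  const int D = X.n_cols;
  const int B = X.n_rows / T;
  const int H = tau.n_elem;
  const int dh = D / H;
  mat dWo = M.t() * dOut;
  rowvec dbo = sum(dOut, 0);
  mat dM = dOut * Wo.t();
  mat dQKV(size(QKV), fill::zeros);
  vec dtau(H, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const int r0 = b * T;
    for (int h = 0; h < H; ++h) {
      mat Q = QKV.submat(r0, h * dh, r0 + T - 1, (h + 1) * dh - 1);
      mat K = QKV.submat(r0, D + h * dh, r0 + T - 1, D + (h + 1) * dh - 1);
      mat V = QKV.submat(r0, 2 * D + h * dh, r0 + T - 1,
                         2 * D + (h + 1) * dh - 1);
      mat A = Abig.submat(r0, h * T, r0 + T - 1, (h + 1) * T - 1);
      mat dO = dM.submat(r0, h * dh, r0 + T - 1, (h + 1) * dh - 1);
      mat dV = A.t() * dO;
      mat dA = dO * V.t();
      vec rowdot = sum(dA % A, 1);
      mat dS = A % (dA.each_col() - rowdot);   // masked entries: A = 0
      mat R = Q * K.t();
      dtau(h) += -accu(dS % R) / (tau(h) * tau(h));
      dQKV.submat(r0, h * dh, r0 + T - 1, (h + 1) * dh - 1) =
        dS * K / tau(h);
      dQKV.submat(r0, D + h * dh, r0 + T - 1, D + (h + 1) * dh - 1) =
        dS.t() * Q / tau(h);
      dQKV.submat(r0, 2 * D + h * dh, r0 + T - 1, 2 * D + (h + 1) * dh - 1) =
        dV;
    }
  }
  mat dX = dQKV * Wqkv.t();
  mat dWqkv = X.t() * dQKV;
  rowvec dbqkv = sum(dQKV, 0);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dWqkv") = dWqkv,
                            Rcpp::Named("dbqkv") = dbqkv,
                            Rcpp::Named("dWo") = dWo,
                            Rcpp::Named("dbo") = dbo,
                            Rcpp::Named("dtau") = dtau);
}
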