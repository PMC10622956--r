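// Hot inner loops of the network: the temporal convolution (shared 1-D
// filters applied per electrode), the spatial convolution across
// electrodes, and the ordinary 1-D block convolution. Everything else
// (attention, batchnorm, pooling, activations, optimizers) stays in R.
//
// Layouts (column-major, matching the R arrays):
//   temporal conv  in  (C, T, B)          out (F, C, T1, B)
//   spatial conv   in  (F, C, T1, B)      out (Fo, T1, B)
//   block conv     in  (G, L, B)          out (F, T1, B)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---- temporal convolution -------------------------------------------------

// [[Rcpp::export(name = ".conv_time_fwd_cpp")]]
NumericVector conv_time_fwd_cpp(NumericVector X, NumericMatrix W,
                                int C, int T, int B) {
  const int F = W.nrow(), k = W.ncol();
  const int T1 = T - k + 1;
  NumericVector out(static_cast<R_xlen_t>(F) * C * T1 * B);
  out.attr("dim") = IntegerVector::create(F, C, T1, B);
  arma::mat Wm(W.begin(), F, k, false);
  arma::mat Xcol(k, T1);
  arma::mat O(F, T1);
  const double* xp = X.begin();
  double* op = out.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      // gather the electrode's series into im2col form
      for (int t = 0; t < T1; ++t) {
        const double* src = xp + (static_cast<R_xlen_t>(b) * T + t) * C + c;
        for (int j = 0; j < k; ++j) Xcol(j, t) = src[static_cast<R_xlen_t>(j) * C];
      }
      O = Wm * Xcol;
      for (int t = 0; t < T1; ++t) {
        double* dst = op + ((static_cast<R_xlen_t>(b) * T1 + t) * C + c) * F;
        std::memcpy(dst, O.colptr(t), sizeof(double) * F);
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv_time_bwd_cpp")]]
List conv_time_bwd_cpp(NumericVector dY, NumericVector X, NumericMatrix W,
                       int C, int T, int B) {
  const int F = W.nrow(), k = W.ncol();
  const int T1 = T - k + 1;
  NumericVector dX(static_cast<R_xlen_t>(C) * T * B);
  dX.attr("dim") = IntegerVector::create(C, T, B);
  arma::mat Wm(W.begin(), F, k, false);
  arma::mat dW(F, k, arma::fill::zeros);
  arma::mat Xcol(k, T1), G(F, T1), dXcol(k, T1);
  const double* xp = X.begin();
  const double* gp = dY.begin();
  double* dxp = dX.begin();
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      for (int t = 0; t < T1; ++t) {
        const double* src = xp + (static_cast<R_xlen_t>(b) * T + t) * C + c;
        for (int j = 0; j < k; ++j) Xcol(j, t) = src[static_cast<R_xlen_t>(j) * C];
        const double* gsrc = gp + ((static_cast<R_xlen_t>(b) * T1 + t) * C + c) * F;
        std::memcpy(G.colptr(t), gsrc, sizeof(double) * F);
      }
      dW += G * Xcol.t();
      dXcol = Wm.t() * G;
      for (int t = 0; t < T1; ++t) {
        double* dst = dxp + (static_cast<R_xlen_t>(b) * T + t) * C + c;
        for (int j = 0; j < k; ++j) dst[static_cast<R_xlen_t>(j) * C] += dXcol(j, t);
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = wrap(dW));
}

// ---- spatial convolution --------------------------------------------------

// [[Rcpp::export(name = ".conv_spat_fwd_cpp")]]
NumericVector conv_spat_fwd_cpp(NumericVector A, NumericMatrix W,
                                int F, int C, int T1, int B) {
  const int Fo = W.ncol();            // W is (F*C) x Fo
  NumericVector out(static_cast<R_xlen_t>(Fo) * T1 * B);
  out.attr("dim") = IntegerVector::create(Fo, T1, B);
  arma::mat Wm(W.begin(), static_cast<size_t>(F) * C, Fo, false);
  for (int b = 0; b < B; ++b) {
    arma::mat Ab(const_cast<double*>(A.begin()) +
                   static_cast<R_xlen_t>(b) * F * C * T1,
                 static_cast<size_t>(F) * C, T1, false, true);
    arma::mat Ob(out.begin() + static_cast<R_xlen_t>(b) * Fo * T1,
                 Fo, T1, false, true);
    Ob = Wm.t() * Ab;
  }
  return out;
}

// [[Rcpp::export(name = ".conv_spat_bwd_cpp")]]
List conv_spat_bwd_cpp(NumericVector dY, NumericVector A, NumericMatrix W,
                       int F, int C, int T1, int B) {
  const int Fo = W.ncol();
  NumericVector dA(static_cast<R_xlen_t>(F) * C * T1 * B);
  dA.attr("dim") = IntegerVector::create(F, C, T1, B);
  arma::mat Wm(W.begin(), static_cast<size_t>(F) * C, Fo, false);
  arma::mat dW(static_cast<size_t>(F) * C, Fo, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    arma::mat Ab(const_cast<double*>(A.begin()) +
                   static_cast<R_xlen_t>(b) * F * C * T1,
                 static_cast<size_t>(F) * C, T1, false, true);
    arma::mat dYb(const_cast<double*>(dY.begin()) +
                    static_cast<R_xlen_t>(b) * Fo * T1,
                  Fo, T1, false, true);
    arma::mat dAb(dA.begin() + static_cast<R_xlen_t>(b) * F * C * T1,
                  static_cast<size_t>(F) * C, T1, false, true);
    dAb = Wm * dYb;
    dW += Ab * dYb.t();
  }
  return List::create(_["dX"] = dA, _["dW"] = wrap(dW));
}

// ---- ordinary 1-D block convolution ---------------------------------------

// [[Rcpp::export(name = ".conv1d_fwd_cpp")]]
NumericVector conv1d_fwd_cpp(NumericVector X, NumericMatrix W,
                             int G, int L, int B, int k) {
  const int F = W.ncol();             // W is (G*k) x F
  const int T1 = L - k + 1;
  NumericVector out(static_cast<R_xlen_t>(F) * T1 * B);
  out.attr("dim") = IntegerVector::create(F, T1, B);
  arma::mat Wm(W.begin(), static_cast<size_t>(G) * k, F, false);
  arma::mat M(static_cast<size_t>(G) * k, T1);
  for (int b = 0; b < B; ++b) {
    const double* xb = X.begin() + static_cast<R_xlen_t>(b) * G * L;
    // column t1 of M is the contiguous window X[, t1:(t1+k-1), b]
    for (int t = 0; t < T1; ++t) {
      std::memcpy(M.colptr(t), xb + static_cast<R_xlen_t>(t) * G,
                  sizeof(double) * G * k);
    }
    arma::mat Ob(out.begin() + static_cast<R_xlen_t>(b) * F * T1,
                 F, T1, false, true);
    Ob = Wm.t() * M;
  }
  return out;
}

// [[Rcpp::export(name = ".conv1d_bwd_cpp")]]
List conv1d_bwd_cpp(NumericVector dY, NumericVector X, NumericMatrix W,
                    int G, int L, int B, int k) {
  const int F = W.ncol();
  const int T1 = L - k + 1;
  NumericVector dX(static_cast<R_xlen_t>(G) * L * B);
  dX.attr("dim") = IntegerVector::create(G, L, B);
  arma::mat Wm(W.begin(), static_cast<size_t>(G) * k, F, false);
  arma::mat dW(static_cast<size_t>(G) * k, F, arma::fill::zeros);
  arma::mat M(static_cast<size_t>(G) * k, T1), dM(static_cast<size_t>(G) * k, T1);
  const int gk = G * k;
  for (int b = 0; b < B; ++b) {
    const double* xb = X.begin() + static_cast<R_xlen_t>(b) * G * L;
    for (int t = 0; t < T1; ++t) {
      std::memcpy(M.colptr(t), xb + static_cast<R_xlen_t>(t) * G,
                  sizeof(double) * gk);
    }
    arma::mat dYb(const_cast<double*>(dY.begin()) +
                    static_cast<R_xlen_t>(b) * F * T1,
                  F, T1, false, true);
    dW += M * dYb.t();
    dM = Wm * dYb;
    double* dxb = dX.begin() + static_cast<R_xlen_t>(b) * G * L;
    for (int t = 0; t < T1; ++t) {
      const double* src = dM.colptr(t);
      double* dst = dxb + static_cast<R_xlen_t>(t) * G;
      for (int i = 0; i < gk; ++i) dst[i] += src[i];
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = wrap(dW));
}
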