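// Fused elementwise/reduction kernels for the network hot path.
// Minibatches reach these as (channels x N) matrices with N = length*batch;
// each kernel makes one or two linear passes instead of the half dozen
// full-size temporaries the equivalent vectorised R would allocate.

#include <Rcpp.h>
using namespace Rcpp;

// Batch-norm forward, training mode: per-channel batch statistics.
// Returns Y, xhat (cached for backward), is = 1/sqrt(var+eps), m, v.
// [[Rcpp::export(name = ".cpp_bn_train")]]
List cpp_bn_train(const NumericMatrix& X, const NumericVector& g,
                  const NumericVector& b, double eps) {
  const int C = X.nrow(); const R_xlen_t N = X.ncol();
  NumericVector m(C), v(C), is(C);
  const double* x = X.begin();
  for (R_xlen_t j = 0; j < N; ++j) {
    const double* col = x + j * C;
    for (int i = 0; i < C; ++i) {
      m[i] += col[i];
      v[i] += col[i] * col[i];
    }
  }
  for (int i = 0; i < C; ++i) {
    m[i] /= N;
    v[i] = v[i] / N - m[i] * m[i];
    if (v[i] < 0) v[i] = 0;
    is[i] = 1.0 / std::sqrt(v[i] + eps);
  }
  NumericMatrix Y(no_init(C, (int)N)), xhat(no_init(C, (int)N));
  double* y = Y.begin();
  double* xh = xhat.begin();
  for (R_xlen_t j = 0; j < N; ++j) {
    const double* col = x + j * C;
    double* yc = y + j * C;
    double* xc = xh + j * C;
    for (int i = 0; i < C; ++i) {
      xc[i] = (col[i] - m[i]) * is[i];
      yc[i] = g[i] * xc[i] + b[i];
    }
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["is"] = is,
                      _["m"] = m, _["v"] = v);
}

// Batch-norm forward, evaluation mode: running statistics.
// [[Rcpp::export(name = ".cpp_bn_eval")]]
List cpp_bn_eval(const NumericMatrix& X, const NumericVector& g,
                 const NumericVector& b, const NumericVector& rm,
                 const NumericVector& rv, double eps) {
  const int C = X.nrow(); const R_xlen_t N = X.ncol();
  NumericVector is(C);
  for (int i = 0; i < C; ++i) is[i] = 1.0 / std::sqrt(rv[i] + eps);
  NumericMatrix Y(no_init(C, (int)N)), xhat(no_init(C, (int)N));
  const double* x = X.begin();
  double* y = Y.begin();
  double* xh = xhat.begin();
  for (R_xlen_t j = 0; j < N; ++j) {
    const double* col = x + j * C;
    double* yc = y + j * C;
    double* xc = xh + j * C;
    for (int i = 0; i < C; ++i) {
      xc[i] = (col[i] - rm[i]) * is[i];
      yc[i] = g[i] * xc[i] + b[i];
    }
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["is"] = is);
}

// Batch-norm backward. In training mode the batch statistics depend on
// the input, giving the full three-term gradient; in evaluation mode the
// statistics are constants and the gradient is a plain rescale.
// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(const NumericMatrix& dY, const NumericMatrix& xhat,
                const NumericVector& is, const NumericVector& g,
                bool train) {
  const int C = dY.nrow(); const R_xlen_t N = dY.ncol();
  NumericVector dg(C), db(C);
  const double* dy = dY.begin();
  const double* xh = xhat.begin();
  for (R_xlen_t j = 0; j < N; ++j) {
    const double* dc = dy + j * C;
    const double* xc = xh + j * C;
    for (int i = 0; i < C; ++i) {
      dg[i] += dc[i] * xc[i];
      db[i] += dc[i];
    }
  }
  NumericMatrix dX(no_init(C, (int)N));
  double* dx = dX.begin();
  if (train) {
    for (R_xlen_t j = 0; j < N; ++j) {
      const double* dc = dy + j * C;
      const double* xc = xh + j * C;
      double* dxc = dx + j * C;
      for (int i = 0; i < C; ++i)
        dxc[i] = (g[i] * is[i] / N) * (N * dc[i] - db[i] - xc[i] * dg[i]);
    }
  } else {
    for (R_xlen_t j = 0; j < N; ++j) {
      const double* dc = dy + j * C;
      double* dxc = dx + j * C;
      for (int i = 0; i < C; ++i)
        dxc[i] = dc[i] * g[i] * is[i];
    }
  }
  return List::create(_["dg"] = dg, _["db"] = db, _["dX"] = dX);
}

// ReLU; the output doubles as the backward mask (dX = dY * (Y > 0)).
// [[Rcpp::export(name = ".cpp_relu")]]
NumericVector cpp_relu(const NumericVector& X) {
  NumericVector Y(clone(X));
  double* y = Y.begin();
  const R_xlen_t n = Y.size();
  for (R_xlen_t i = 0; i < n; ++i) if (y[i] < 0) y[i] = 0;
  Y.attr("dim") = X.attr("dim");
  return Y;
}

// [[Rcpp::export(name = ".cpp_relu_bwd")]]
NumericVector cpp_relu_bwd(const NumericVector& dY, const NumericVector& Y) {
  NumericVector dX(clone(dY));
  double* dx = dX.begin();
  const double* y = Y.begin();
  const R_xlen_t n = dX.size();
  for (R_xlen_t i = 0; i < n; ++i) if (y[i] <= 0) dx[i] = 0;
  dX.attr("dim") = dY.attr("dim");
  return dX;
}

// Residual add: Y = A + B without an extra R-level temporary.
// [[Rcpp::export(name = ".cpp_add")]]
NumericVector cpp_add(const NumericVector& A, const NumericVector& B) {
  NumericVector Y(clone(A));
  double* y = Y.begin();
  const double* b = B.begin();
  const R_xlen_t n = Y.size();
  for (R_xlen_t i = 0; i < n; ++i) y[i] += b[i];
  Y.attr("dim") = A.attr("dim");
  return Y;
}

// im2col gather. X holds B contiguous (Cin x Lin) blocks; idx is 1-based
// into one block, 0 marking zero-padding. Output has `rows` rows and
// length(idx)/rows * B columns (the (rows, Lout, B) layout flattened).
// [[Rcpp::export(name = ".cpp_gather")]]
NumericVector cpp_gather(const NumericVector& X, const IntegerVector& idx,
                         int B, int in_block, int rows) {
  const R_xlen_t n = idx.size();
  NumericVector out(no_init(n * (R_xlen_t)B));
  const double* x = X.begin();
  const int* id = idx.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (R_xlen_t)b * in_block;
    double* ob = o + (R_xlen_t)b * n;
    for (R_xlen_t i = 0; i < n; ++i)
      ob[i] = id[i] ? xb[id[i] - 1] : 0.0;
  }
  out.attr("dim") = IntegerVector::create(rows, (int)(n / rows) * B);
  return out;
}

// col2im scatter-add, the adjoint of cpp_gather.
// [[Rcpp::export(name = ".cpp_scatter")]]
NumericVector cpp_scatter(const NumericVector& dXc, const IntegerVector& idx,
                          int B, int in_block, int Cin) {
  const R_xlen_t n = idx.size();
  NumericVector out((R_xlen_t)in_block * B);   // zero-initialised
  const double* d = dXc.begin();
  const int* id = idx.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    double* ob = o + (R_xlen_t)b * in_block;
    const double* db = d + (R_xlen_t)b * n;
    for (R_xlen_t i = 0; i < n; ++i)
      if (id[i]) ob[id[i] - 1] += db[i];
  }
  out.attr("dim") = IntegerVector::create(Cin, in_block / Cin * B);
  return out;
}

// global average pool over the length axis: (C, L*B) -> (C, B)
// [[Rcpp::export(name = ".cpp_pool_fwd")]]
NumericMatrix cpp_pool_fwd(const NumericVector& X, int C, int L, int B) {
  NumericMatrix out(C, B);   // zero-initialised
  const double* x = X.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = x + (R_xlen_t)b * C * L;
    double* ob = o + (R_xlen_t)b * C;
    for (int l = 0; l < L; ++l)
      for (int i = 0; i < C; ++i) ob[i] += xb[(R_xlen_t)l * C + i];
    for (int i = 0; i < C; ++i) ob[i] /= L;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_pool_bwd")]]
NumericVector cpp_pool_bwd(const NumericMatrix& dY, int C, int L, int B) {
  NumericVector out(no_init((R_xlen_t)C * L * B));
  const double* d = dY.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* db = d + (R_xlen_t)b * C;
    double* ob = o + (R_xlen_t)b * C * L;
    for (int l = 0; l < L; ++l)
      for (int i = 0; i < C; ++i) ob[(R_xlen_t)l * C + i] = db[i] / L;
  }
  out.attr("dim") = IntegerVector::create(C, L * B);
  return out;
}
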