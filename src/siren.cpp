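#include <Rcpp.h>
using namespace Rcpp;

// Fused evaluation of the 3-hidden-layer sine decoder for one set of
// generated weights. Layer 1 maps coordinates (3) to width w; layers 2
// and 3 are width-preserving with residual skips over the whole layer;
// a dense linear output follows. The forward pass stores the pre-sine
// arguments and activations in coordinate-major (w x M) layout so the
// backward pass touches contiguous memory and only needs cosines.
// Must stay numerically identical to the R reference implementation
// (decoder_forward / decoder_backward), which the test suite asserts.

// [[Rcpp::export]]
List cpp_siren_forward(NumericMatrix coords,
                       NumericMatrix W1, NumericVector b1,
                       NumericMatrix W2, NumericVector b2,
                       NumericMatrix W3, NumericVector b3,
                       NumericVector Wo, double bo,
                       double om, bool want_cache) {
  int M = coords.nrow();
  int w = W1.ncol();
  NumericVector out(M);
  NumericMatrix u1(want_cache ? w : 1, want_cache ? M : 1);
  NumericMatrix u2(want_cache ? w : 1, want_cache ? M : 1);
  NumericMatrix u3(want_cache ? w : 1, want_cache ? M : 1);
  NumericMatrix h1m(want_cache ? w : 1, want_cache ? M : 1);
  NumericMatrix h2m(want_cache ? w : 1, want_cache ? M : 1);
  std::vector<double> h1(w), h2(w);
  for (int m = 0; m < M; ++m) {
    double x0 = coords(m, 0), x1 = coords(m, 1), x2 = coords(m, 2);
    for (int j = 0; j < w; ++j) {
      double u = om * (x0 * W1(0, j) + x1 * W1(1, j) + x2 * W1(2, j) + b1[j]);
      if (want_cache) u1(j, m) = u;
      h1[j] = std::sin(u);
      if (want_cache) h1m(j, m) = h1[j];
    }
    for (int j = 0; j < w; ++j) {
      double u = b2[j];
      for (int i = 0; i < w; ++i) u += h1[i] * W2(i, j);
      u *= om;
      if (want_cache) u2(j, m) = u;
      h2[j] = h1[j] + std::sin(u);
      if (want_cache) h2m(j, m) = h2[j];
    }
    double acc = bo;
    for (int j = 0; j < w; ++j) {
      double u = b3[j];
      for (int i = 0; i < w; ++i) u += h2[i] * W3(i, j);
      u *= om;
      if (want_cache) u3(j, m) = u;
      acc += (h2[j] + std::sin(u)) * Wo[j];
    }
    out[m] = acc;
  }
  if (want_cache)
    return List::create(_["out"] = out, _["u1"] = u1, _["u2"] = u2,
                        _["u3"] = u3, _["h1"] = h1m, _["h2"] = h2m);
  return List::create(_["out"] = out);
}

// [[Rcpp::export]]
List cpp_siren_backward(NumericMatrix coords,
                        NumericMatrix W1, NumericMatrix W2,
                        NumericMatrix W3, NumericVector Wo,
                        double om, NumericVector gout,
                        NumericMatrix u1, NumericMatrix u2,
                        NumericMatrix u3, NumericMatrix h1m,
                        NumericMatrix h2m) {
  int M = coords.nrow();
  int w = W1.ncol();
  NumericMatrix dW1(3, w), dW2(w, w), dW3(w, w);
  NumericVector db1(w), db2(w), db3(w), dWo(w);
  double dbo = 0.0;
  std::vector<double> g(w), du(w), g1(w);
  for (int m = 0; m < M; ++m) {
    double gm = gout[m];
    if (gm == 0.0) continue;
    dbo += gm;
    const double *h1 = &h1m(0, m);
    const double *h2 = &h2m(0, m);
    for (int j = 0; j < w; ++j) {
      dWo[j] += gm * (h2[j] + std::sin(u3(j, m)));
      g[j] = gm * Wo[j];           // dL/dh3
    }
    // layer 3
    for (int j = 0; j < w; ++j) du[j] = g[j] * std::cos(u3(j, m)) * om;
    for (int j = 0; j < w; ++j) {
      db3[j] += du[j];
      double *col = &dW3(0, j);
      double d = du[j];
      for (int i = 0; i < w; ++i) col[i] += h2[i] * d;
    }
    for (int i = 0; i < w; ++i) {
      double s = g[i];              // residual skip
      const double *row = &W3(i, 0);
      for (int j = 0; j < w; ++j) s += row[(size_t)j * w] * du[j];
      g1[i] = s;                    // dL/dh2
    }
    // layer 2
    for (int j = 0; j < w; ++j) du[j] = g1[j] * std::cos(u2(j, m)) * om;
    for (int j = 0; j < w; ++j) {
      db2[j] += du[j];
      double *col = &dW2(0, j);
      double d = du[j];
      for (int i = 0; i < w; ++i) col[i] += h1[i] * d;
    }
    for (int i = 0; i < w; ++i) {
      double s = g1[i];
      const double *row = &W2(i, 0);
      for (int j = 0; j < w; ++j) s += row[(size_t)j * w] * du[j];
      g[i] = s;                     // dL/dh1
    }
    // layer 1 (no skip into coordinates)
    double x0 = coords(m, 0), x1 = coords(m, 1), x2 = coords(m, 2);
    for (int j = 0; j < w; ++j) {
      double d = g[j] * std::cos(u1(j, m)) * om;
      db1[j] += d;
      dW1(0, j) += x0 * d;
      dW1(1, j) += x1 * d;
      dW1(2, j) += x2 * d;
    }
  }
  return List::create(_["dW1"] = dW1, _["db1"] = db1, _["dW2"] = dW2,
                      _["db2"] = db2, _["dW3"] = dW3, _["db3"] = db3,
                      _["dWo"] = dWo, _["dbo"] = dbo);
}
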