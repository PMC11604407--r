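// Parallel-beam ray-driven projector pair. Rays are sampled every half
// pixel; the image is bilinearly interpolated at the sample coordinates
// (1-based grid row/col units, prepared in R). The back-projector is the
// exact adjoint of the forward projector.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_project_ray(NumericMatrix img, NumericMatrix r,
                              NumericMatrix c, double ds) {
  const int n = img.nrow();
  const int ns = r.nrow(), nd = r.ncol();
  NumericVector p(nd);
  for (int j = 0; j < nd; ++j) {
    double acc = 0.0;
    for (int m = 0; m < ns; ++m) {
      const double rr = r(m, j) - 1.0, cc = c(m, j) - 1.0;
      const int i0 = (int)std::floor(rr), j0 = (int)std::floor(cc);
      const double fr = rr - i0, fc = cc - j0;
      if (i0 >= 0 && i0 < n) {
        if (j0 >= 0 && j0 < n) acc += img(i0, j0) * (1 - fr) * (1 - fc);
        if (j0 + 1 >= 0 && j0 + 1 < n) acc += img(i0, j0 + 1) * (1 - fr) * fc;
      }
      if (i0 + 1 >= 0 && i0 + 1 < n) {
        if (j0 >= 0 && j0 < n) acc += img(i0 + 1, j0) * fr * (1 - fc);
        if (j0 + 1 >= 0 && j0 + 1 < n) acc += img(i0 + 1, j0 + 1) * fr * fc;
      }
    }
    p[j] = acc * ds;
  }
  return p;
}

// [[Rcpp::export]]
NumericMatrix cpp_backproject_ray(NumericVector p, NumericMatrix r,
                                  NumericMatrix c, double ds, int n) {
  const int ns = r.nrow(), nd = r.ncol();
  NumericMatrix img(n, n);
  for (int j = 0; j < nd; ++j) {
    const double v = p[j] * ds;
    if (v == 0.0) continue;
    for (int m = 0; m < ns; ++m) {
      const double rr = r(m, j) - 1.0, cc = c(m, j) - 1.0;
      const int i0 = (int)std::floor(rr), j0 = (int)std::floor(cc);
      const double fr = rr - i0, fc = cc - j0;
      if (i0 >= 0 && i0 < n) {
        if (j0 >= 0 && j0 < n) img(i0, j0) += v * (1 - fr) * (1 - fc);
        if (j0 + 1 >= 0 && j0 + 1 < n) img(i0, j0 + 1) += v * (1 - fr) * fc;
      }
      if (i0 + 1 >= 0 && i0 + 1 < n) {
        if (j0 >= 0 && j0 < n) img(i0 + 1, j0) += v * fr * (1 - fc);
        if (j0 + 1 >= 0 && j0 + 1 < n) img(i0 + 1, j0 + 1) += v * fr * fc;
      }
    }
  }
  return img;
}
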