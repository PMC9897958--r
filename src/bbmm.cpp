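#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brownian bridge UD accumulation.
//
// For each consecutive-fix bridge the bivariate normal position density is
// integrated over the time fraction alpha with a trapezoid rule (K nodes,
// alpha = 0..1), each bridge weighted by its duration.  Node densities are
// isotropic, so the grid accumulation is a separable outer product,
// truncated at trunc_sd standard deviations.  The caller normalizes.
//
// Grid: row 1 = southernmost row; cell centre x = xmin + (j - 0.5) * res.

// [[Rcpp::export(name = ".bbmm_ud_accumulate")]]
NumericMatrix bbmm_ud_accumulate(NumericVector x, NumericVector y,
                                 NumericVector th, double sigma2m,
                                 double delta2, int K, double xmin,
                                 double ymin, double res, int nrow, int ncol,
                                 double trunc_sd) {
  int n = x.size();
  NumericMatrix out(nrow, ncol);
  if (K < 2) stop("K must be >= 2");
  std::vector<double> gx(ncol), gy(nrow);
  for (int b = 0; b + 1 < n; b++) {
    double T = th[b + 1] - th[b];
    if (!(T > 0)) continue;
    for (int k = 0; k < K; k++) {
      double alpha = (double)k / (K - 1);
      double w = (k == 0 || k == K - 1) ? 0.5 : 1.0;
      double weight = w * T / (K - 1);
      double mux = (1 - alpha) * x[b] + alpha * x[b + 1];
      double muy = (1 - alpha) * y[b] + alpha * y[b + 1];
      double s2 = T * alpha * (1 - alpha) * sigma2m +
                  ((1 - alpha) * (1 - alpha) + alpha * alpha) * delta2;
      if (!(s2 > 0)) continue;
      double lim = trunc_sd * std::sqrt(s2);
      int j0 = (int)std::floor((mux - lim - xmin) / res);
      int j1 = (int)std::floor((mux + lim - xmin) / res);
      int i0 = (int)std::floor((muy - lim - ymin) / res);
      int i1 = (int)std::floor((muy + lim - ymin) / res);
      if (j0 < 0) j0 = 0;
      if (i0 < 0) i0 = 0;
      if (j1 > ncol - 1) j1 = ncol - 1;
      if (i1 > nrow - 1) i1 = nrow - 1;
      if (j0 > j1 || i0 > i1) continue;
      for (int j = j0; j <= j1; j++) {
        double dx = xmin + (j + 0.5) * res - mux;
        gx[j] = std::exp(-0.5 * dx * dx / s2);
      }
      for (int i = i0; i <= i1; i++) {
        double dy = ymin + (i + 0.5) * res - muy;
        gy[i] = std::exp(-0.5 * dy * dy / s2);
      }
      double scale = weight / s2;
      for (int j = j0; j <= j1; j++) {
        double g = scale * gx[j];
        for (int i = i0; i <= i1; i++) out(i, j) += g * gy[i];
      }
    }
  }
  return out;
}
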