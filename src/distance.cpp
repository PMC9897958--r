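#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher 2012),
// squared distances in cell units; and brute-force distance from cell
// centres to a densified point set (for vector line features).

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_squared")]]
NumericMatrix edt_squared(LogicalMatrix target) {
  int nr = target.nrow(), nc = target.ncol();
  // large finite sentinel: the parabola envelope assumes finite f
  double INF = 1e30;
  NumericMatrix d(nr, nc);
  for (int i = 0; i < nr; i++)
    for (int j = 0; j < nc; j++) d(i, j) = target(i, j) ? 0.0 : INF;
  std::vector<double> f(std::max(nr, nc)), out(std::max(nr, nc));
  // columns then rows
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = d(i, j);
    dt1d(f, out, nr);
    for (int i = 0; i < nr; i++) d(i, j) = out[i];
  }
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = d(i, j);
    dt1d(f, out, nc);
    for (int j = 0; j < nc; j++) d(i, j) = out[j];
  }
  return d;
}

// [[Rcpp::export(name = ".dist_cells_to_points")]]
NumericMatrix dist_cells_to_points(int nrow, int ncol, double xmin,
                                   double ymin, double res, NumericVector px,
                                   NumericVector py) {
  NumericMatrix d(nrow, ncol);
  int np = px.size();
  for (int i = 0; i < nrow; i++) {
    double cy = ymin + (i + 0.5) * res;
    for (int j = 0; j < ncol; j++) {
      double cx = xmin + (j + 0.5) * res;
      double best = std::numeric_limits<double>::infinity();
      for (int p = 0; p < np; p++) {
        double dx = cx - px[p], dy = cy - py[p];
        double dd = dx * dx + dy * dy;
        if (dd < best) best = dd;
      }
      d(i, j) = std::sqrt(best);
    }
  }
  return d;
}

// [[Rcpp::export(name = ".min_dist_points_to_cells")]]
NumericVector min_dist_points_to_cells(NumericVector px, NumericVector py,
                                       NumericVector cx, NumericVector cy,
                                       double half) {
  // distance from each point to the nearest cell *square* (centre +- half)
  int np = px.size(), nc = cx.size();
  NumericVector d(np);
  for (int p = 0; p < np; p++) {
    double best = std::numeric_limits<double>::infinity();
    for (int c = 0; c < nc; c++) {
      double dx = std::fabs(px[p] - cx[c]) - half;
      double dy = std::fabs(py[p] - cy[c]) - half;
      if (dx < 0) dx = 0;
      if (dy < 0) dy = 0;
      double dd = dx * dx + dy * dy;
      if (dd < best) best = dd;
      if (best == 0) break;
    }
    d[p] = std::sqrt(best);
  }
  return d;
}
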