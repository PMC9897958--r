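#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Landscape-level moving-window metrics over a circular window.
//
// Conventions (FRAGSTATS landscape-level defaults):
//  - adjacency: rook (4-neighbour), single count; both cells of a pair must
//    lie inside the window, so the window boundary contributes no edge
//  - window membership: cell-centre distance <= radius; windows truncated at
//    the raster border
//  - IJI defined only when >= 3 classes are present in the window (NA else)
//  - AI: classes whose maximal like-adjacency count is zero (single-cell
//    classes) contribute nothing to the proportion-weighted sum
//
// r uses integer class codes 1..nclass; group maps each code to a
// composition group: 0 none, 1 forest, 2 developed, 3 open.

static void window_metrics_one(const IntegerMatrix &r, int nclass,
                               const IntegerVector &group,
                               int frow, int fcol, int mrad,
                               const LogicalMatrix &win, double res,
                               double *out) {
  int nr = r.nrow(), nc = r.ncol();
  std::vector<int> cnt(nclass + 1, 0);
  std::vector<int> like(nclass + 1, 0);
  // unlike adjacency counts per unordered class pair (c1 < c2)
  std::vector<int> pair_cnt((nclass + 1) * (nclass + 1), 0);
  int ncells = 0, unlike_total = 0;

  for (int di = -mrad; di <= mrad; di++) {
    int i = frow + di;
    if (i < 0 || i >= nr) continue;
    for (int dj = -mrad; dj <= mrad; dj++) {
      if (!win(di + mrad, dj + mrad)) continue;
      int j = fcol + dj;
      if (j < 0 || j >= nc) continue;
      int c = r(i, j);
      ncells++;
      cnt[c]++;
      // east neighbour (dj+1) and north neighbour (di+1), single count
      for (int d = 0; d < 2; d++) {
        int di2 = d == 0 ? di : di + 1;
        int dj2 = d == 0 ? dj + 1 : dj;
        if (di2 > mrad || dj2 > mrad) continue;
        if (!win(di2 + mrad, dj2 + mrad)) continue;
        int i2 = frow + di2, j2 = fcol + dj2;
        if (i2 < 0 || i2 >= nr || j2 < 0 || j2 >= nc) continue;
        int c2 = r(i2, j2);
        if (c2 == c) {
          like[c]++;
        } else {
          unlike_total++;
          int a = c < c2 ? c : c2, b = c < c2 ? c2 : c;
          pair_cnt[a * (nclass + 1) + b]++;
        }
      }
    }
  }

  double area = (double)ncells * res * res; // m^2
  int richness = 0;
  double nfor = 0, ndev = 0, nopen = 0;
  for (int c = 1; c <= nclass; c++) {
    if (cnt[c] > 0) richness++;
    if (group[c - 1] == 1) nfor += cnt[c];
    else if (group[c - 1] == 2) ndev += cnt[c];
    else if (group[c - 1] == 3) nopen += cnt[c];
  }

  // percent composition
  out[0] = 100.0 * nfor / ncells;
  out[1] = 100.0 * ndev / ncells;
  out[2] = 100.0 * nopen / ncells;
  // edge density, m per ha
  out[3] = 10000.0 * (unlike_total * res) / area;
  // IJI (percent), >= 3 classes required
  if (richness >= 3 && unlike_total > 0) {
    double E = unlike_total * res, H = 0.0;
    for (int a = 1; a <= nclass; a++)
      for (int b = a + 1; b <= nclass; b++) {
        int e = pair_cnt[a * (nclass + 1) + b];
        if (e > 0) {
          double p = (e * res) / E;
          H -= p * std::log(p);
        }
      }
    out[4] = 100.0 * H / std::log(0.5 * richness * (richness - 1.0));
  } else {
    out[4] = NA_REAL;
  }
  // patch richness density, classes per 100 ha
  out[5] = 1.0e6 * richness / area;
  // aggregation index (percent)
  double ai = 0.0;
  for (int c = 1; c <= nclass; c++) {
    if (cnt[c] == 0) continue;
    long A = cnt[c];
    long n = (long)std::floor(std::sqrt((double)A));
    long m = A - n * n;
    long maxg = 2 * n * (n - 1);
    if (m > 0) maxg += (m <= n) ? (2 * m - 1) : (2 * m - 2);
    if (maxg > 0) ai += ((double)cnt[c] / ncells) * ((double)like[c] / maxg);
  }
  out[6] = 100.0 * ai;
}

// [[Rcpp::export(name = ".mw_metrics_cells")]]
NumericMatrix mw_metrics_cells(IntegerMatrix r, int nclass, IntegerVector group,
                               IntegerVector rows, IntegerVector cols,
                               int mrad, LogicalMatrix win, double res) {
  int n = rows.size();
  NumericMatrix out(n, 7);
  double buf[7];
  for (int k = 0; k < n; k++) {
    window_metrics_one(r, nclass, group, rows[k] - 1, cols[k] - 1, mrad, win,
                       res, buf);
    for (int m = 0; m < 7; m++) out(k, m) = buf[m];
  }
  colnames(out) = CharacterVector::create("for", "dev", "open", "ED", "IJI",
                                          "PRD", "AI");
  return out;
}

// [[Rcpp::export(name = ".mw_metrics_full")]]
List mw_metrics_full(IntegerMatrix r, int nclass, IntegerVector group,
                     int mrad, LogicalMatrix win, double res) {
  int nr = r.nrow(), nc = r.ncol();
  List bands(7);
  std::vector<NumericMatrix> m;
  for (int b = 0; b < 7; b++) m.push_back(NumericMatrix(nr, nc));
  double buf[7];
  for (int i = 0; i < nr; i++)
    for (int j = 0; j < nc; j++) {
      window_metrics_one(r, nclass, group, i, j, mrad, win, res, buf);
      for (int b = 0; b < 7; b++) m[b](i, j) = buf[b];
    }
  for (int b = 0; b < 7; b++) bands[b] = m[b];
  bands.attr("names") = CharacterVector::create("for", "dev", "open", "ED",
                                                "IJI", "PRD", "AI");
  return bands;
}
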