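#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Connected-component labelling (rook adjacency) and multi-source BFS fill,
// used by the modified-random-clusters landscape generator.

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix occ) {
  int nr = occ.nrow(), nc = occ.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nr; i++)
    for (int j = 0; j < nc; j++) {
      if (!occ(i, j) || lab(i, j) != 0) continue;
      next++;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> cur = q.front();
        q.pop();
        int ci = cur.first, cj = cur.second;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; d++) {
          int ni = ci + di[d], nj = cj + dj[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (occ(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push(std::make_pair(ni, nj));
          }
        }
      }
    }
  lab.attr("n") = next;
  return lab;
}

// [[Rcpp::export(name = ".bfs_fill")]]
IntegerMatrix bfs_fill(IntegerMatrix cls) {
  // cells with value 0 take the class of the nearest (BFS order, rook)
  // assigned cell; deterministic given the input
  int nr = cls.nrow(), nc = cls.ncol();
  IntegerMatrix out = clone(cls);
  std::queue<std::pair<int, int> > q;
  for (int i = 0; i < nr; i++)
    for (int j = 0; j < nc; j++)
      if (out(i, j) != 0) q.push(std::make_pair(i, j));
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    std::pair<int, int> cur = q.front();
    q.pop();
    int ci = cur.first, cj = cur.second;
    for (int d = 0; d < 4; d++) {
      int ni = ci + di[d], nj = cj + dj[d];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (out(ni, nj) == 0) {
        out(ni, nj) = out(ci, cj);
        q.push(std::make_pair(ni, nj));
      }
    }
  }
  return out;
}
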