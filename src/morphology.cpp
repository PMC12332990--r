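// Binary-mask morphology: connected-component labelling under 6/18/26
// connectivity and brute-force boundary distance sets for HD95.

#include <Rcpp.h>
#include <queue>
#include <cmath>

using namespace Rcpp;

// Label connected components of a binary volume.  Returns an integer volume
// with components numbered 1..n in scan order of their first voxel.
// [[Rcpp::export]]
IntegerVector cpp_cc_label(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  IntegerVector lab(N, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int order = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (order == 0) continue;
        if ((connectivity == 6 && order > 1) ||
            (connectivity == 18 && order > 2))
          continue;
        offs.push_back({dx, dy, dz});
      }

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t cur = q.front(); q.pop();
      const int cx = cur % X, cy = (cur / X) % Y, cz = cur / ((R_xlen_t)X * Y);
      for (const auto& o : offs) {
        const int nx = cx + o[0], ny = cy + o[1], nz = cz + o[2];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
        const R_xlen_t ni = (R_xlen_t)nx + (R_xlen_t)X * (ny + (R_xlen_t)Y * nz);
        if (mask[ni] && lab[ni] == 0) { lab[ni] = next; q.push(ni); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Directed nearest-neighbour distances from each row of `a` to the point
// set `b` (both n x 3, world mm).  Brute force; boundary sets are small.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
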