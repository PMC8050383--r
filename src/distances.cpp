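#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// For each row of A, the Euclidean distance to the nearest row of B
// (vertex-to-vertex point-set distances; max of these is the one-sided
// Hausdorff distance). Uses a uniform hash grid over B with expanding-shell
// search; falls back to brute force for tiny B.

// [[Rcpp::export]]
NumericVector nn_distances_cpp(const NumericMatrix &A, const NumericMatrix &B) {
  const int nA = A.nrow(), nB = B.nrow();
  NumericVector out(nA);
  if (nB == 0) stop("empty reference point set");

  if (nB <= 64) {
    for (int i = 0; i < nA; ++i) {
      double best = R_PosInf;
      for (int j = 0; j < nB; ++j) {
        double dx = A(i,0)-B(j,0), dy = A(i,1)-B(j,1), dz = A(i,2)-B(j,2);
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best) best = d2;
      }
      out[i] = std::sqrt(best);
    }
    return out;
  }

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int j = 0; j < nB; ++j)
    for (int d = 0; d < 3; ++d) {
      if (B(j,d) < lo[d]) lo[d] = B(j,d);
      if (B(j,d) > hi[d]) hi[d] = B(j,d);
    }
  double ext[3];
  double vol = 1.0;
  for (int d = 0; d < 3; ++d) {
    ext[d] = std::max(hi[d] - lo[d], 1e-9);
    vol *= ext[d];
  }
  double h = std::cbrt(vol / nB) * 2.0;
  int ng[3];
  for (int d = 0; d < 3; ++d) {
    ng[d] = std::max(1, std::min(256, (int)std::floor(ext[d] / h) + 1));
  }
  auto cellOf = [&](double x, int d) -> int {
    int c = (int)std::floor((x - lo[d]) / ext[d] * ng[d]);
    return std::max(0, std::min(ng[d] - 1, c));
  };
  double cw[3];
  for (int d = 0; d < 3; ++d) cw[d] = ext[d] / ng[d];
  double cwmin = std::min(cw[0], std::min(cw[1], cw[2]));

  std::vector<std::vector<int>> buckets((size_t)ng[0] * ng[1] * ng[2]);
  auto bidx = [&](int i, int j, int k) -> size_t {
    return (size_t)i + (size_t)ng[0] * ((size_t)j + (size_t)ng[1] * k);
  };
  for (int j = 0; j < nB; ++j)
    buckets[bidx(cellOf(B(j,0),0), cellOf(B(j,1),1), cellOf(B(j,2),2))].push_back(j);

  int maxShell = ng[0] + ng[1] + ng[2] + 2;
  for (int i = 0; i < nA; ++i) {
    double px = A(i,0), py = A(i,1), pz = A(i,2);
    int ci = cellOf(px,0), cj = cellOf(py,1), ck = cellOf(pz,2);
    double best = R_PosInf;
    for (int s = 0; s <= maxShell; ++s) {
      // a point in a cell at Chebyshev cell-distance >= s is at least (s-1)*cwmin away
      if (best < R_PosInf && std::sqrt(best) <= (double)(s - 1) * cwmin) break;
      bool any = false;
      int i0 = std::max(0, ci - s), i1 = std::min(ng[0]-1, ci + s);
      int j0 = std::max(0, cj - s), j1 = std::min(ng[1]-1, cj + s);
      int k0 = std::max(0, ck - s), k1 = std::min(ng[2]-1, ck + s);
      for (int bi = i0; bi <= i1; ++bi)
        for (int bj = j0; bj <= j1; ++bj)
          for (int bk = k0; bk <= k1; ++bk) {
            int ch = std::max(std::abs(bi-ci), std::max(std::abs(bj-cj), std::abs(bk-ck)));
            if (ch != s) continue; // only the new shell
            any = true;
            for (int j : buckets[bidx(bi,bj,bk)]) {
              double dx = px-B(j,0), dy = py-B(j,1), dz = pz-B(j,2);
              double d2 = dx*dx + dy*dy + dz*dz;
              if (d2 < best) best = d2;
            }
          }
      if (!any && best < R_PosInf) break;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
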