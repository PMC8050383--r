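#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
using namespace Rcpp;

// Hole filling: background voxels not reachable from the array border become
// foreground. per_slice fills within each axial (x,y) slice with
// 4-connectivity; otherwise the fill is volumetric with 6-connectivity.

// [[Rcpp::export]]
LogicalVector fill_holes_cpp(const LogicalVector &occ, bool per_slice) {
  IntegerVector dm = occ.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int *o = LOGICAL(occ);
  std::vector<char> reach(n, 0);
  auto idx = [&](int i, int j, int k) { return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k); };

  std::queue<R_xlen_t> q;
  auto push = [&](int i, int j, int k) {
    R_xlen_t t = idx(i, j, k);
    if (!reach[t] && !o[t]) { reach[t] = 1; q.push(t); }
  };

  if (per_slice) {
    for (int k = 0; k < nz; ++k) {
      for (int i = 0; i < nx; ++i) { push(i, 0, k); push(i, ny - 1, k); }
      for (int j = 0; j < ny; ++j) { push(0, j, k); push(nx - 1, j, k); }
      while (!q.empty()) {
        R_xlen_t t = q.front(); q.pop();
        int i = t % nx, j = (t / nx) % ny;
        if (i > 0) push(i - 1, j, k);
        if (i < nx - 1) push(i + 1, j, k);
        if (j > 0) push(i, j - 1, k);
        if (j < ny - 1) push(i, j + 1, k);
      }
    }
  } else {
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) { push(0, j, k); push(nx - 1, j, k); }
    for (int i = 0; i < nx; ++i)
      for (int k = 0; k < nz; ++k) { push(i, 0, k); push(i, ny - 1, k); }
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) { push(i, j, 0); push(i, j, nz - 1); }
    while (!q.empty()) {
      R_xlen_t t = q.front(); q.pop();
      int i = t % nx, j = (t / nx) % ny, k = t / ((R_xlen_t)nx * ny);
      if (i > 0) push(i - 1, j, k);
      if (i < nx - 1) push(i + 1, j, k);
      if (j > 0) push(i, j - 1, k);
      if (j < ny - 1) push(i, j + 1, k);
      if (k > 0) push(i, j, k - 1);
      if (k < nz - 1) push(i, j, k + 1);
    }
  }

  LogicalVector out(n);
  out.attr("dim") = dm;
  for (R_xlen_t t = 0; t < n; ++t) out[t] = o[t] || !reach[t];
  return out;
}

// Connected-component labelling; labels are assigned in order of the lowest
// linear voxel index of each component's seed (label 1 = first seen).
// [[Rcpp::export]]
IntegerVector label_components_cpp(const LogicalVector &occ, int connectivity) {
  IntegerVector dm = occ.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int *o = LOGICAL(occ);
  IntegerVector lab(n);
  lab.attr("dim") = dm;
  std::fill(lab.begin(), lab.end(), 0);

  std::vector<std::array<int,3>> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({di, dj, dk});
      }

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!o[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t t = q.front(); q.pop();
      int i = t % nx, j = (t / nx) % ny, k = t / ((R_xlen_t)nx * ny);
      for (auto &d : offs) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t u = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (o[u] && !lab[u]) { lab[u] = next; q.push(u); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
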