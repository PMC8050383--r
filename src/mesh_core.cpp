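#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline uint64_t ekey(int a, int b) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return ((uint64_t)lo << 32) | (uint32_t)hi;
}

// Signed enclosed volume by the divergence theorem (sum of signed tetrahedra
// against the origin). Positive for outward-oriented closed meshes.
// [[Rcpp::export]]
double mesh_volume_cpp(const NumericMatrix &V, const IntegerMatrix &F) {
  double vol = 0.0;
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f,0), b = F(f,1), c = F(f,2);
    double ax = V(a,0), ay = V(a,1), az = V(a,2);
    double bx = V(b,0), by = V(b,1), bz = V(b,2);
    double cx = V(c,0), cy = V(c,1), cz = V(c,2);
    vol += ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) + az * (bx * cy - by * cx);
  }
  return vol / 6.0;
}

// [[Rcpp::export]]
double mesh_area_cpp(const NumericMatrix &V, const IntegerMatrix &F) {
  double area = 0.0;
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f,0), b = F(f,1), c = F(f,2);
    double ux = V(b,0)-V(a,0), uy = V(b,1)-V(a,1), uz = V(b,2)-V(a,2);
    double vx = V(c,0)-V(a,0), vy = V(c,1)-V(a,1), vz = V(c,2)-V(a,2);
    double nx = uy*vz - uz*vy, ny = uz*vx - ux*vz, nz = ux*vy - uy*vx;
    area += 0.5 * std::sqrt(nx*nx + ny*ny + nz*nz);
  }
  return area;
}

// Centroid of the enclosed volume (not of the surface).
// [[Rcpp::export]]
NumericVector volume_centroid_cpp(const NumericMatrix &V, const IntegerMatrix &F) {
  double vol = 0.0, cx = 0.0, cy = 0.0, cz = 0.0;
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f,0), b = F(f,1), c = F(f,2);
    double ax = V(a,0), ay = V(a,1), az = V(a,2);
    double bx = V(b,0), by = V(b,1), bz = V(b,2);
    double gx = V(c,0), gy = V(c,1), gz = V(c,2);
    double v6 = ax * (by * gz - bz * gy) - ay * (bx * gz - bz * gx) + az * (bx * gy - by * gx);
    vol += v6;
    cx += v6 * (ax + bx + gx);
    cy += v6 * (ay + by + gy);
    cz += v6 * (az + bz + gz);
  }
  // tet centroid = (0 + a + b + c)/4; weights cancel the 1/6 factors
  return NumericVector::create(cx / (4.0 * vol), cy / (4.0 * vol), cz / (4.0 * vol));
}

// Edge census for watertightness / orientation checks.
// An edge is "good" when used exactly once in each direction.
// [[Rcpp::export]]
List edge_report_cpp(const IntegerMatrix &F) {
  std::unordered_map<uint64_t, std::pair<int,int>> em; // key -> (count lo->hi, count hi->lo)
  em.reserve(F.nrow() * 2);
  for (int f = 0; f < F.nrow(); ++f) {
    int vv[3] = {F(f,0), F(f,1), F(f,2)};
    for (int e = 0; e < 3; ++e) {
      int a = vv[e], b = vv[(e+1)%3];
      auto &p = em[ekey(a, b)];
      if (a < b) p.first++; else p.second++;
    }
  }
  int nb = 0, nnm = 0, nmis = 0;
  for (auto &kv : em) {
    int tot = kv.second.first + kv.second.second;
    if (tot == 1) ++nb;
    else if (tot > 2) ++nnm;
    else if (kv.second.first != 1 || kv.second.second != 1) ++nmis; // two faces, same direction
  }
  return List::create(_["n_edges"] = (int)em.size(), _["n_boundary"] = nb,
                      _["n_nonmanifold"] = nnm, _["n_misoriented"] = nmis);
}

// [[Rcpp::export]]
NumericMatrix vertex_normals_cpp(const NumericMatrix &V, const IntegerMatrix &F) {
  NumericMatrix N(V.nrow(), 3);
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f,0), b = F(f,1), c = F(f,2);
    double ux = V(b,0)-V(a,0), uy = V(b,1)-V(a,1), uz = V(b,2)-V(a,2);
    double vx = V(c,0)-V(a,0), vy = V(c,1)-V(a,1), vz = V(c,2)-V(a,2);
    double nx = uy*vz - uz*vy, ny = uz*vx - ux*vz, nz = ux*vy - uy*vx; // area-weighted
    for (int t = 0; t < 3; ++t) {
      int vi = F(f,t);
      N(vi,0) += nx; N(vi,1) += ny; N(vi,2) += nz;
    }
  }
  for (int i = 0; i < N.nrow(); ++i) {
    double L = std::sqrt(N(i,0)*N(i,0) + N(i,1)*N(i,1) + N(i,2)*N(i,2));
    if (L > 0) { N(i,0) /= L; N(i,1) /= L; N(i,2) /= L; }
  }
  return N;
}

// One uniform-weight Laplacian relaxation pass: v <- v + factor * (mean(neighbours) - v).
// [[Rcpp::export]]
NumericMatrix laplacian_pass_cpp(const NumericMatrix &V, const IntegerMatrix &F, double factor) {
  int n = V.nrow();
  std::vector<double> sx(n, 0.0), sy(n, 0.0), sz(n, 0.0);
  std::vector<double> cnt(n, 0.0);
  std::unordered_map<uint64_t, bool> seen;
  seen.reserve(F.nrow() * 2);
  for (int f = 0; f < F.nrow(); ++f) {
    int vv[3] = {F(f,0), F(f,1), F(f,2)};
    for (int e = 0; e < 3; ++e) {
      int a = vv[e], b = vv[(e+1)%3];
      uint64_t k = ekey(a, b);
      if (seen.find(k) != seen.end()) continue;
      seen[k] = true;
      sx[a] += V(b,0); sy[a] += V(b,1); sz[a] += V(b,2); cnt[a] += 1;
      sx[b] += V(a,0); sy[b] += V(a,1); sz[b] += V(a,2); cnt[b] += 1;
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    if (cnt[i] > 0) {
      out(i,0) = V(i,0) + factor * (sx[i] / cnt[i] - V(i,0));
      out(i,1) = V(i,1) + factor * (sy[i] / cnt[i] - V(i,1));
      out(i,2) = V(i,2) + factor * (sz[i] / cnt[i] - V(i,2));
    } else {
      out(i,0) = V(i,0); out(i,1) = V(i,1); out(i,2) = V(i,2);
    }
  }
  return out;
}
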