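#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Parity (even-odd) point-in-mesh classification for a watertight mesh.
// Casts a ray along +x from each query point and counts crossings with the
// triangle set; triangles are bucketed on a 2D (y,z) grid for speed.
// Triangles whose (y,z) projection is degenerate (edge-on to the ray) are
// skipped; such hits are measure-zero and callers jitter their sample grids.

// [[Rcpp::export]]
LogicalVector points_in_mesh_cpp(const NumericMatrix &V, const IntegerMatrix &F,
                                 const NumericMatrix &P) {
  const int nF = F.nrow(), nP = P.nrow();
  LogicalVector out(nP);
  if (nF == 0) { std::fill(out.begin(), out.end(), false); return out; }

  double ylo = R_PosInf, yhi = R_NegInf, zlo = R_PosInf, zhi = R_NegInf;
  for (int i = 0; i < V.nrow(); ++i) {
    ylo = std::min(ylo, V(i,1)); yhi = std::max(yhi, V(i,1));
    zlo = std::min(zlo, V(i,2)); zhi = std::max(zhi, V(i,2));
  }
  double ey = std::max(yhi - ylo, 1e-9), ez = std::max(zhi - zlo, 1e-9);
  int gy = std::max(1, std::min(512, (int)std::sqrt((double)nF / 4.0) + 1));
  int gz = gy;
  auto cy = [&](double y) { return std::max(0, std::min(gy - 1, (int)std::floor((y - ylo) / ey * gy))); };
  auto cz = [&](double z) { return std::max(0, std::min(gz - 1, (int)std::floor((z - zlo) / ez * gz))); };

  std::vector<std::vector<int>> buckets((size_t)gy * gz);
  for (int f = 0; f < nF; ++f) {
    double fy0 = R_PosInf, fy1 = R_NegInf, fz0 = R_PosInf, fz1 = R_NegInf;
    for (int t = 0; t < 3; ++t) {
      int vi = F(f,t);
      fy0 = std::min(fy0, V(vi,1)); fy1 = std::max(fy1, V(vi,1));
      fz0 = std::min(fz0, V(vi,2)); fz1 = std::max(fz1, V(vi,2));
    }
    for (int j = cy(fy0); j <= cy(fy1); ++j)
      for (int k = cz(fz0); k <= cz(fz1); ++k)
        buckets[(size_t)j + (size_t)gy * k].push_back(f);
  }

  for (int p = 0; p < nP; ++p) {
    double px = P(p,0), py = P(p,1), pz = P(p,2);
    if (py < ylo || py > yhi || pz < zlo || pz > zhi) { out[p] = false; continue; }
    int crossings = 0;
    for (int f : buckets[(size_t)cy(py) + (size_t)gy * cz(pz)]) {
      int a = F(f,0), b = F(f,1), c = F(f,2);
      double ay = V(a,1), az = V(a,2), by = V(b,1), bz = V(b,2), gy2 = V(c,1), gz2 = V(c,2);
      // 2D edge functions in the (y,z) projection
      double d0 = (by - ay) * (pz - az) - (bz - az) * (py - ay);
      double d1 = (gy2 - by) * (pz - bz) - (gz2 - bz) * (py - by);
      double d2 = (ay - gy2) * (pz - gz2) - (az - gz2) * (py - gy2);
      bool pos = d0 > 0 && d1 > 0 && d2 > 0;
      bool neg = d0 < 0 && d1 < 0 && d2 < 0;
      if (!pos && !neg) continue;
      // plane: n . (X - A) = 0 ; solve for x at (py, pz)
      double ux = V(b,0)-V(a,0), uy = by-ay, uz = bz-az;
      double vx = V(c,0)-V(a,0), vy = gy2-ay, vz = gz2-az;
      double nx = uy*vz - uz*vy, ny = uz*vx - ux*vz, nz = ux*vy - uy*vx;
      if (nx == 0.0) continue; // projection degenerate w.r.t. the ray
      double x = V(a,0) + (ny * (ay - py) + nz * (az - pz)) / nx;
      if (x > px) ++crossings;
    }
    out[p] = (crossings % 2) == 1;
  }
  return out;
}

// Per-face wall thickness: from each face centroid, cast a ray along the
// inward normal and report the distance to the first intersection with a
// face sharing no vertex with the source face. NA when no hit.
// [[Rcpp::export]]
NumericVector thickness_cpp(const NumericMatrix &V, const IntegerMatrix &F,
                            double eps) {
  const int nF = F.nrow();
  NumericVector out(nF);

  std::vector<double> cxv(nF), cyv(nF), czv(nF), nxv(nF), nyv(nF), nzv(nF), areav(nF);
  std::vector<std::array<double,6>> bbox(nF);
  for (int f = 0; f < nF; ++f) {
    int a = F(f,0), b = F(f,1), c = F(f,2);
    cxv[f] = (V(a,0)+V(b,0)+V(c,0))/3.0;
    cyv[f] = (V(a,1)+V(b,1)+V(c,1))/3.0;
    czv[f] = (V(a,2)+V(b,2)+V(c,2))/3.0;
    double ux = V(b,0)-V(a,0), uy = V(b,1)-V(a,1), uz = V(b,2)-V(a,2);
    double vx = V(c,0)-V(a,0), vy = V(c,1)-V(a,1), vz = V(c,2)-V(a,2);
    double nx = uy*vz-uz*vy, ny = uz*vx-ux*vz, nz = ux*vy-uy*vx;
    double L = std::sqrt(nx*nx+ny*ny+nz*nz);
    areav[f] = 0.5*L;
    if (L > 0) { nx/=L; ny/=L; nz/=L; }
    nxv[f]=nx; nyv[f]=ny; nzv[f]=nz;
    bbox[f] = { std::min({V(a,0),V(b,0),V(c,0)}), std::max({V(a,0),V(b,0),V(c,0)}),
                std::min({V(a,1),V(b,1),V(c,1)}), std::max({V(a,1),V(b,1),V(c,1)}),
                std::min({V(a,2),V(b,2),V(c,2)}), std::max({V(a,2),V(b,2),V(c,2)}) };
  }

  // uniform 3D grid over the mesh bbox; triangles binned by their bboxes,
  // rays walk cells front-to-back (3D-DDA) and stop at the first hit
  double lo3[3] = {R_PosInf, R_PosInf, R_PosInf}, hi3[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      lo3[d] = std::min(lo3[d], V(i,d));
      hi3[d] = std::max(hi3[d], V(i,d));
    }
  double ext3[3], volb = 1.0;
  for (int d = 0; d < 3; ++d) {
    ext3[d] = std::max(hi3[d] - lo3[d], 1e-9);
    volb *= ext3[d];
  }
  double hcell = std::cbrt(volb / std::max(nF, 1)) * 2.0;
  int ng[3];
  for (int d = 0; d < 3; ++d)
    ng[d] = std::max(1, std::min(128, (int)std::floor(ext3[d] / hcell) + 1));
  double cw3[3];
  for (int d = 0; d < 3; ++d) cw3[d] = ext3[d] / ng[d];
  auto cellOf = [&](double x, int d) {
    return std::max(0, std::min(ng[d] - 1, (int)std::floor((x - lo3[d]) / cw3[d])));
  };
  std::vector<std::vector<int>> grid((size_t)ng[0] * ng[1] * ng[2]);
  auto gidx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)ng[0] * ((size_t)j + (size_t)ng[1] * k);
  };
  for (int g = 0; g < nF; ++g)
    for (int i = cellOf(bbox[g][0],0); i <= cellOf(bbox[g][1],0); ++i)
      for (int j = cellOf(bbox[g][2],1); j <= cellOf(bbox[g][3],1); ++j)
        for (int k = cellOf(bbox[g][4],2); k <= cellOf(bbox[g][5],2); ++k)
          grid[gidx(i,j,k)].push_back(g);
  std::vector<int> stamp(nF, -1);

  for (int f = 0; f < nF; ++f) {
    if (areav[f] < 1e-12) { out[f] = NA_REAL; continue; }
    double ox = cxv[f], oy = cyv[f], oz = czv[f];
    double dir3[3] = {-nxv[f], -nyv[f], -nzv[f]}; // inward
    double org3[3] = {ox, oy, oz};
    int fa = F(f,0), fb = F(f,1), fc = F(f,2);
    double best = R_PosInf;

    auto testTri = [&](int g) {
      if (g == f || areav[g] < 1e-12) return;
      if (stamp[g] == f) return;
      stamp[g] = f;
      int ga = F(g,0), gb = F(g,1), gc = F(g,2);
      if (ga==fa||ga==fb||ga==fc||gb==fa||gb==fb||gb==fc||gc==fa||gc==fb||gc==fc)
        return; // vertex-adjacent faces are not the "other wall"
      double dx = dir3[0], dy = dir3[1], dz = dir3[2];
      double e1x = V(gb,0)-V(ga,0), e1y = V(gb,1)-V(ga,1), e1z = V(gb,2)-V(ga,2);
      double e2x = V(gc,0)-V(ga,0), e2y = V(gc,1)-V(ga,1), e2z = V(gc,2)-V(ga,2);
      double px2 = dy*e2z - dz*e2y, py2 = dz*e2x - dx*e2z, pz2 = dx*e2y - dy*e2x;
      double det = e1x*px2 + e1y*py2 + e1z*pz2;
      if (std::fabs(det) < 1e-14) return;
      double inv = 1.0/det;
      double tx = ox - V(ga,0), ty = oy - V(ga,1), tz = oz - V(ga,2);
      double u = (tx*px2 + ty*py2 + tz*pz2) * inv;
      if (u < -1e-12 || u > 1.0 + 1e-12) return;
      double qx = ty*e1z - tz*e1y, qy = tz*e1x - tx*e1z, qz = tx*e1y - ty*e1x;
      double w = (dx*qx + dy*qy + dz*qz) * inv;
      if (w < -1e-12 || u + w > 1.0 + 1e-12) return;
      double t = (e2x*qx + e2y*qy + e2z*qz) * inv;
      if (t > eps && t < best) best = t;
    };

    // 3D-DDA through the grid
    int ci[3];
    double tMax[3], tDelta[3];
    int step[3];
    for (int d = 0; d < 3; ++d) {
      ci[d] = cellOf(org3[d], d);
      if (dir3[d] > 1e-14) {
        step[d] = 1;
        tMax[d] = (lo3[d] + (ci[d] + 1) * cw3[d] - org3[d]) / dir3[d];
        tDelta[d] = cw3[d] / dir3[d];
      } else if (dir3[d] < -1e-14) {
        step[d] = -1;
        tMax[d] = (lo3[d] + ci[d] * cw3[d] - org3[d]) / dir3[d];
        tDelta[d] = -cw3[d] / dir3[d];
      } else {
        step[d] = 0;
        tMax[d] = R_PosInf;
        tDelta[d] = R_PosInf;
      }
    }
    double tExit = 0.0;
    while (true) {
      for (int t : grid[gidx(ci[0], ci[1], ci[2])]) testTri(t);
      int ax = 0;
      if (tMax[1] < tMax[ax]) ax = 1;
      if (tMax[2] < tMax[ax]) ax = 2;
      tExit = tMax[ax];
      if (best < tExit) break; // hit before leaving scanned cells
      ci[ax] += step[ax];
      if (ci[ax] < 0 || ci[ax] >= ng[ax]) break;
      tMax[ax] += tDelta[ax];
    }
    out[f] = std::isfinite(best) ? best : NA_REAL;
  }
  return out;
}
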