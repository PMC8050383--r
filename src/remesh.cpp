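#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// Incremental isotropic remeshing (split / collapse / flip / tangential
// relaxation) targeting a uniform edge length, with feature-edge
// preservation: edges whose adjacent-face dihedral angle exceeds the sharp
// angle are detected on the input mesh and constrained as polylines --
// their vertices move only along the line, polyline junction/corner
// vertices are fixed, and feature edges are never flipped or crossed.

namespace {

typedef std::array<double,3> V3;

inline V3 sub(const V3 &a, const V3 &b) { return {a[0]-b[0], a[1]-b[1], a[2]-b[2]}; }
inline V3 add(const V3 &a, const V3 &b) { return {a[0]+b[0], a[1]+b[1], a[2]+b[2]}; }
inline V3 scl(const V3 &a, double s) { return {a[0]*s, a[1]*s, a[2]*s}; }
inline double dot(const V3 &a, const V3 &b) { return a[0]*b[0]+a[1]*b[1]+a[2]*b[2]; }
inline V3 cross(const V3 &a, const V3 &b) {
  return {a[1]*b[2]-a[2]*b[1], a[2]*b[0]-a[0]*b[2], a[0]*b[1]-a[1]*b[0]};
}
inline double norm(const V3 &a) { return std::sqrt(dot(a,a)); }
inline V3 normalize(const V3 &a) {
  double L = norm(a);
  return L > 0 ? scl(a, 1.0/L) : a;
}

struct Mesh {
  std::vector<V3> pos;
  std::vector<std::array<int,3>> tri;      // tri[0] == -1 when dead
  std::vector<std::vector<int>> v2t;       // vertex -> incident (alive) tris
  std::vector<int> lvl;                    // 0 free, 1 feature line, 2 corner
  std::vector<std::vector<int>> fadj;      // feature-edge adjacency

  bool alive(int t) const { return tri[t][0] >= 0; }

  V3 faceNormal(int t) const {
    const auto &f = tri[t];
    return cross(sub(pos[f[1]], pos[f[0]]), sub(pos[f[2]], pos[f[0]]));
  }

  void rebuildV2T() {
    for (auto &l : v2t) l.clear();
    v2t.resize(pos.size());
    for (size_t t = 0; t < tri.size(); ++t)
      if (alive(t))
        for (int e = 0; e < 3; ++e) v2t[tri[t][e]].push_back((int)t);
  }

  bool isFeatureEdge(int u, int v) const {
    for (int x : fadj[u]) if (x == v) return true;
    return false;
  }
  void addFeature(int u, int v) {
    if (!isFeatureEdge(u, v)) { fadj[u].push_back(v); fadj[v].push_back(u); }
  }
  void dropFeature(int u, int v) {
    auto rm = [](std::vector<int> &a, int x) {
      a.erase(std::remove(a.begin(), a.end(), x), a.end());
    };
    rm(fadj[u], v); rm(fadj[v], u);
  }
};

inline uint64_t ukey(int a, int b) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return ((uint64_t)lo << 32) | (uint32_t)hi;
}

void detectFeatures(Mesh &m, double sharpDeg) {
  std::unordered_map<uint64_t, std::array<int,2>> e2t;
  for (size_t t = 0; t < m.tri.size(); ++t) {
    for (int e = 0; e < 3; ++e) {
      uint64_t k = ukey(m.tri[t][e], m.tri[t][(e+1)%3]);
      auto it = e2t.find(k);
      if (it == e2t.end()) e2t[k] = {(int)t, -1};
      else it->second[1] = (int)t;
    }
  }
  double cosTh = std::cos(sharpDeg * M_PI / 180.0);
  m.fadj.assign(m.pos.size(), {});
  for (auto &kv : e2t) {
    if (kv.second[1] < 0) continue;
    V3 n1 = normalize(m.faceNormal(kv.second[0]));
    V3 n2 = normalize(m.faceNormal(kv.second[1]));
    if (dot(n1, n2) < cosTh) {
      int u = (int)(kv.first >> 32), v = (int)(kv.first & 0xffffffffu);
      m.addFeature(u, v);
    }
  }
  m.lvl.assign(m.pos.size(), 0);
  for (size_t i = 0; i < m.pos.size(); ++i) {
    size_t d = m.fadj[i].size();
    if (d == 2) m.lvl[i] = 1;
    else if (d > 0) m.lvl[i] = 2;
  }
}

int splitPass(Mesh &m, double high) {
  std::unordered_map<uint64_t, int> mid; // edge -> midpoint vertex
  for (size_t t = 0; t < m.tri.size(); ++t) {
    if (!m.alive(t)) continue;
    for (int e = 0; e < 3; ++e) {
      int a = m.tri[t][e], b = m.tri[t][(e+1)%3];
      uint64_t k = ukey(a, b);
      if (mid.count(k)) continue;
      if (norm(sub(m.pos[a], m.pos[b])) > high) {
        int nv = (int)m.pos.size();
        m.pos.push_back(scl(add(m.pos[a], m.pos[b]), 0.5));
        bool fe = m.isFeatureEdge(a, b);
        m.lvl.push_back(fe ? 1 : 0);
        m.fadj.push_back({});
        if (fe) {
          m.dropFeature(a, b);
          m.addFeature(a, nv);
          m.addFeature(nv, b);
        }
        mid[k] = nv;
      }
    }
  }
  if (mid.empty()) return 0;
  std::vector<std::array<int,3>> fresh;
  for (size_t t = 0; t < m.tri.size(); ++t) {
    if (!m.alive(t)) continue;
    int a = m.tri[t][0], b = m.tri[t][1], c = m.tri[t][2];
    auto gm = [&](int u, int v) -> int {
      auto it = mid.find(ukey(u, v));
      return it == mid.end() ? -1 : it->second;
    };
    int mab = gm(a,b), mbc = gm(b,c), mca = gm(c,a);
    int s = (mab >= 0) + (mbc >= 0) + (mca >= 0);
    if (s == 0) continue;
    m.tri[t][0] = -1;
    if (s == 3) {
      fresh.push_back({a, mab, mca});
      fresh.push_back({mab, b, mbc});
      fresh.push_back({mca, mbc, c});
      fresh.push_back({mab, mbc, mca});
    } else if (s == 1) {
      // rotate so split edge is (a,b)
      if (mbc >= 0) { int t0=a; a=b; b=c; c=t0; mab=mbc; }
      else if (mca >= 0) { int t0=c; c=b; b=a; a=t0; mab=mca; }
      fresh.push_back({a, mab, c});
      fresh.push_back({mab, b, c});
    } else { // s == 2: rotate so the unsplit edge is (c,a)
      if (mab < 0) { int t0 = a; a = b; b = c; c = t0; mab = mbc; mbc = mca; }
      else if (mbc < 0) { int t0 = c; c = b; b = a; a = t0; int q = mab; mab = mca; mbc = q; }
      fresh.push_back({a, mab, c});
      fresh.push_back({mab, b, mbc});
      fresh.push_back({mab, mbc, c});
    }
  }
  for (auto &f : fresh) m.tri.push_back(f);
  m.rebuildV2T();
  return (int)mid.size();
}

int collapsePass(Mesh &m, double low, double high) {
  struct Cand { double len; int u, v; };
  std::vector<Cand> cands;
  std::unordered_map<uint64_t, bool> seen;
  for (size_t t = 0; t < m.tri.size(); ++t) {
    if (!m.alive(t)) continue;
    for (int e = 0; e < 3; ++e) {
      int a = m.tri[t][e], b = m.tri[t][(e+1)%3];
      uint64_t k = ukey(a, b);
      if (seen.count(k)) continue;
      seen[k] = true;
      double L = norm(sub(m.pos[a], m.pos[b]));
      if (L < low) cands.push_back({L, a, b});
    }
  }
  std::sort(cands.begin(), cands.end(),
            [](const Cand &x, const Cand &y) { return x.len < y.len; });

  std::vector<char> dead(m.pos.size(), 0);
  int done = 0;
  for (auto &cd : cands) {
    int u = cd.u, v = cd.v;
    if (dead[u] || dead[v]) continue;
    double L = norm(sub(m.pos[u], m.pos[v]));
    if (L >= low) continue;

    bool fe = m.isFeatureEdge(u, v);
    if (!fe && m.lvl[u] >= 1 && m.lvl[v] >= 1) continue; // would pinch a feature
    if (fe && m.lvl[u] == 2 && m.lvl[v] == 2) continue;  // cannot merge corners

    // survivor position / level
    V3 npos;
    int nlvl;
    if (fe) {
      if (m.lvl[u] == 2) { npos = m.pos[u]; nlvl = 2; }
      else if (m.lvl[v] == 2) { npos = m.pos[v]; nlvl = 2; }
      else { npos = scl(add(m.pos[u], m.pos[v]), 0.5); nlvl = 1; }
      // shared feature neighbour would create a degenerate feature triangle
      bool shared = false;
      for (int x : m.fadj[u]) if (x != v)
        for (int y : m.fadj[v]) if (y == x) shared = true;
      if (shared) continue;
    } else {
      if (m.lvl[u] >= 1) { npos = m.pos[u]; nlvl = m.lvl[u]; }
      else if (m.lvl[v] >= 1) { npos = m.pos[v]; nlvl = m.lvl[v]; }
      else { npos = scl(add(m.pos[u], m.pos[v]), 0.5); nlvl = 0; }
    }

    // tris on the edge, and link condition
    std::vector<int> edgeTris;
    for (int t : m.v2t[u]) {
      const auto &f = m.tri[t];
      if (f[0] == v || f[1] == v || f[2] == v) edgeTris.push_back(t);
    }
    if (edgeTris.size() != 2) continue;
    std::vector<int> opp;
    for (int t : edgeTris)
      for (int e = 0; e < 3; ++e)
        if (m.tri[t][e] != u && m.tri[t][e] != v) opp.push_back(m.tri[t][e]);
    auto nbrs = [&](int w) {
      std::vector<int> r;
      for (int t : m.v2t[w])
        for (int e = 0; e < 3; ++e)
          if (m.tri[t][e] != w) r.push_back(m.tri[t][e]);
      std::sort(r.begin(), r.end());
      r.erase(std::unique(r.begin(), r.end()), r.end());
      return r;
    };
    std::vector<int> nu = nbrs(u), nv = nbrs(v), common;
    std::set_intersection(nu.begin(), nu.end(), nv.begin(), nv.end(),
                          std::back_inserter(common));
    bool linkOk = true;
    for (int w : common)
      if (std::find(opp.begin(), opp.end(), w) == opp.end()) linkOk = false;
    if (!linkOk) continue;

    // geometry guard: no normal flips, no degenerate faces, no overlong edges
    bool ok = true;
    for (int w : {u, v}) {
      for (int t : m.v2t[w]) {
        const auto &f = m.tri[t];
        bool onEdge = std::find(edgeTris.begin(), edgeTris.end(), t) != edgeTris.end();
        if (onEdge) continue;
        V3 p[3], q[3];
        for (int e = 0; e < 3; ++e) {
          p[e] = m.pos[f[e]];
          q[e] = (f[e] == u || f[e] == v) ? npos : m.pos[f[e]];
        }
        V3 n0 = cross(sub(p[1],p[0]), sub(p[2],p[0]));
        V3 n1 = cross(sub(q[1],q[0]), sub(q[2],q[0]));
        if (norm(n1) < 1e-12 || dot(n0, n1) <= 0) { ok = false; break; }
        for (int e = 0; e < 3; ++e)
          if (norm(sub(q[e], q[(e+1)%3])) > high * 1.2) { ok = false; break; }
        if (!ok) break;
      }
      if (!ok) break;
    }
    if (!ok) continue;

    // execute: collapse v into u
    m.pos[u] = npos;
    m.lvl[u] = nlvl;
    if (fe) m.dropFeature(u, v);
    // re-home v's feature adjacency
    std::vector<int> vf = m.fadj[v];
    for (int x : vf) {
      m.dropFeature(v, x);
      if (x != u) m.addFeature(u, x);
    }
    for (int t : edgeTris) m.tri[t][0] = -1;
    std::vector<int> moved;
    for (int t : m.v2t[v]) {
      if (!m.alive(t)) continue;
      for (int e = 0; e < 3; ++e)
        if (m.tri[t][e] == v) m.tri[t][e] = u;
      moved.push_back(t);
    }
    // refresh incidence of u (drop dead, add moved)
    std::vector<int> nu2;
    for (int t : m.v2t[u]) if (m.alive(t)) nu2.push_back(t);
    for (int t : moved) nu2.push_back(t);
    std::sort(nu2.begin(), nu2.end());
    nu2.erase(std::unique(nu2.begin(), nu2.end()), nu2.end());
    m.v2t[u] = nu2;
    m.v2t[v].clear();
    // opposite vertices lost incident tris
    for (int w : opp) {
      std::vector<int> r;
      for (int t : m.v2t[w]) if (m.alive(t)) r.push_back(t);
      m.v2t[w] = r;
    }
    dead[v] = 1;
    dead[u] = 1; // treat as dirty for the rest of this pass
    ++done;
  }
  return done;
}

int flipPass(Mesh &m) {
  // valences
  std::vector<int> val(m.pos.size(), 0);
  {
    std::unordered_map<uint64_t, bool> seen;
    for (size_t t = 0; t < m.tri.size(); ++t) {
      if (!m.alive(t)) continue;
      for (int e = 0; e < 3; ++e) {
        int a = m.tri[t][e], b = m.tri[t][(e+1)%3];
        uint64_t k = ukey(a, b);
        if (seen.count(k)) continue;
        seen[k] = true;
        ++val[a]; ++val[b];
      }
    }
  }
  std::unordered_map<uint64_t, std::array<int,2>> e2t;
  for (size_t t = 0; t < m.tri.size(); ++t) {
    if (!m.alive(t)) continue;
    for (int e = 0; e < 3; ++e) {
      uint64_t k = ukey(m.tri[t][e], m.tri[t][(e+1)%3]);
      auto it = e2t.find(k);
      if (it == e2t.end()) e2t[k] = {(int)t, -1};
      else it->second[1] = (int)t;
    }
  }
  auto sq = [](int x) { return x * x; };
  int done = 0;
  std::vector<char> touched(m.tri.size(), 0);
  for (auto &kv : e2t) {
    int t1 = kv.second[0], t2 = kv.second[1];
    if (t2 < 0 || !m.alive(t1) || !m.alive(t2) || touched[t1] || touched[t2]) continue;
    int u = (int)(kv.first >> 32), v = (int)(kv.first & 0xffffffffu);
    if (m.isFeatureEdge(u, v) || m.lvl[u] == 2 || m.lvl[v] == 2) continue;
    // orient: t1 = (u,v,a) with directed edge u->v, t2 = (v,u,b)
    auto orient = [&](int t, int s0, int s1) -> int {
      const auto &f = m.tri[t];
      for (int e = 0; e < 3; ++e)
        if (f[e] == s0 && f[(e+1)%3] == s1) return f[(e+2)%3];
      return -1;
    };
    int a = orient(t1, u, v), b = orient(t2, v, u);
    if (a < 0) { std::swap(t1, t2); a = orient(t1, u, v); b = orient(t2, v, u); }
    if (a < 0 || b < 0) continue;
    int before = sq(val[u]-6) + sq(val[v]-6) + sq(val[a]-6) + sq(val[b]-6);
    // u,v lose an edge; a,b gain one
    int after = sq(val[u]-1-6) + sq(val[v]-1-6) + sq(val[a]+1-6) + sq(val[b]+1-6);
    if (after >= before) continue;
    if (m.isFeatureEdge(a, b)) continue;
    // a-b must not already be an edge
    bool exists = false;
    for (int t : m.v2t[a]) {
      const auto &f = m.tri[t];
      if (f[0] == b || f[1] == b || f[2] == b) exists = true;
    }
    if (exists) continue;
    V3 n1o = m.faceNormal(t1), n2o = m.faceNormal(t2);
    V3 nav = normalize(add(normalize(n1o), normalize(n2o)));
    V3 pa = m.pos[a], pb = m.pos[b], pu = m.pos[u], pv = m.pos[v];
    V3 n1n = cross(sub(pu,pa), sub(pb,pa)); // tri (a,u,b)
    V3 n2n = cross(sub(pv,pb), sub(pa,pb)); // tri (b,v,a)
    if (norm(n1n) < 1e-12 || norm(n2n) < 1e-12) continue;
    if (dot(normalize(n1n), nav) < 0.3 || dot(normalize(n2n), nav) < 0.3) continue;
    // execute
    m.tri[t1] = {a, u, b};
    m.tri[t2] = {b, v, a};
    touched[t1] = touched[t2] = 1;
    auto rmT = [&](int w, int t) {
      auto &l = m.v2t[w];
      l.erase(std::remove(l.begin(), l.end(), t), l.end());
    };
    rmT(v, t1); rmT(u, t2);
    m.v2t[a].push_back(t2); m.v2t[b].push_back(t1);
    --val[u]; --val[v]; ++val[a]; ++val[b];
    ++done;
  }
  return done;
}

void relaxPass(Mesh &m, double lambda) {
  // area-weighted vertex normals
  std::vector<V3> vn(m.pos.size(), {0,0,0});
  for (size_t t = 0; t < m.tri.size(); ++t) {
    if (!m.alive(t)) continue;
    V3 n = m.faceNormal(t);
    for (int e = 0; e < 3; ++e) vn[m.tri[t][e]] = add(vn[m.tri[t][e]], n);
  }
  std::vector<V3> cen(m.pos.size(), {0,0,0});
  std::vector<double> cnt(m.pos.size(), 0.0);
  std::unordered_map<uint64_t, bool> seen;
  for (size_t t = 0; t < m.tri.size(); ++t) {
    if (!m.alive(t)) continue;
    for (int e = 0; e < 3; ++e) {
      int a = m.tri[t][e], b = m.tri[t][(e+1)%3];
      uint64_t k = ukey(a, b);
      if (seen.count(k)) continue;
      seen[k] = true;
      cen[a] = add(cen[a], m.pos[b]); cnt[a] += 1;
      cen[b] = add(cen[b], m.pos[a]); cnt[b] += 1;
    }
  }
  std::vector<V3> np = m.pos;
  for (size_t i = 0; i < m.pos.size(); ++i) {
    if (cnt[i] == 0 || m.lvl[i] == 2) continue;
    if (m.lvl[i] == 1) {
      if (m.fadj[i].size() != 2) continue;
      V3 mid = scl(add(m.pos[m.fadj[i][0]], m.pos[m.fadj[i][1]]), 0.5);
      V3 d = scl(sub(mid, m.pos[i]), lambda);
      V3 tdir = normalize(sub(m.pos[m.fadj[i][0]], m.pos[m.fadj[i][1]]));
      np[i] = add(m.pos[i], scl(tdir, dot(d, tdir)));
    } else {
      V3 c = scl(cen[i], 1.0 / cnt[i]);
      V3 d = scl(sub(c, m.pos[i]), lambda);
      V3 n = normalize(vn[i]);
      np[i] = add(m.pos[i], sub(d, scl(n, dot(d, n))));
    }
  }
  m.pos = np;
}

} // namespace

// [[Rcpp::export]]
List remesh_cpp(const NumericMatrix &V, const IntegerMatrix &F,
                double target, double sharp_deg, int iterations) {
  Mesh m;
  m.pos.resize(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) m.pos[i] = {V(i,0), V(i,1), V(i,2)};
  m.tri.resize(F.nrow());
  for (int t = 0; t < F.nrow(); ++t) m.tri[t] = {F(t,0), F(t,1), F(t,2)};
  detectFeatures(m, sharp_deg);
  m.rebuildV2T();

  const double high = target * 4.0 / 3.0, low = target * 4.0 / 5.0;
  for (int it = 0; it < iterations; ++it) {
    int ns = splitPass(m, high);
    int nc = collapsePass(m, low, high);
    m.rebuildV2T();
    int nf = flipPass(m);
    relaxPass(m, 0.5);
    if (ns == 0 && nc == 0 && nf == 0) {
      relaxPass(m, 0.5);
      break;
    }
  }

  // compact
  std::vector<int> vmap(m.pos.size(), -1);
  std::vector<V3> vp;
  std::vector<std::array<int,3>> ft;
  for (size_t t = 0; t < m.tri.size(); ++t) {
    if (!m.alive(t)) continue;
    std::array<int,3> f;
    for (int e = 0; e < 3; ++e) {
      int v = m.tri[t][e];
      if (vmap[v] < 0) { vmap[v] = (int)vp.size(); vp.push_back(m.pos[v]); }
      f[e] = vmap[v];
    }
    ft.push_back(f);
  }
  NumericMatrix Vo(vp.size(), 3);
  for (size_t i = 0; i < vp.size(); ++i)
    for (int d = 0; d < 3; ++d) Vo(i, d) = vp[i][d];
  IntegerMatrix Fo(ft.size(), 3);
  for (size_t t = 0; t < ft.size(); ++t)
    for (int e = 0; e < 3; ++e) Fo(t, e) = ft[t][e];
  return List::create(_["vertices"] = Vo, _["faces"] = Fo);
}
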