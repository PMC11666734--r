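// Geometry kernels: point-to-triangle projection, a uniform-grid closest-point
// structure over a triangle soup, vertex/face normals, topology queries
// (components, boundary loops, watertightness) and incremental isotropic
// remeshing (edge split / collapse / flip + tangential relaxation with
// back-projection onto the input surface).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>
#include <functional>
#include <cstdint>

using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
  V3 operator+(const V3& o) const { return V3(x + o.x, y + o.y, z + o.z); }
  V3 operator-(const V3& o) const { return V3(x - o.x, y - o.y, z - o.z); }
  V3 operator*(double s) const { return V3(x * s, y * s, z * s); }
};
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

// Ericson, Real-Time Collision Detection, 5.1.5
static V3 closestPointTriangle(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// ---- uniform grid over triangles ------------------------------------------

struct TriGrid {
  std::vector<V3> verts;
  std::vector<std::array<int, 3>> faces;
  V3 lo, hi;
  double h;            // cell size
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;  // face indices per cell
  mutable std::vector<int> stamp;       // per-face visit stamp
  mutable int stampVal;

  int cellIndex(int i, int j, int k) const { return (k * ny + j) * nx + i; }

  void build(const NumericMatrix& V, const IntegerMatrix& F) {
    int nV = V.nrow(), nF = F.nrow();
    verts.resize(nV);
    for (int i = 0; i < nV; i++) verts[i] = V3(V(i, 0), V(i, 1), V(i, 2));
    faces.resize(nF);
    for (int i = 0; i < nF; i++) faces[i] = {F(i, 0), F(i, 1), F(i, 2)};
    lo = V3(R_PosInf, R_PosInf, R_PosInf);
    hi = V3(R_NegInf, R_NegInf, R_NegInf);
    for (auto& v : verts) {
      lo.x = std::min(lo.x, v.x); lo.y = std::min(lo.y, v.y); lo.z = std::min(lo.z, v.z);
      hi.x = std::max(hi.x, v.x); hi.y = std::max(hi.y, v.y); hi.z = std::max(hi.z, v.z);
    }
    V3 ext = hi - lo;
    double diag = std::max(1e-12, norm(ext));
    // aim for ~2 faces per occupied cell
    double vol = std::max(ext.x, 1e-6 * diag) * std::max(ext.y, 1e-6 * diag) *
                 std::max(ext.z, 1e-6 * diag);
    h = std::cbrt(vol / std::max(1, nF / 2));
    h = std::max(h, 1e-6 * diag);
    nx = std::max(1, std::min(128, (int)std::ceil(ext.x / h)));
    ny = std::max(1, std::min(128, (int)std::ceil(ext.y / h)));
    nz = std::max(1, std::min(128, (int)std::ceil(ext.z / h)));
    cells.assign((size_t)nx * ny * nz, {});
    for (int f = 0; f < nF; f++) {
      V3 a = verts[faces[f][0]], b = verts[faces[f][1]], c = verts[faces[f][2]];
      V3 flo(std::min({a.x, b.x, c.x}), std::min({a.y, b.y, c.y}), std::min({a.z, b.z, c.z}));
      V3 fhi(std::max({a.x, b.x, c.x}), std::max({a.y, b.y, c.y}), std::max({a.z, b.z, c.z}));
      int i0 = clampc((flo.x - lo.x) / hx(), nx), i1 = clampc((fhi.x - lo.x) / hx(), nx);
      int j0 = clampc((flo.y - lo.y) / hy(), ny), j1 = clampc((fhi.y - lo.y) / hy(), ny);
      int k0 = clampc((flo.z - lo.z) / hz(), nz), k1 = clampc((fhi.z - lo.z) / hz(), nz);
      for (int k = k0; k <= k1; k++)
        for (int j = j0; j <= j1; j++)
          for (int i = i0; i <= i1; i++) cells[cellIndex(i, j, k)].push_back(f);
    }
    stamp.assign(nF, -1);
    stampVal = 0;
  }
  double hx() const { return (hi.x - lo.x) > 0 ? (hi.x - lo.x) / nx : 1.0; }
  double hy() const { return (hi.y - lo.y) > 0 ? (hi.y - lo.y) / ny : 1.0; }
  double hz() const { return (hi.z - lo.z) > 0 ? (hi.z - lo.z) / nz : 1.0; }
  static int clampc(double v, int n) {
    int i = (int)std::floor(v);
    return std::max(0, std::min(n - 1, i));
  }

  // closest point on the soup; returns face index, fills cp and dist
  int query(const V3& q, V3& cp, double& best) const {
    ++stampVal;
    best = R_PosInf;
    int bestFace = -1;
    double hmin = std::min({hx(), hy(), hz()});
    int qi = std::max(0, std::min(nx - 1, (int)std::floor((q.x - lo.x) / hx())));
    int qj = std::max(0, std::min(ny - 1, (int)std::floor((q.y - lo.y) / hy())));
    int qk = std::max(0, std::min(nz - 1, (int)std::floor((q.z - lo.z) / hz())));
    int rmax = std::max({nx, ny, nz});
    for (int r = 0; r <= rmax; r++) {
      // cells whose Chebyshev ring index is r
      bool any = false;
      int i0 = std::max(0, qi - r), i1 = std::min(nx - 1, qi + r);
      int j0 = std::max(0, qj - r), j1 = std::min(ny - 1, qj + r);
      int k0 = std::max(0, qk - r), k1 = std::min(nz - 1, qk + r);
      for (int k = k0; k <= k1; k++)
        for (int j = j0; j <= j1; j++)
          for (int i = i0; i <= i1; i++) {
            if (std::max({std::abs(i - qi), std::abs(j - qj), std::abs(k - qk)}) != r) continue;
            any = true;
            for (int f : cells[cellIndex(i, j, k)]) {
              if (stamp[f] == stampVal) continue;
              stamp[f] = stampVal;
              V3 p = closestPointTriangle(q, verts[faces[f][0]], verts[faces[f][1]],
                                          verts[faces[f][2]]);
              double d = norm(p - q);
              if (d < best) { best = d; cp = p; bestFace = f; }
            }
          }
      // cells at ring r+1 or beyond are at least r*hmin from q
      if (bestFace >= 0 && best <= (double)r * hmin) break;
      if (!any && bestFace >= 0) break;  // rings are exhausted outside the grid
    }
    return bestFace;
  }
};

static void finalizeGrid(SEXP p) {
  TriGrid* g = (TriGrid*)R_ExternalPtrAddr(p);
  if (g) { delete g; R_ClearExternalPtr(p); }
}

// [[Rcpp::export]]
SEXP cpg_build(NumericMatrix V, IntegerMatrix F) {
  TriGrid* g = new TriGrid();
  g->build(V, F);
  SEXP p = PROTECT(R_MakeExternalPtr(g, R_NilValue, R_NilValue));
  R_RegisterCFinalizerEx(p, finalizeGrid, TRUE);
  UNPROTECT(1);
  return p;
}

// [[Rcpp::export]]
List cpg_query(SEXP ptr, NumericMatrix Q) {
  TriGrid* g = (TriGrid*)R_ExternalPtrAddr(ptr);
  if (!g) stop("stale closest-point structure");
  int n = Q.nrow();
  NumericMatrix P(n, 3);
  NumericVector D(n);
  IntegerVector Fi(n);
  for (int i = 0; i < n; i++) {
    V3 cp; double d;
    int f = g->query(V3(Q(i, 0), Q(i, 1), Q(i, 2)), cp, d);
    P(i, 0) = cp.x; P(i, 1) = cp.y; P(i, 2) = cp.z;
    D[i] = d; Fi[i] = f;
  }
  return List::create(_["points"] = P, _["dist"] = D, _["face"] = Fi);
}

// [[Rcpp::export]]
NumericMatrix cpp_face_normals(NumericMatrix V, IntegerMatrix F) {
  int nF = F.nrow();
  NumericMatrix N(nF, 3);
  for (int f = 0; f < nF; f++) {
    V3 a(V(F(f, 0), 0), V(F(f, 0), 1), V(F(f, 0), 2));
    V3 b(V(F(f, 1), 0), V(F(f, 1), 1), V(F(f, 1), 2));
    V3 c(V(F(f, 2), 0), V(F(f, 2), 1), V(F(f, 2), 2));
    V3 n = cross(b - a, c - a);
    double l = norm(n);
    if (l > 0) n = n * (1.0 / l);
    N(f, 0) = n.x; N(f, 1) = n.y; N(f, 2) = n.z;
  }
  return N;
}

// area-weighted vertex normals
// [[Rcpp::export]]
NumericMatrix cpp_vertex_normals(NumericMatrix V, IntegerMatrix F) {
  int nV = V.nrow(), nF = F.nrow();
  NumericMatrix N(nV, 3);
  for (int f = 0; f < nF; f++) {
    V3 a(V(F(f, 0), 0), V(F(f, 0), 1), V(F(f, 0), 2));
    V3 b(V(F(f, 1), 0), V(F(f, 1), 1), V(F(f, 1), 2));
    V3 c(V(F(f, 2), 0), V(F(f, 2), 1), V(F(f, 2), 2));
    V3 n = cross(b - a, c - a);  // |n| = 2*area
    for (int k = 0; k < 3; k++) {
      int v = F(f, k);
      N(v, 0) += n.x; N(v, 1) += n.y; N(v, 2) += n.z;
    }
  }
  for (int v = 0; v < nV; v++) {
    double l = std::sqrt(N(v, 0) * N(v, 0) + N(v, 1) * N(v, 1) + N(v, 2) * N(v, 2));
    if (l > 0) { N(v, 0) /= l; N(v, 1) /= l; N(v, 2) /= l; }
  }
  return N;
}

// connected components over vertices linked by faces; 1-based labels
// [[Rcpp::export]]
IntegerVector cpp_vertex_components(int nV, IntegerMatrix F) {
  std::vector<int> parent(nV);
  for (int i = 0; i < nV; i++) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int f = 0; f < F.nrow(); f++) {
    int a = find(F(f, 0)), b = find(F(f, 1)), c = find(F(f, 2));
    parent[b] = a; parent[find(c)] = find(a);
  }
  std::unordered_map<int, int> label;
  IntegerVector out(nV);
  for (int i = 0; i < nV; i++) {
    int r = find(i);
    auto it = label.find(r);
    if (it == label.end()) { int id = (int)label.size() + 1; label[r] = id; out[i] = id; }
    else out[i] = it->second;
  }
  return out;
}

static inline int64_t ekey(int a, int b) {
  if (a > b) std::swap(a, b);
  return (int64_t)a * 0x100000000LL + b;
}

// per-undirected-edge face counts; watertight = all counts == 2 and each
// directed edge used exactly once (consistent orientation)
// [[Rcpp::export]]
List cpp_edge_audit(int nV, IntegerMatrix F) {
  std::unordered_map<int64_t, int> cnt;
  std::unordered_map<int64_t, int> dir;  // directed edge multiplicity
  cnt.reserve(F.nrow() * 2);
  bool oriented = true;
  for (int f = 0; f < F.nrow(); f++) {
    int v[3] = {F(f, 0), F(f, 1), F(f, 2)};
    for (int k = 0; k < 3; k++) {
      int a = v[k], b = v[(k + 1) % 3];
      cnt[ekey(a, b)]++;
      int64_t dk = (int64_t)a * 0x100000000LL + b;
      if (++dir[dk] > 1) oriented = false;
    }
  }
  int nBoundary = 0, nNonManifold = 0;
  for (auto& kv : cnt) {
    if (kv.second == 1) nBoundary++;
    else if (kv.second > 2) nNonManifold++;
  }
  return List::create(_["n_edges"] = (int)cnt.size(), _["n_boundary"] = nBoundary,
                      _["n_nonmanifold"] = nNonManifold, _["oriented"] = oriented,
                      _["watertight"] = (nBoundary == 0 && nNonManifold == 0 && oriented));
}

// boundary loops as lists of 0-based vertex indices, ordered along the loop
// [[Rcpp::export]]
List cpp_boundary_loops(int nV, IntegerMatrix F) {
  std::unordered_map<int64_t, int> cnt;
  for (int f = 0; f < F.nrow(); f++) {
    int v[3] = {F(f, 0), F(f, 1), F(f, 2)};
    for (int k = 0; k < 3; k++) cnt[ekey(v[k], v[(k + 1) % 3])]++;
  }
  // boundary directed edges follow face orientation: edge (a,b) of a face is a
  // boundary edge if the undirected edge has count 1
  std::unordered_map<int, int> nxt;
  for (int f = 0; f < F.nrow(); f++) {
    int v[3] = {F(f, 0), F(f, 1), F(f, 2)};
    for (int k = 0; k < 3; k++) {
      int a = v[k], b = v[(k + 1) % 3];
      if (cnt[ekey(a, b)] == 1) nxt[b] = a;  // reversed: boundary traversed opposite to face
    }
  }
  std::unordered_set<int> used;
  List loops;
  for (auto& kv : nxt) {
    int start = kv.first;
    if (used.count(start)) continue;
    std::vector<int> loop;
    int cur = start;
    while (true) {
      loop.push_back(cur);
      used.insert(cur);
      auto it = nxt.find(cur);
      if (it == nxt.end()) break;
      cur = it->second;
      if (cur == start) break;
      if (used.count(cur)) break;
    }
    loops.push_back(IntegerVector(loop.begin(), loop.end()));
  }
  return loops;
}

// ---- incremental isotropic remeshing ---------------------------------------

struct RMesh {
  std::vector<V3> V;
  std::vector<std::array<int, 3>> F;
  std::vector<char> faceAlive;

  void compact() {
    std::vector<std::array<int, 3>> nf;
    nf.reserve(F.size());
    for (size_t i = 0; i < F.size(); i++) if (faceAlive[i]) nf.push_back(F[i]);
    F = std::move(nf);
    faceAlive.assign(F.size(), 1);
    // drop unreferenced vertices
    std::vector<int> remap(V.size(), -1);
    std::vector<V3> nv;
    for (auto& f : F)
      for (int k = 0; k < 3; k++) {
        if (remap[f[k]] < 0) { remap[f[k]] = (int)nv.size(); nv.push_back(V[f[k]]); }
      }
    for (auto& f : F) for (int k = 0; k < 3; k++) f[k] = remap[f[k]];
    V = std::move(nv);
  }
};

static void splitPass(RMesh& m, double lmax) {
  std::unordered_map<int64_t, int> mid;  // edge -> midpoint vertex
  double l2 = lmax * lmax;
  size_t nf0 = m.F.size();
  for (size_t f = 0; f < nf0; f++) {
    if (!m.faceAlive[f]) continue;
    for (int k = 0; k < 3; k++) {
      int a = m.F[f][k], b = m.F[f][(k + 1) % 3];
      V3 d = m.V[a] - m.V[b];
      if (dot(d, d) > l2) {
        int64_t key = ekey(a, b);
        if (!mid.count(key)) {
          mid[key] = (int)m.V.size();
          m.V.push_back((m.V[a] + m.V[b]) * 0.5);
        }
      }
    }
  }
  if (mid.empty()) return;
  for (size_t f = 0; f < nf0; f++) {
    if (!m.faceAlive[f]) continue;
    int a = m.F[f][0], b = m.F[f][1], c = m.F[f][2];
    auto ga = mid.find(ekey(a, b)), gb = mid.find(ekey(b, c)), gc = mid.find(ekey(c, a));
    int mab = ga == mid.end() ? -1 : ga->second;
    int mbc = gb == mid.end() ? -1 : gb->second;
    int mca = gc == mid.end() ? -1 : gc->second;
    int ns = (mab >= 0) + (mbc >= 0) + (mca >= 0);
    if (ns == 0) continue;
    m.faceAlive[f] = 0;
    auto add = [&](int p, int q, int r) {
      m.F.push_back({p, q, r});
      m.faceAlive.push_back(1);
    };
    if (ns == 3) {
      add(a, mab, mca); add(mab, b, mbc); add(mbc, c, mca); add(mab, mbc, mca);
    } else if (ns == 2) {
      // rotate so that the un-split edge is (c,a)
      while (mca >= 0) {  // rotate (a,b,c) -> (b,c,a)
        int t = a; a = b; b = c; c = t;
        int tm = mab; mab = mbc; mbc = mca; mca = tm;
      }
      add(a, mab, mbc); add(mab, b, mbc); add(a, mbc, c);
    } else {
      while (mab < 0) {
        int t = a; a = b; b = c; c = t;
        int tm = mab; mab = mbc; mbc = mca; mca = tm;
      }
      add(a, mab, c); add(mab, b, c);
    }
  }
}

static void collapsePass(RMesh& m, double lmin, double lmax) {
  m.compact();
  int nV = (int)m.V.size();
  std::vector<std::vector<int>> vf(nV);   // vertex -> face ids
  std::vector<std::unordered_set<int>> vn(nV);  // vertex neighbors
  for (size_t f = 0; f < m.F.size(); f++)
    for (int k = 0; k < 3; k++) {
      int a = m.F[f][k];
      vf[a].push_back((int)f);
      vn[a].insert(m.F[f][(k + 1) % 3]);
      vn[a].insert(m.F[f][(k + 2) % 3]);
    }
  // boundary vertices are locked
  std::vector<char> locked(nV, 0);
  {
    std::unordered_map<int64_t, int> cnt;
    for (auto& f : m.F)
      for (int k = 0; k < 3; k++) cnt[ekey(f[k], f[(k + 1) % 3])]++;
    for (auto& kv : cnt)
      if (kv.second != 2) {
        locked[(int)(kv.first >> 32)] = 1;
        locked[(int)(kv.first & 0xffffffff)] = 1;
      }
  }
  double lmin2 = lmin * lmin, lmax2 = lmax * lmax;
  for (int u = 0; u < nV; u++) {
    if (locked[u]) continue;
    for (int v : std::vector<int>(vn[u].begin(), vn[u].end())) {
      if (v <= u || locked[v] || locked[u]) continue;
      V3 d = m.V[u] - m.V[v];
      if (dot(d, d) >= lmin2) continue;
      // link condition: common neighbors must be exactly the shared-face apexes
      std::vector<int> common;
      for (int w : vn[u]) if (vn[v].count(w)) common.push_back(w);
      int shared = 0;
      for (int f : vf[u]) {
        auto& t = m.F[f];
        if (!m.faceAlive[f]) continue;
        bool hu = false, hv = false;
        for (int k = 0; k < 3; k++) { hu |= t[k] == u; hv |= t[k] == v; }
        if (hu && hv) shared++;
      }
      if ((int)common.size() != shared || shared != 2) continue;
      V3 mid = (m.V[u] + m.V[v]) * 0.5;
      // reject if collapse makes an over-long edge
      bool bad = false;
      for (int w : vn[u]) if (w != v) { V3 e = mid - m.V[w]; if (dot(e, e) > lmax2) { bad = true; break; } }
      if (!bad) for (int w : vn[v]) if (w != u) { V3 e = mid - m.V[w]; if (dot(e, e) > lmax2) { bad = true; break; } }
      if (bad) continue;
      // perform collapse v -> u
      m.V[u] = mid;
      for (int f : vf[v]) {
        if (!m.faceAlive[f]) continue;
        auto& t = m.F[f];
        bool hasU = (t[0] == u || t[1] == u || t[2] == u);
        if (hasU) { m.faceAlive[f] = 0; continue; }
        for (int k = 0; k < 3; k++) if (t[k] == v) t[k] = u;
        vf[u].push_back(f);
      }
      for (int w : vn[v]) {
        if (w == u) continue;
        vn[w].erase(v); vn[w].insert(u);
        vn[u].insert(w);
      }
      vn[u].erase(v);
      // lock the one-ring for the rest of this pass
      locked[u] = 1; locked[v] = 1;
      for (int w : vn[u]) locked[w] = 1;
      break;
    }
  }
  m.compact();
}

static void flipPass(RMesh& m) {
  m.compact();
  int nV = (int)m.V.size();
  std::vector<int> val(nV, 0);
  for (auto& f : m.F) for (int k = 0; k < 3; k++) val[f[k]]++;
  // each vertex's valence = #incident faces = #incident edges on closed manifold
  std::unordered_map<int64_t, std::array<int, 2>> efaces;  // edge -> up to 2 faces
  for (size_t f = 0; f < m.F.size(); f++)
    for (int k = 0; k < 3; k++) {
      int64_t key = ekey(m.F[f][k], m.F[f][(k + 1) % 3]);
      auto it = efaces.find(key);
      if (it == efaces.end()) efaces[key] = {(int)f, -1};
      else it->second[1] = (int)f;
    }
  std::unordered_set<int64_t> exists;
  for (auto& kv : efaces) exists.insert(kv.first);
  std::vector<char> dirty(m.F.size(), 0);
  auto dev = [&](int v, int delta) { int d = val[v] + delta - 6; return d * d; };
  for (auto& kv : efaces) {
    int f0 = kv.second[0], f1 = kv.second[1];
    if (f1 < 0 || dirty[f0] || dirty[f1]) continue;
    int a = (int)(kv.first >> 32), b = (int)(kv.first & 0xffffffff);
    auto opp = [&](int f) {
      for (int k = 0; k < 3; k++) {
        int v = m.F[f][k];
        if (v != a && v != b) return v;
      }
      return -1;
    };
    int p = opp(f0), q = opp(f1);
    if (p < 0 || q < 0 || p == q) continue;
    if (exists.count(ekey(p, q))) continue;
    int before = dev(a, 0) + dev(b, 0) + dev(p, 0) + dev(q, 0);
    int after = dev(a, -1) + dev(b, -1) + dev(p, 1) + dev(q, 1);
    if (after >= before) continue;
    // geometric guard: new triangles must not be degenerate or folded
    V3 n0 = cross(m.V[b] - m.V[a], m.V[p] - m.V[a]);
    V3 nNew0 = cross(m.V[q] - m.V[p], m.V[a] - m.V[p]);
    V3 nNew1 = cross(m.V[p] - m.V[q], m.V[b] - m.V[q]);
    if (norm(nNew0) < 1e-14 || norm(nNew1) < 1e-14) continue;
    if (dot(n0, nNew0) <= 0 || dot(n0, nNew1) <= 0) continue;
    // orientation: f0 is (a, b, p) up to rotation (or (b, a, p)); rebuild both
    // faces keeping the winding of f0
    bool abOrder = false;  // true if f0 winds a->b
    for (int k = 0; k < 3; k++)
      if (m.F[f0][k] == a && m.F[f0][(k + 1) % 3] == b) abOrder = true;
    if (abOrder) {
      m.F[f0] = {a, q, p};
      m.F[f1] = {q, b, p};
    } else {
      m.F[f0] = {a, p, q};
      m.F[f1] = {q, p, b};
    }
    val[a]--; val[b]--; val[p]++; val[q]++;
    dirty[f0] = 1; dirty[f1] = 1;
    exists.insert(ekey(p, q));
  }
}

static void relaxPass(RMesh& m, const TriGrid& orig, int rounds) {
  int nV = (int)m.V.size();
  std::vector<char> boundary(nV, 0);
  {
    std::unordered_map<int64_t, int> cnt;
    for (auto& f : m.F)
      for (int k = 0; k < 3; k++) cnt[ekey(f[k], f[(k + 1) % 3])]++;
    for (auto& kv : cnt)
      if (kv.second != 2) {
        boundary[(int)(kv.first >> 32)] = 1;
        boundary[(int)(kv.first & 0xffffffff)] = 1;
      }
  }
  for (int it = 0; it < rounds; it++) {
    std::vector<V3> cen(nV);
    std::vector<double> wsum(nV, 0.0);
    std::vector<V3> nrm(nV);
    for (auto& f : m.F) {
      V3 a = m.V[f[0]], b = m.V[f[1]], c = m.V[f[2]];
      V3 n = cross(b - a, c - a);
      for (int k = 0; k < 3; k++) {
        int u = f[k], v = f[(k + 1) % 3];
        cen[u] = cen[u] + m.V[v]; wsum[u] += 1.0;
        cen[v] = cen[v] + m.V[u]; wsum[v] += 1.0;
        nrm[f[k]] = nrm[f[k]] + n;
      }
    }
    for (int v = 0; v < nV; v++) {
      if (boundary[v] || wsum[v] == 0) continue;
      V3 c = cen[v] * (1.0 / wsum[v]);
      V3 n = nrm[v];
      double l = norm(n);
      V3 d = c - m.V[v];
      if (l > 0) { n = n * (1.0 / l); d = d - n * dot(d, n); }
      V3 moved = m.V[v] + d * 0.6;
      V3 cp; double dist;
      orig.query(moved, cp, dist);
      m.V[v] = cp;
    }
  }
}

// [[Rcpp::export]]
List cpp_remesh(NumericMatrix V, IntegerMatrix F, double target, int iterations) {
  TriGrid orig;
  orig.build(V, F);
  RMesh m;
  m.V.resize(V.nrow());
  for (int i = 0; i < V.nrow(); i++) m.V[i] = V3(V(i, 0), V(i, 1), V(i, 2));
  m.F.resize(F.nrow());
  for (int i = 0; i < F.nrow(); i++) m.F[i] = {F(i, 0), F(i, 1), F(i, 2)};
  m.faceAlive.assign(m.F.size(), 1);
  double lmax = 4.0 / 3.0 * target, lmin = 4.0 / 5.0 * target;
  for (int it = 0; it < iterations; it++) {
    splitPass(m, lmax);
    // the collapse pass locks one-rings for safety, so repeat it until it
    // stops making progress (coarsening by large factors needs several)
    for (int c = 0; c < 10; c++) {
      size_t nv = m.V.size();
      collapsePass(m, lmin, lmax);
      if (m.V.size() == nv) break;
    }
    flipPass(m);
    relaxPass(m, orig, 2);
  }
  m.compact();
  NumericMatrix Vo((int)m.V.size(), 3);
  for (size_t i = 0; i < m.V.size(); i++) {
    Vo(i, 0) = m.V[i].x; Vo(i, 1) = m.V[i].y; Vo(i, 2) = m.V[i].z;
  }
  IntegerMatrix Fo((int)m.F.size(), 3);
  for (size_t i = 0; i < m.F.size(); i++) {
    Fo(i, 0) = m.F[i][0]; Fo(i, 1) = m.F[i][1]; Fo(i, 2) = m.F[i][2];
  }
  return List::create(_["vertices"] = Vo, _["faces"] = Fo);
}
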