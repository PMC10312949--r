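// 3-D Delaunay tetrahedralization (incremental Bowyer-Watson) and helpers for
// circumradius-filtered alpha-complexes: voxel rasterization and point-in-union
// tests. Inputs are expected deduplicated; a tiny deterministic jitter breaks
// exact degeneracies (cospherical / coplanar subsets) so floating-point
// predicates suffice at the point-cloud sizes this package works with.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <limits>
#include <map>
#include <random>
#include <utility>
#include <vector>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];      // vertex indices (0-based), positive orientation
  int nb[4];     // neighbor opposite v[i], -1 if none
  double cc[3];  // circumcenter
  double r2;     // squared circumradius (DBL_MAX if degenerate)
  bool alive;
};

inline double orient3d(const double* a, const double* b, const double* c,
                       const double* d) {
  const double bx = b[0] - a[0], by = b[1] - a[1], bz = b[2] - a[2];
  const double cx = c[0] - a[0], cy = c[1] - a[1], cz = c[2] - a[2];
  const double dx = d[0] - a[0], dy = d[1] - a[1], dz = d[2] - a[2];
  return bx * (cy * dz - cz * dy) - by * (cx * dz - cz * dx) +
         bz * (cx * dy - cy * dx);
}

// circumcenter/r2 of tet; returns false when the four points are (near-)coplanar
inline bool circumsphere(const double* a, const double* b, const double* c,
                         const double* d, double* cc, double& r2) {
  double m[3][3], rhs[3];
  const double* pts[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    double s = 0.0;
    for (int j = 0; j < 3; ++j) {
      m[i][j] = 2.0 * (pts[i][j] - a[j]);
      s += pts[i][j] * pts[i][j] - a[j] * a[j];
    }
    rhs[i] = s;
  }
  const double det =
      m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
      m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
      m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  double scale = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) scale = std::max(scale, std::fabs(m[i][j]));
  if (std::fabs(det) < 1e-12 * scale * scale * scale + 1e-300) return false;
  // Cramer's rule
  for (int k = 0; k < 3; ++k) {
    double mm[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) mm[i][j] = (j == k) ? rhs[i] : m[i][j];
    const double dk =
        mm[0][0] * (mm[1][1] * mm[2][2] - mm[1][2] * mm[2][1]) -
        mm[0][1] * (mm[1][0] * mm[2][2] - mm[1][2] * mm[2][0]) +
        mm[0][2] * (mm[1][0] * mm[2][1] - mm[1][1] * mm[2][0]);
    cc[k] = dk / det;
  }
  r2 = 0.0;
  for (int j = 0; j < 3; ++j) r2 += (cc[j] - a[j]) * (cc[j] - a[j]);
  return true;
}

class Triangulator {
 public:
  std::vector<double> P;  // flat xyz, includes 4 super vertices at the end
  int n_input;
  std::vector<Tet> T;
  int last_alive = 0;

  const double* pt(int i) const { return &P[3 * i]; }

  void set_circum(Tet& t) {
    if (!circumsphere(pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pt(t.v[3]), t.cc,
                      t.r2))
      t.r2 = std::numeric_limits<double>::max();
  }

  bool in_sphere(const Tet& t, const double* p) const {
    if (t.r2 == std::numeric_limits<double>::max()) return true;
    double d2 = 0.0;
    for (int j = 0; j < 3; ++j) d2 += (p[j] - t.cc[j]) * (p[j] - t.cc[j]);
    return d2 < t.r2 * (1.0 + 1e-12);
  }

  void make_super(double lo[3], double hi[3]) {
    double c[3], span = 0.0;
    for (int j = 0; j < 3; ++j) {
      c[j] = 0.5 * (lo[j] + hi[j]);
      span = std::max(span, hi[j] - lo[j]);
    }
    const double R = 20.0 * span + 1.0;
    const double sv[4][3] = {{c[0], c[1], c[2] + 3.0 * R},
                             {c[0] - 3.0 * R, c[1] - R, c[2] - R},
                             {c[0] + 3.0 * R, c[1] - R, c[2] - R},
                             {c[0], c[1] + 3.0 * R, c[2] - R}};
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 3; ++j) P.push_back(sv[i][j]);
    Tet t;
    t.v[0] = n_input;
    t.v[1] = n_input + 1;
    t.v[2] = n_input + 2;
    t.v[3] = n_input + 3;
    if (orient3d(pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pt(t.v[3])) < 0)
      std::swap(t.v[2], t.v[3]);
    for (int i = 0; i < 4; ++i) t.nb[i] = -1;
    t.alive = true;
    set_circum(t);
    T.push_back(t);
  }

  // orientation walk to a tetrahedron containing p (falls back to scan)
  int locate(const double* p) {
    int cur = last_alive;
    if (cur >= (int)T.size() || !T[cur].alive) {
      cur = -1;
      for (int i = (int)T.size() - 1; i >= 0; --i)
        if (T[i].alive) { cur = i; break; }
    }
    const int max_steps = 8 * (int)T.size() + 64;
    for (int step = 0; step < max_steps && cur >= 0; ++step) {
      const Tet& t = T[cur];
      int worst = -1;
      double worst_o = -1e-14;
      const double* q[4] = {pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pt(t.v[3])};
      for (int i = 0; i < 4; ++i) {
        const double* f[4] = {q[0], q[1], q[2], q[3]};
        f[i] = p;
        const double o = orient3d(f[0], f[1], f[2], f[3]);
        if (o < worst_o) { worst_o = o; worst = i; }
      }
      if (worst < 0) return cur;  // inside (all orientations non-negative)
      cur = t.nb[worst];
    }
    // robust fallback: linear scan for any circumsphere containing p
    for (int i = 0; i < (int)T.size(); ++i)
      if (T[i].alive && in_sphere(T[i], p)) return i;
    stop("point location failed in Delaunay construction");
    return -1;
  }

  void insert(int pi) {
    const double* p = pt(pi);
    const int seed_tet = locate(p);
    // BFS cavity of circumsphere-violating tets
    std::vector<int> bad;
    std::vector<int> stack;
    std::vector<char> mark(T.size(), 0);
    stack.push_back(seed_tet);
    mark[seed_tet] = 1;
    while (!stack.empty()) {
      const int ti = stack.back();
      stack.pop_back();
      if (!T[ti].alive || !in_sphere(T[ti], p)) continue;
      bad.push_back(ti);
      mark[ti] = 2;
      for (int i = 0; i < 4; ++i) {
        const int nbi = T[ti].nb[i];
        if (nbi >= 0 && !mark[nbi]) {
          mark[nbi] = 1;
          stack.push_back(nbi);
        }
      }
    }
    // boundary faces: (3 vertices, external tet, owner dead tet)
    struct BFace { int a, b, c, ext, dead; };
    std::vector<BFace> faces;
    for (int ti : bad) {
      for (int i = 0; i < 4; ++i) {
        const int nbi = T[ti].nb[i];
        if (nbi < 0 || mark[nbi] != 2) {
          BFace f;
          int k = 0;
          int vv[3];
          for (int j = 0; j < 4; ++j)
            if (j != i) vv[k++] = T[ti].v[j];
          f.a = vv[0]; f.b = vv[1]; f.c = vv[2];
          f.ext = nbi;
          f.dead = ti;
          faces.push_back(f);
        }
      }
    }
    for (int ti : bad) T[ti].alive = false;
    // build new tets p + each boundary face
    std::map<std::pair<int, int>, std::pair<int, int>> edge_map;  // edge -> (tet, face)
    for (const BFace& f : faces) {
      Tet t;
      t.v[0] = pi; t.v[1] = f.a; t.v[2] = f.b; t.v[3] = f.c;
      if (orient3d(pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pt(t.v[3])) < 0)
        std::swap(t.v[2], t.v[3]);
      t.nb[0] = f.ext;
      t.nb[1] = t.nb[2] = t.nb[3] = -1;
      t.alive = true;
      set_circum(t);
      const int tid = (int)T.size();
      T.push_back(t);
      if (f.ext >= 0) {  // repoint external neighbor across this face
        for (int j = 0; j < 4; ++j)
          if (T[f.ext].nb[j] == f.dead) { T[f.ext].nb[j] = tid; break; }
      }
      // wire faces containing p: face i>0 excludes v[i], edge = the two
      // non-p vertices of that face
      for (int i = 1; i < 4; ++i) {
        int e1 = -1, e2 = -1;
        for (int j = 1; j < 4; ++j)
          if (j != i) { (e1 < 0 ? e1 : e2) = T[tid].v[j]; }
        std::pair<int, int> key(std::min(e1, e2), std::max(e1, e2));
        auto it = edge_map.find(key);
        if (it == edge_map.end()) {
          edge_map[key] = std::make_pair(tid, i);
        } else {
          T[tid].nb[i] = it->second.first;
          T[it->second.first].nb[it->second.second] = tid;
          edge_map.erase(it);
        }
      }
      last_alive = tid;
    }
  }
};

inline bool point_in_tet(const double* p, const double* a, const double* b,
                         const double* c, const double* d) {
  const double D = orient3d(a, b, c, d);
  if (D <= 0) return false;
  const double tol = -1e-9 * D;
  if (orient3d(p, b, c, d) < tol) return false;
  if (orient3d(a, p, c, d) < tol) return false;
  if (orient3d(a, b, p, d) < tol) return false;
  if (orient3d(a, b, c, p) < tol) return false;
  return true;
}

}  // namespace

// Delaunay tetrahedralization. Returns 1-based tetrahedron vertex indices,
// circumradii, and the (jittered) coordinates actually triangulated.
// [[Rcpp::export(name = ".delaunay3d_cpp")]]
List delaunay3d_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a tetrahedralization");
  Triangulator tri;
  tri.n_input = n;
  tri.P.resize(3 * n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      tri.P[3 * i + j] = pts(i, j);
      lo[j] = std::min(lo[j], pts(i, j));
      hi[j] = std::max(hi[j], pts(i, j));
    }
  double diag = 0.0;
  for (int j = 0; j < 3; ++j) diag += (hi[j] - lo[j]) * (hi[j] - lo[j]);
  diag = std::sqrt(diag);
  if (diag <= 0) stop("degenerate (coincident) point cloud");
  // deterministic symbolic-perturbation stand-in: fixed-seed uniform jitter
  std::mt19937 rng(0x5eedu);
  std::uniform_real_distribution<double> U(-1.0, 1.0);
  const double eps = 1e-7 * diag;
  for (int i = 0; i < 3 * n; ++i) tri.P[i] += eps * U(rng);

  tri.make_super(lo, hi);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), rng);
  for (int i = 0; i < n; ++i) {
    tri.insert(order[i]);
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  int m = 0;
  for (const Tet& t : tri.T)
    if (t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n && t.v[3] < n) ++m;
  IntegerMatrix tets(m, 4);
  NumericVector radius(m);
  int k = 0;
  for (const Tet& t : tri.T) {
    if (!(t.alive && t.v[0] < n && t.v[1] < n && t.v[2] < n && t.v[3] < n))
      continue;
    for (int j = 0; j < 4; ++j) tets(k, j) = t.v[j] + 1;
    radius[k] = (t.r2 == std::numeric_limits<double>::max())
                    ? R_PosInf
                    : std::sqrt(t.r2);
    ++k;
  }
  NumericMatrix jp(n, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) jp(i, j) = tri.P[3 * i + j];
  return List::create(_["tets"] = tets, _["circumradius"] = radius,
                      _["points"] = jp);
}

// Voxels (0-based linear indices, R array order) whose centers lie inside the
// union of the given tetrahedra.
// [[Rcpp::export(name = ".rasterize_tets_cpp")]]
IntegerVector rasterize_tets_cpp(NumericMatrix pts, IntegerMatrix tets,
                                 IntegerVector dims, double voxel,
                                 NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<char> mask((size_t)nx * ny * nz, 0);
  const int m = tets.nrow();
  for (int t = 0; t < m; ++t) {
    const double* a = &pts(tets(t, 0) - 1, 0);
    // NumericMatrix is column-major; build contiguous copies
    double A[3], B[3], C[3], D[3];
    for (int j = 0; j < 3; ++j) {
      A[j] = pts(tets(t, 0) - 1, j);
      B[j] = pts(tets(t, 1) - 1, j);
      C[j] = pts(tets(t, 2) - 1, j);
      D[j] = pts(tets(t, 3) - 1, j);
    }
    (void)a;
    double lo[3], hi[3];
    for (int j = 0; j < 3; ++j) {
      lo[j] = std::min(std::min(A[j], B[j]), std::min(C[j], D[j]));
      hi[j] = std::max(std::max(A[j], B[j]), std::max(C[j], D[j]));
    }
    int ilo[3], ihi[3];
    const int dd[3] = {nx, ny, nz};
    bool empty = false;
    for (int j = 0; j < 3; ++j) {
      ilo[j] = std::max(0, (int)std::floor((lo[j] - origin[j]) / voxel - 0.5));
      ihi[j] = std::min(dd[j] - 1,
                        (int)std::floor((hi[j] - origin[j]) / voxel + 0.5));
      if (ilo[j] > ihi[j]) empty = true;
    }
    if (empty) continue;
    for (int k = ilo[2]; k <= ihi[2]; ++k)
      for (int jy = ilo[1]; jy <= ihi[1]; ++jy)
        for (int ix = ilo[0]; ix <= ihi[0]; ++ix) {
          const size_t lin = (size_t)ix + (size_t)nx * (jy + (size_t)ny * k);
          if (mask[lin]) continue;
          const double q[3] = {origin[0] + (ix + 0.5) * voxel,
                               origin[1] + (jy + 0.5) * voxel,
                               origin[2] + (k + 0.5) * voxel};
          if (point_in_tet(q, A, B, C, D)) mask[lin] = 1;
        }
  }
  size_t cnt = 0;
  for (char c : mask) cnt += (c != 0);
  IntegerVector out(cnt);
  size_t k2 = 0;
  for (size_t i = 0; i < mask.size(); ++i)
    if (mask[i]) out[k2++] = (int)i;
  return out;
}

// Membership of query points in the union of tetrahedra.
// [[Rcpp::export(name = ".points_in_tets_cpp")]]
LogicalVector points_in_tets_cpp(NumericMatrix query, NumericMatrix pts,
                                 IntegerMatrix tets) {
  const int nq = query.nrow(), m = tets.nrow();
  std::vector<double> lo(3 * m), hi(3 * m);
  for (int t = 0; t < m; ++t)
    for (int j = 0; j < 3; ++j) {
      double l = R_PosInf, h = R_NegInf;
      for (int v = 0; v < 4; ++v) {
        const double x = pts(tets(t, v) - 1, j);
        l = std::min(l, x);
        h = std::max(h, x);
      }
      lo[3 * t + j] = l;
      hi[3 * t + j] = h;
    }
  LogicalVector out(nq);
  for (int q = 0; q < nq; ++q) {
    const double p[3] = {query(q, 0), query(q, 1), query(q, 2)};
    bool inside = false;
    for (int t = 0; t < m && !inside; ++t) {
      bool inbox = true;
      for (int j = 0; j < 3; ++j)
        if (p[j] < lo[3 * t + j] - 1e-9 || p[j] > hi[3 * t + j] + 1e-9) {
          inbox = false;
          break;
        }
      if (!inbox) continue;
      double A[3], B[3], C[3], D[3];
      for (int j = 0; j < 3; ++j) {
        A[j] = pts(tets(t, 0) - 1, j);
        B[j] = pts(tets(t, 1) - 1, j);
        C[j] = pts(tets(t, 2) - 1, j);
        D[j] = pts(tets(t, 3) - 1, j);
      }
      inside = point_in_tet(p, A, B, C, D);
    }
    out[q] = inside;
  }
  return out;
}
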