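#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Nearest node (3D Euclidean) for every point; brute force over the node
// grid. Returns 1-based node indices.
// [[Rcpp::export]]
IntegerVector nearest_node_cpp(NumericMatrix P, NumericMatrix nodes) {
  const int np = P.nrow(), nn = nodes.nrow();
  IntegerVector out(np);
  std::vector<double> nx(nn), ny(nn), nz(nn);
  for (int j = 0; j < nn; ++j) {
    nx[j] = nodes(j, 0); ny[j] = nodes(j, 1); nz[j] = nodes(j, 2);
  }
  for (int i = 0; i < np; ++i) {
    const double x = P(i, 0), y = P(i, 1), z = P(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int arg = 0;
    for (int j = 0; j < nn; ++j) {
      const double dx = x - nx[j], dy = y - ny[j], dz = z - nz[j];
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; arg = j; }
    }
    out[i] = arg + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Geodesic distance field: first-order fast marching on a triangle mesh with
// Kimmel-Sethian obtuse-angle unfolding (virtual update stencils), followed
// by Gauss-Seidel repair sweeps.

static inline double edge_len(const NumericMatrix& V, int a, int b) {
  const double dx = V(a, 0) - V(b, 0), dy = V(a, 1) - V(b, 1),
               dz = V(a, 2) - V(b, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Update of vertex c from stencil (p, q): b = |cp|, a = |cq|, angle at c.
static double local_update(double dp, double dq, double b, double a,
                           double cos_t, double sin_t) {
  if (!std::isfinite(dp) && !std::isfinite(dq))
    return std::numeric_limits<double>::infinity();
  const double fallback = std::min(dp + b, dq + a);
  if (!std::isfinite(dp) || !std::isfinite(dq)) return fallback;
  if (dq < dp) { std::swap(dp, dq); std::swap(a, b); }
  const double u = dq - dp;
  const double A = a * a + b * b - 2.0 * a * b * cos_t;
  const double B = 2.0 * b * u * (a * cos_t - b);
  const double C = b * b * (u * u - a * a * sin_t * sin_t);
  const double disc = B * B - 4.0 * A * C;
  if (disc >= 0.0 && A > 0.0) {
    const double t = (-B + std::sqrt(disc)) / (2.0 * A);
    if (u < t && t > 0.0) {
      const double q1 = b * (t - u) / t;
      if (a * cos_t < q1 && (cos_t <= 0.0 || q1 < a / cos_t))
        return std::min(fallback, t + dp);
    }
  }
  return fallback;
}

struct Stencil {
  int c, p, q;          // update c from p, q
  double b, a;          // |cp|, |cq| (unfolded, straight-line)
  double cos_t, sin_t;  // angle at c between cp and cq
};

struct Pt2 { double x, y; };

static inline double cross2(const Pt2& o, const Pt2& u, const Pt2& v) {
  return (u.x - o.x) * (v.y - o.y) - (u.y - o.y) * (v.x - o.x);
}

// Planar circle-circle intersection: point at distance d1 from P and d2 from
// Q, choosing the solution on `side` (> 0: left of P->Q).
static bool circle_pt(const Pt2& P, const Pt2& Q, double d1, double d2,
                      double side, Pt2& out) {
  const double ex = Q.x - P.x, ey = Q.y - P.y;
  const double L = std::sqrt(ex * ex + ey * ey);
  if (L <= 0) return false;
  const double u = (d1 * d1 - d2 * d2 + L * L) / (2.0 * L);
  double h2 = d1 * d1 - u * u;
  if (h2 < 0) h2 = 0;
  const double h = std::sqrt(h2);
  const double ux = ex / L, uy = ey / L;
  const double sgn = (side >= 0) ? 1.0 : -1.0;
  out.x = P.x + u * ux - sgn * h * uy;
  out.y = P.y + u * uy + sgn * h * ux;
  return true;
}

class MeshGeom {
public:
  int nv, nt;
  const NumericMatrix& V;
  const IntegerMatrix& F;
  std::map<long long, std::pair<int, int> > edge_tri;
  std::vector<Stencil> stencils;
  std::vector<std::vector<int> > by_source;  // vertex -> stencils using it as p/q
  std::vector<std::vector<int> > by_center;  // vertex -> stencils updating it

  MeshGeom(const NumericMatrix& V_, const IntegerMatrix& F_) : V(V_), F(F_) {
    nv = V.nrow(); nt = F.nrow();
    for (int t = 0; t < nt; ++t)
      for (int k = 0; k < 3; ++k)
        add_edge(F(t, k), F(t, (k + 1) % 3), t);
    by_source.resize(nv);
    by_center.resize(nv);
    for (int t = 0; t < nt; ++t)
      for (int k = 0; k < 3; ++k) build_stencils(t, k);
    for (size_t s = 0; s < stencils.size(); ++s) {
      by_center[stencils[s].c].push_back((int)s);
      by_source[stencils[s].p].push_back((int)s);
      by_source[stencils[s].q].push_back((int)s);
    }
  }

private:
  static long long ekey(int a, int b) {
    if (a > b) std::swap(a, b);
    return (long long)a * 0x100000000LL + b;
  }
  void add_edge(int a, int b, int t) {
    std::pair<int, int>& pr = edge_tri
      .insert(std::make_pair(ekey(a, b), std::make_pair(-1, -1))).first->second;
    if (pr.first < 0) pr.first = t; else pr.second = t;
  }
  int tri_across(int a, int b, int not_t) const {
    std::map<long long, std::pair<int, int> >::const_iterator it =
      edge_tri.find(ekey(a, b));
    if (it == edge_tri.end()) return -1;
    if (it->second.first != not_t && it->second.first >= 0) return it->second.first;
    if (it->second.second != not_t) return it->second.second;
    return -1;
  }
  int third_vertex(int t, int a, int b) const {
    for (int k = 0; k < 3; ++k) {
      const int v = F(t, k);
      if (v != a && v != b) return v;
    }
    return -1;
  }
  void push_stencil(int c, int p, int q, double b, double a,
                    double cos_t, double sin_t) {
    Stencil s; s.c = c; s.p = p; s.q = q; s.b = b; s.a = a;
    s.cos_t = cos_t; s.sin_t = sin_t;
    stencils.push_back(s);
  }

  void build_stencils(int t, int k) {
    const int c = F(t, k), pA = F(t, (k + 1) % 3), pB = F(t, (k + 2) % 3);
    const double b = edge_len(V, c, pA);   // |cA|
    const double a = edge_len(V, c, pB);   // |cB|
    const double lab = edge_len(V, pA, pB);
    double ct = (a * a + b * b - lab * lab) / (2.0 * a * b);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    if (ct >= 0.0) {  // acute (or right) angle at c: direct stencil
      push_stencil(c, pA, pB, b, a, ct, st);
      return;
    }
    // obtuse: unfold across the far edge until a vertex falls inside the wedge
    const double thC = std::acos(ct);
    Pt2 posP, posQ;
    posP.x = b; posP.y = 0.0;                       // A
    posQ.x = a * ct; posQ.y = a * st;               // B
    int idP = pA, idQ = pB, prev = t;
    bool done = false;
    for (int depth = 0; depth < 16 && !done; ++depth) {
      const int t2 = tri_across(idP, idQ, prev);
      if (t2 < 0) break;
      const int idR = third_vertex(t2, idP, idQ);
      if (idR < 0) break;
      // place R on the side of P->Q away from c (origin)
      Pt2 origin; origin.x = 0.0; origin.y = 0.0;
      const double side_c = cross2(posP, posQ, origin);
      Pt2 posR;
      if (!circle_pt(posP, posQ, edge_len(V, idP, idR), edge_len(V, idQ, idR),
                     -side_c, posR)) break;
      const double ang = std::atan2(posR.y, posR.x);
      const double lr = std::sqrt(posR.x * posR.x + posR.y * posR.y);
      if (lr <= 0) break;
      if (ang > 1e-12 && ang < thC - 1e-12) {
        // split: virtual triangles (c, A, R) and (c, R, B)
        push_stencil(c, pA, idR, b, lr, std::cos(ang), std::sin(ang));
        push_stencil(c, idR, pB, lr, a, std::cos(thC - ang),
                     std::sin(thC - ang));
        done = true;
      } else if (ang <= 1e-12) {
        posP = posR; idP = idR; prev = t2;
      } else {
        posQ = posR; idQ = idR; prev = t2;
      }
    }
    if (!done) push_stencil(c, pA, pB, b, a, ct, st);  // fallback
  }
};

// [[Rcpp::export]]
NumericVector fast_march_cpp(NumericMatrix V, IntegerMatrix F,
                             NumericVector init, int max_sweeps = 30) {
  const int nv = V.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  MeshGeom G(V, F);

  std::vector<double> d(nv, INF);
  typedef std::pair<double, int> DV;
  std::priority_queue<DV, std::vector<DV>, std::greater<DV> > heap;
  for (int i = 0; i < nv; ++i)
    if (R_finite(init[i])) { d[i] = init[i]; heap.push(DV(d[i], i)); }

  std::vector<char> frozen(nv, 0);
  while (!heap.empty()) {
    const DV top = heap.top(); heap.pop();
    const int i = top.second;
    if (frozen[i] || top.first > d[i]) continue;
    frozen[i] = 1;
    const std::vector<int>& ss = G.by_source[i];
    for (size_t s = 0; s < ss.size(); ++s) {
      const Stencil& st = G.stencils[ss[s]];
      if (frozen[st.c]) continue;
      const double cand = local_update(d[st.p], d[st.q], st.b, st.a,
                                       st.cos_t, st.sin_t);
      if (cand < d[st.c]) { d[st.c] = cand; heap.push(DV(cand, st.c)); }
    }
  }

  // Gauss-Seidel sweeps over all stencils (alternating direction) to repair
  // residual causality violations.
  double scale = 0.0;
  for (int i = 0; i < nv; ++i)
    if (std::isfinite(d[i]) && d[i] > scale) scale = d[i];
  const double tol = 1e-12 * std::max(scale, 1.0);
  const int ns = (int)G.stencils.size();
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double change = 0.0;
    for (int ii = 0; ii < ns; ++ii) {
      const int s = (sweep % 2 == 0) ? ii : (ns - 1 - ii);
      const Stencil& st = G.stencils[s];
      const double cand = local_update(d[st.p], d[st.q], st.b, st.a,
                                       st.cos_t, st.sin_t);
      if (cand < d[st.c] - tol) {
        change = std::max(change, d[st.c] - cand);
        d[st.c] = cand;
      }
    }
    if (change <= tol) break;
  }

  NumericVector out(nv);
  for (int i = 0; i < nv; ++i) out[i] = d[i];
  return out;
}
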