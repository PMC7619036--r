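#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Anisotropic eikonal solver on tetrahedral meshes by iterative sweeping
// with exact local solves (fast-iterative-method style updates run to a
// fixed-point).  The per-element symmetric tensor Minv defines travel time
// along a straight segment d as sqrt(d' Minv d); for conduction velocities
// v_f, v_s, v_n along the orthonormal frame (f, s, n),
//   Minv = f f'/v_f^2 + s s'/v_s^2 + n n'/v_n^2.
// A set of "fast edges" (endocardial surface shortcuts traversed at v_endo)
// is relaxed inside every sweep.

struct Sym3 {
  double m11, m21, m31, m22, m32, m33;
  inline double quad(double x, double y, double z) const {
    return m11 * x * x + m22 * y * y + m33 * z * z +
           2.0 * (m21 * x * y + m31 * x * z + m32 * y * z);
  }
  inline double bil(double x1, double y1, double z1, double x2, double y2,
                    double z2) const {
    return m11 * x1 * x2 + m22 * y1 * y2 + m33 * z1 * z2 +
           m21 * (x1 * y2 + y1 * x2) + m31 * (x1 * z2 + z1 * x2) +
           m32 * (y1 * z2 + z1 * y2);
  }
};

static inline double edge_solve(const Sym3& M, const double* w0,
                                const double* e, double T1, double dT) {
  // minimize over a in [0,1]: T1 + a*dT + sqrt(q(a)), q = |w0 - a e|_M^2
  const double c0 = M.quad(w0[0], w0[1], w0[2]);
  const double c1 = M.bil(w0[0], w0[1], w0[2], e[0], e[1], e[2]);
  const double c2 = M.quad(e[0], e[1], e[2]);
  double best = R_PosInf;
  auto eval = [&](double a) {
    const double wx = w0[0] - a * e[0], wy = w0[1] - a * e[1],
                 wz = w0[2] - a * e[2];
    const double q = M.quad(wx, wy, wz);
    return T1 + a * dT + std::sqrt(std::max(0.0, q));
  };
  best = std::min(eval(0.0), eval(1.0));
  const double A = c2 * (c2 - dT * dT);
  const double B = -2.0 * c1 * (c2 - dT * dT);
  const double Cq = c1 * c1 - dT * dT * c0;
  if (std::fabs(A) > 1e-300) {
    const double disc = B * B - 4.0 * A * Cq;
    if (disc >= 0.0) {
      const double sq = std::sqrt(disc);
      for (double a : {(-B + sq) / (2 * A), (-B - sq) / (2 * A)})
        if (a > 0.0 && a < 1.0) best = std::min(best, eval(a));
    }
  }
  return best;
}

static double face_solve(const Sym3& M, const double* x4, const double* x1,
                         const double* x2, const double* x3, double T1,
                         double T2, double T3) {
  const bool f1 = std::isfinite(T1), f2 = std::isfinite(T2),
             f3 = std::isfinite(T3);
  if (!f1 && !f2 && !f3) return R_PosInf;
  double w0[3] = {x4[0] - x1[0], x4[1] - x1[1], x4[2] - x1[2]};
  double e2[3] = {x2[0] - x1[0], x2[1] - x1[1], x2[2] - x1[2]};
  double e3[3] = {x3[0] - x1[0], x3[1] - x1[1], x3[2] - x1[2]};
  double best = R_PosInf;
  // vertex candidates
  if (f1) best = std::min(best, T1 + std::sqrt(std::max(0.0, M.quad(w0[0], w0[1], w0[2]))));
  double w2[3] = {x4[0] - x2[0], x4[1] - x2[1], x4[2] - x2[2]};
  double w3[3] = {x4[0] - x3[0], x4[1] - x3[1], x4[2] - x3[2]};
  if (f2) best = std::min(best, T2 + std::sqrt(std::max(0.0, M.quad(w2[0], w2[1], w2[2]))));
  if (f3) best = std::min(best, T3 + std::sqrt(std::max(0.0, M.quad(w3[0], w3[1], w3[2]))));
  // edge candidates
  if (f1 && f2) best = std::min(best, edge_solve(M, w0, e2, T1, T2 - T1));
  if (f1 && f3) best = std::min(best, edge_solve(M, w0, e3, T1, T3 - T1));
  if (f2 && f3) {
    double e23[3] = {x3[0] - x2[0], x3[1] - x2[1], x3[2] - x2[2]};
    best = std::min(best, edge_solve(M, w2, e23, T2, T3 - T2));
  }
  // interior candidate
  if (f1 && f2 && f3) {
    const double g11 = M.quad(e2[0], e2[1], e2[2]);
    const double g12 = M.bil(e2[0], e2[1], e2[2], e3[0], e3[1], e3[2]);
    const double g22 = M.quad(e3[0], e3[1], e3[2]);
    const double det = g11 * g22 - g12 * g12;
    if (det > 1e-300) {
      const double h1 = M.bil(e2[0], e2[1], e2[2], w0[0], w0[1], w0[2]);
      const double h2 = M.bil(e3[0], e3[1], e3[2], w0[0], w0[1], w0[2]);
      const double d2 = T2 - T1, d3 = T3 - T1;
      // G^{-1}
      const double i11 = g22 / det, i12 = -g12 / det, i22 = g11 / det;
      const double q0 = h1 * (i11 * h1 + i12 * h2) + h2 * (i12 * h1 + i22 * h2);
      const double q1 = h1 * (i11 * d2 + i12 * d3) + h2 * (i12 * d2 + i22 * d3);
      const double q2 = d2 * (i11 * d2 + i12 * d3) + d3 * (i12 * d2 + i22 * d3);
      const double c0 = M.quad(w0[0], w0[1], w0[2]);
      (void)q1;
      if (q2 < 1.0 && c0 - q0 >= 0.0) {
        const double tau = std::sqrt((c0 - q0) / (1.0 - q2));
        const double a =
            i11 * (h1 - tau * d2) + i12 * (h2 - tau * d3);
        const double b =
            i12 * (h1 - tau * d2) + i22 * (h2 - tau * d3);
        if (a > 0.0 && b > 0.0 && a + b < 1.0) {
          const double wx = w0[0] - a * e2[0] - b * e3[0];
          const double wy = w0[1] - a * e2[1] - b * e3[1];
          const double wz = w0[2] - a * e2[2] - b * e3[2];
          const double cand = T1 + a * d2 + b * d3 +
                              std::sqrt(std::max(0.0, M.quad(wx, wy, wz)));
          best = std::min(best, cand);
        }
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_eikonal(NumericMatrix nodes, IntegerMatrix tets,
                          NumericMatrix minv, IntegerVector roots,
                          NumericVector onsets, IntegerMatrix fast_edges,
                          NumericVector fast_len, double v_fast, double tol,
                          int max_sweeps) {
  const int n = nodes.nrow(), nt = tets.nrow();
  // node -> incident tets (CSR)
  std::vector<int> cnt(n, 0);
  for (int t = 0; t < nt; ++t)
    for (int j = 0; j < 4; ++j) cnt[tets(t, j) - 1]++;
  std::vector<int> off(n + 1, 0);
  for (int i = 0; i < n; ++i) off[i + 1] = off[i] + cnt[i];
  std::vector<int> adj(off[n]);
  {
    std::vector<int> pos(off.begin(), off.end() - 1);
    for (int t = 0; t < nt; ++t)
      for (int j = 0; j < 4; ++j) adj[pos[tets(t, j) - 1]++] = t;
  }
  // node -> fast edges (store neighbour and time cost)
  std::vector<std::vector<std::pair<int, double>>> fadj(n);
  for (int e = 0; e < fast_edges.nrow(); ++e) {
    const int a = fast_edges(e, 0) - 1, b = fast_edges(e, 1) - 1;
    const double w = fast_len[e] / v_fast;
    fadj[a].push_back({b, w});
    fadj[b].push_back({a, w});
  }
  std::vector<double> T(n, R_PosInf);
  std::vector<bool> fixed(n, false);
  for (int i = 0; i < roots.size(); ++i) {
    T[roots[i] - 1] = onsets[i];
    fixed[roots[i] - 1] = true;
  }
  std::vector<Sym3> M(nt);
  for (int t = 0; t < nt; ++t)
    M[t] = {minv(t, 0), minv(t, 1), minv(t, 2),
            minv(t, 3), minv(t, 4), minv(t, 5)};
  // row-major copy so each node's xyz is contiguous
  std::vector<double> X(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) X[3 * (size_t)i + d] = nodes(i, d);
  auto update_node = [&](int v) -> double {
    double best = T[v];
    for (int a = off[v]; a < off[v + 1]; ++a) {
      const int t = adj[a];
      int others[3], no = 0;
      for (int j = 0; j < 4; ++j) {
        const int u = tets(t, j) - 1;
        if (u != v) others[no++] = u;
      }
      if (no != 3) continue;  // degenerate (repeated vertex)
      const double cand = face_solve(
          M[t], &X[3 * (size_t)v], &X[3 * (size_t)others[0]],
          &X[3 * (size_t)others[1]], &X[3 * (size_t)others[2]],
          T[others[0]], T[others[1]], T[others[2]]);
      if (cand < best) best = cand;
    }
    for (auto& fe : fadj[v]) {
      const double cand = T[fe.first] + fe.second;
      if (cand < best) best = cand;
    }
    return best;
  };
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_change = 0.0;
    if (sweep % 2 == 0) {
      for (int v = 0; v < n; ++v) {
        if (fixed[v]) continue;
        const double nv = update_node(v);
        if (nv < T[v]) { max_change = std::max(max_change, T[v] - nv); T[v] = nv; }
      }
    } else {
      for (int v = n - 1; v >= 0; --v) {
        if (fixed[v]) continue;
        const double nv = update_node(v);
        if (nv < T[v]) { max_change = std::max(max_change, T[v] - nv); T[v] = nv; }
      }
    }
    if (max_change < tol && sweep > 1) break;
    if ((sweep & 7) == 0) Rcpp::checkUserInterrupt();
  }
  return NumericVector(T.begin(), T.end());
}
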