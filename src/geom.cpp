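#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact symmetric Chamfer distance between two point sets (rows are points,
// 3 columns). Brute-force O(n1*n2) nearest neighbours; no approximation, so
// the value is directly comparable to an exhaustive oracle.
// squared = FALSE: mean Euclidean NN distance convention (mm);
// squared = TRUE : mean squared NN distance convention (mm^2).
// [[Rcpp::export]]
double cpp_chamfer(NumericMatrix P, NumericMatrix Q, bool squared) {
  const int n = P.nrow(), m = Q.nrow();
  const double *px = &P(0, 0), *py = &P(0, 1), *pz = &P(0, 2);
  const double *qx = &Q(0, 0), *qy = &Q(0, 1), *qz = &Q(0, 2);
  std::vector<double> minq(m, R_PosInf);
  double sump = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double xi = px[i], yi = py[i], zi = pz[i];
    for (int j = 0; j < m; ++j) {
      const double dx = xi - qx[j], dy = yi - qy[j], dz = zi - qz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
      if (d2 < minq[j]) minq[j] = d2;
    }
    sump += squared ? best : std::sqrt(best);
  }
  double sumq = 0.0;
  for (int j = 0; j < m; ++j) sumq += squared ? minq[j] : std::sqrt(minq[j]);
  return 0.5 * (sump / n + sumq / m);
}

// For each row of P, the Euclidean distance to its nearest neighbour in Q.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix P, NumericMatrix Q) {
  const int n = P.nrow(), m = Q.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = P(i, 0) - Q(j, 0), dy = P(i, 1) - Q(j, 1),
                   dz = P(i, 2) - Q(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Parity (even-odd) point-in-solid classification of a lattice of points
// against a closed triangulated surface, cast along +x. The grid is the
// tensor product xs x ys x zs; returns a logical vector in x-fastest order.
// Watertight input is assumed; triangles are treated as closed sets with a
// small jitter applied to the ray origin to dodge degenerate hits.
// [[Rcpp::export]]
LogicalVector cpp_grid_inside(NumericVector xs, NumericVector ys,
                              NumericVector zs, NumericMatrix V,
                              IntegerMatrix F) {
  const int nx = xs.size(), ny = ys.size(), nz = zs.size();
  const int nf = F.nrow();
  LogicalVector out((size_t)nx * ny * nz);
  // Precompute triangle vertex coordinates.
  std::vector<double> ax(nf), ay(nf), az(nf), bx(nf), by(nf), bz(nf), cx(nf),
      cy(nf), cz(nf), ymin(nf), ymax(nf), zmin(nf), zmax(nf);
  for (int f = 0; f < nf; ++f) {
    const int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    ax[f] = V(i0, 0); ay[f] = V(i0, 1); az[f] = V(i0, 2);
    bx[f] = V(i1, 0); by[f] = V(i1, 1); bz[f] = V(i1, 2);
    cx[f] = V(i2, 0); cy[f] = V(i2, 1); cz[f] = V(i2, 2);
    ymin[f] = std::min({ay[f], by[f], cy[f]});
    ymax[f] = std::max({ay[f], by[f], cy[f]});
    zmin[f] = std::min({az[f], bz[f], cz[f]});
    zmax[f] = std::max({az[f], bz[f], cz[f]});
  }
  const double eps = 1e-9;
  std::vector<double> hits;
  for (int iz = 0; iz < nz; ++iz) {
    for (int iy = 0; iy < ny; ++iy) {
      const double ry = ys[iy] + 2.3e-7, rz = zs[iz] + 1.7e-7;
      hits.clear();
      for (int f = 0; f < nf; ++f) {
        if (ry < ymin[f] - eps || ry > ymax[f] + eps || rz < zmin[f] - eps ||
            rz > zmax[f] + eps)
          continue;
        // Solve for intersection of the line {y=ry, z=rz} with triangle f
        // in the (y,z) plane, then recover x by barycentric interpolation.
        const double d1y = by[f] - ay[f], d1z = bz[f] - az[f];
        const double d2y = cy[f] - ay[f], d2z = cz[f] - az[f];
        const double det = d1y * d2z - d1z * d2y;
        if (std::fabs(det) < 1e-14) continue;
        const double wy = ry - ay[f], wz = rz - az[f];
        const double u = (wy * d2z - wz * d2y) / det;
        const double v = (d1y * wz - d1z * wy) / det;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        hits.push_back(ax[f] + u * (bx[f] - ax[f]) + v * (cx[f] - ax[f]));
      }
      if (hits.empty()) continue;
      std::sort(hits.begin(), hits.end());
      const size_t base = (size_t)iz * nx * ny + (size_t)iy * nx;
      for (int ix = 0; ix < nx; ++ix) {
        const double x = xs[ix];
        // count hits strictly greater than x
        size_t lo = std::upper_bound(hits.begin(), hits.end(), x) - hits.begin();
        out[base + ix] = ((hits.size() - lo) % 2) == 1;
      }
    }
  }
  return out;
}

// Pseudo-ECG dipole-density integral.
// For each electrode e and time t:
//   phi_e(t) = sum_el  w'(t - act_el) * ( -grad_act_el . grad(1/r_el) ) * vol_el
// where w is a smooth unit upstroke with the given rise time, grad_act is the
// per-element activation-time gradient and r_el the centroid-electrode
// distance. Amplitudes are in normalized units.
// [[Rcpp::export]]
NumericMatrix cpp_pseudo_ecg(NumericMatrix centroids, NumericMatrix grad_act,
                             NumericVector act, NumericVector vol,
                             NumericMatrix electrodes, NumericVector tgrid,
                             double rise_ms) {
  const int nel = centroids.nrow(), ne = electrodes.nrow(), nt = tgrid.size();
  NumericMatrix out(nt, ne);
  const double inv_rise = 1.0 / rise_ms;
  for (int e = 0; e < ne; ++e) {
    const double ex = electrodes(e, 0), ey = electrodes(e, 1),
                 ez = electrodes(e, 2);
    for (int k = 0; k < nel; ++k) {
      const double rx = ex - centroids(k, 0), ry = ey - centroids(k, 1),
                   rz = ez - centroids(k, 2);
      const double r2 = rx * rx + ry * ry + rz * rz;
      const double r = std::sqrt(r2);
      // grad(1/r) wrt source position = r_vec / r^3 (pointing to electrode)
      const double gx = rx / (r2 * r), gy = ry / (r2 * r), gz = rz / (r2 * r);
      const double lead_field =
          -(grad_act(k, 0) * gx + grad_act(k, 1) * gy + grad_act(k, 2) * gz) *
          vol[k];
      if (lead_field == 0.0) continue;
      const double a = act[k];
      for (int it = 0; it < nt; ++it) {
        // derivative of smoothstep upstroke centered at activation time
        const double s = (tgrid[it] - a) * inv_rise + 0.5;
        if (s <= 0.0 || s >= 1.0) continue;
        const double dw = 6.0 * s * (1.0 - s) * inv_rise;
        out(it, e) += dw * lead_field;
      }
    }
  }
  return out;
}
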