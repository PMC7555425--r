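#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

#include <algorithm>
#include <vector>

// Directed nearest-neighbour distances between two point sets (mm).
// For each row of A, the minimum Euclidean distance to any row of B.
// B is sorted along the first coordinate; the scan expands outward from
// the insertion point and prunes once the coordinate gap alone exceeds
// the current best, giving near-linear behaviour on mask surfaces.
// [[Rcpp::export]]
NumericVector cpp_directed_min_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  std::vector<int> ord(nb);
  for (int j = 0; j < nb; ++j) ord[j] = j;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return B(a, 0) < B(b, 0); });
  std::vector<double> bx(nb), by(nb), bz(nb);
  for (int j = 0; j < nb; ++j) {
    bx[j] = B(ord[j], 0);
    by[j] = B(ord[j], 1);
    bz[j] = B(ord[j], 2);
  }
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = DBL_MAX;
    const int start = (int)(std::lower_bound(bx.begin(), bx.end(), ax) -
                            bx.begin());
    int lo = start - 1, hi = start;
    while (lo >= 0 || hi < nb) {
      const double dlo = lo >= 0 ? ax - bx[lo] : DBL_MAX;
      const double dhi = hi < nb ? bx[hi] - ax : DBL_MAX;
      const int j = (dlo <= dhi) ? lo : hi;
      const double dx = std::min(dlo, dhi);
      if (dx * dx >= best) break;
      if (dlo <= dhi) --lo; else ++hi;
      const double dy = ay - by[j], dz = az - bz[j];
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Maximum pairwise Euclidean distance within one point set (mm).
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix P) {
  const int n = P.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = P(i, 0) - P(j, 0);
      const double dy = P(i, 1) - P(j, 1);
      const double dz = P(i, 2) - P(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d > best) best = d;
    }
  }
  return std::sqrt(best);
}

// Cyclic coordinate descent for the lasso
//   min_b 1/(2n) ||y - X b||^2 + lambda ||b||_1
// X must be standardized so that each column has mean 0 and x_j'x_j/n = 1;
// y is centred by the caller. Warm-started from `beta0`. Converges on the
// active set, then runs a full sweep to admit violators (standard strategy).
// [[Rcpp::export]]
NumericVector cpp_lasso_cd(NumericMatrix X, NumericVector y, double lambda,
                           NumericVector beta0, double tol = 1e-9,
                           int max_iter = 5000) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector beta = clone(beta0);
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      const double bj = beta[j];
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * bj;
    }
  }
  auto update = [&](int j) -> double {
    const double bj = beta[j];
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += X(i, j) * r[i];
    double z = bj + dot / n;
    double bn = 0.0;
    if (z > lambda) bn = z - lambda;
    else if (z < -lambda) bn = z + lambda;
    if (bn != bj) {
      const double d = bn - bj;
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
      beta[j] = bn;
      return std::fabs(d);
    }
    return 0.0;
  };
  int iter = 0;
  while (iter < max_iter) {
    // full sweep
    double delta = 0.0;
    for (int j = 0; j < p; ++j) delta = std::max(delta, update(j));
    ++iter;
    if (delta < tol) break;
    // iterate the active set to convergence
    while (iter < max_iter) {
      double d2 = 0.0;
      for (int j = 0; j < p; ++j)
        if (beta[j] != 0.0) d2 = std::max(d2, update(j));
      ++iter;
      if (d2 < tol) break;
    }
  }
  return beta;
}

static inline void cross3(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Triangulated isosurface of a binary mask at level 0.5: marching
// tetrahedra on the Freudenthal (6-tetrahedra) decomposition of each
// grid cell, crossing vertices at edge midpoints. The Freudenthal
// split is face-compatible across neighbouring cells and the grid is
// scanned one voxel beyond the mask, so the triangle soup is a closed,
// watertight surface. Returns c(surface area mm^2, enclosed volume mm^3);
// volume via the divergence theorem with every triangle oriented outward
// (normal pointing away from the inside vertices of its tetrahedron).
// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(IntegerVector mask, IntegerVector dims,
                                   NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // the 6 vertex-permutation paths from cell corner (0,0,0) to (1,1,1)
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  double area = 0.0, vol = 0.0;

  auto value = [&](int x, int y, int z) -> int {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return mask[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
  };

  double pos[4][3];
  int val[4];

  for (int z = -1; z < nz; ++z) {
    for (int y = -1; y < ny; ++y) {
      for (int x = -1; x < nx; ++x) {
        // skip uniform cells fast
        int s = 0;
        for (int c = 0; c < 8; ++c)
          s += value(x + (c & 1), y + ((c >> 1) & 1), z + ((c >> 2) & 1));
        if (s == 0 || s == 8) continue;

        for (int t = 0; t < 6; ++t) {
          int off[4][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {1, 1, 1}};
          off[1][perms[t][0]] = 1;
          off[2][perms[t][0]] = 1;
          off[2][perms[t][1]] = 1;
          int k = 0;
          for (int v = 0; v < 4; ++v) {
            const int vx = x + off[v][0], vy = y + off[v][1], vz = z + off[v][2];
            val[v] = value(vx, vy, vz);
            pos[v][0] = vx * sx;
            pos[v][1] = vy * sy;
            pos[v][2] = vz * sz;
            k += val[v];
          }
          if (k == 0 || k == 4) continue;

          int ins[4], outs[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) (val[v] ? ins[ni++] : outs[no++]) = v;

          double inside[3] = {0, 0, 0};
          for (int v = 0; v < ni; ++v)
            for (int c = 0; c < 3; ++c) inside[c] += pos[ins[v]][c] / ni;

          auto mid = [&](int u, int v, double m[3]) {
            for (int c = 0; c < 3; ++c) m[c] = 0.5 * (pos[u][c] + pos[v][c]);
          };

          double tris[2][3][3];
          int ntri = 0;
          if (ni == 1) {
            mid(ins[0], outs[0], tris[0][0]);
            mid(ins[0], outs[1], tris[0][1]);
            mid(ins[0], outs[2], tris[0][2]);
            ntri = 1;
          } else if (ni == 3) {
            mid(outs[0], ins[0], tris[0][0]);
            mid(outs[0], ins[1], tris[0][1]);
            mid(outs[0], ins[2], tris[0][2]);
            ntri = 1;
          } else {  // ni == 2: quad split into two triangles
            double q[4][3];
            mid(ins[0], outs[0], q[0]);
            mid(ins[0], outs[1], q[1]);
            mid(ins[1], outs[1], q[2]);
            mid(ins[1], outs[0], q[3]);
            for (int c = 0; c < 3; ++c) {
              tris[0][0][c] = q[0][c]; tris[0][1][c] = q[1][c]; tris[0][2][c] = q[2][c];
              tris[1][0][c] = q[0][c]; tris[1][1][c] = q[2][c]; tris[1][2][c] = q[3][c];
            }
            ntri = 2;
          }

          for (int ti = 0; ti < ntri; ++ti) {
            double *p0 = tris[ti][0], *p1 = tris[ti][1], *p2 = tris[ti][2];
            double e1[3], e2[3], nrm[3], cen[3], toin[3];
            for (int c = 0; c < 3; ++c) {
              e1[c] = p1[c] - p0[c];
              e2[c] = p2[c] - p0[c];
              cen[c] = (p0[c] + p1[c] + p2[c]) / 3.0;
            }
            cross3(e1, e2, nrm);
            for (int c = 0; c < 3; ++c) toin[c] = inside[c] - cen[c];
            const double dp = nrm[0] * toin[0] + nrm[1] * toin[1] + nrm[2] * toin[2];
            if (dp > 0) {  // flip so the normal points away from the inside
              double *tmp = p1; p1 = p2; p2 = tmp;
              for (int c = 0; c < 3; ++c) nrm[c] = -nrm[c];
            }
            area += 0.5 * std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2]);
            double c12[3];
            cross3(p1, p2, c12);
            vol += (p0[0] * c12[0] + p0[1] * c12[1] + p0[2] * c12[2]) / 6.0;
          }
        }
      }
    }
  }
  return NumericVector::create(area, std::fabs(vol));
}
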