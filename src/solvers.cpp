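#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Gauss-Seidel / SOR sweeps for the coupled linear-elastic (viscous) system
//   mu * Lap(v) + (mu + lam) * grad(div v) = -F
// on a regular grid with the velocity clamped to 0 on the boundary ring.
// v and f are (nx*ny*nz*3) arrays in R storage order; v is updated in place.
// If `active` is non-empty only flagged voxels are updated (SORA); `updmag`
// (length nx*ny*nz) receives the largest absolute update seen per voxel over
// the sweeps, which the caller uses to grow the active set.
// [[Rcpp::export]]
void cpp_sor_sweeps(NumericVector v, NumericVector f,
                    int nx, int ny, int nz,
                    double mu, double lam, double omega, int nsweeps,
                    LogicalVector active, NumericVector updmag) {
  const int nxy = nx * ny;
  const int n = nxy * nz;
  const bool useActive = active.size() == n;
  const double ml = mu + lam;
  // Laplacian: 7-point stencil; grad(div) diagonal: central-difference
  // divergence then central-difference gradient, i.e. (v(+2e)-2v+v(-2e))/4
  const double diag = -(6.0 * mu + 0.5 * ml);
  double *V = REAL(v);
  const double *F = REAL(f);
  double *U = REAL(updmag);
  for (int i = 0; i < n; ++i) U[i] = 0.0;
  const int stride[3] = {1, nx, nxy};

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        for (int i = 1; i < nx - 1; ++i) {
          const int id = i + nx * j + nxy * k;
          if (useActive && !active[id]) continue;
          double maxupd = 0.0;
          for (int c = 0; c < 3; ++c) {
            double *vc = V + (size_t)c * n;
            // 7-point Laplacian neighbours
            double lap = vc[id - 1] + vc[id + 1]
                       + vc[id - nx] + vc[id + nx]
                       + vc[id - nxy] + vc[id + nxy];
            // grad(div) diagonal part: wide second difference along axis c,
            // out-of-grid reads are 0 (clamped boundary)
            const int coord = (c == 0) ? i : ((c == 1) ? j : k);
            const int cmax = (c == 0) ? nx : ((c == 1) ? ny : nz);
            const double vp2 = (coord + 2 <= cmax - 1) ? vc[id + 2 * stride[c]] : 0.0;
            const double vm2 = (coord - 2 >= 0) ? vc[id - 2 * stride[c]] : 0.0;
            const double djj = 0.25 * (vp2 + vm2);
            // cross terms: sum_{a != c} d2 v_a / (dx_a dx_c), central diffs
            double cross = 0.0;
            for (int a = 0; a < 3; ++a) {
              if (a == c) continue;
              const double *va = V + (size_t)a * n;
              cross += (va[id + stride[a] + stride[c]]
                      - va[id + stride[a] - stride[c]]
                      - va[id - stride[a] + stride[c]]
                      + va[id - stride[a] - stride[c]]) * 0.25;
            }
            const double off = mu * lap + ml * (djj + cross);
            const double gs = (-F[(size_t)c * n + id] - off) / diag;
            const double vnew = (1.0 - omega) * vc[id] + omega * gs;
            const double d = std::abs(vnew - vc[id]);
            if (d > maxupd) maxupd = d;
            vc[id] = vnew;
          }
          if (maxupd > U[id]) U[id] = maxupd;
        }
      }
    }
  }
}

// 3D connected-component labelling of a binary mask, 6-connectivity.
// Returns an integer array of labels (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, int nx, int ny, int nz) {
  const int nxy = nx * ny;
  const int n = nxy * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    lab[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      const int id = q.front(); q.pop();
      const int i = id % nx, j = (id / nx) % ny, k = id / nxy;
      const int nb[6] = {i > 0 ? id - 1 : -1, i < nx - 1 ? id + 1 : -1,
                         j > 0 ? id - nx : -1, j < ny - 1 ? id + nx : -1,
                         k > 0 ? id - nxy : -1, k < nz - 1 ? id + nxy : -1};
      for (int t = 0; t < 6; ++t) {
        const int m = nb[t];
        if (m >= 0 && mask[m] && lab[m] == 0) { lab[m] = next; q.push(m); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  return lab;
}
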