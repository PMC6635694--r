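// Low-level geometry kernels: solid voxelization of a triangle mesh by
// x-ray parity, a 3-4-5-style chamfer signed distance transform on a
// cell-centred grid, marching-tetrahedra isosurface extraction with
// exact edge-keyed vertex sharing, and trilinear field sampling.
//
// All grids are cell-centred: cell (i,j,k) (0-based) has its centre at
// origin + (i + 0.5) * pitch, and field values are attached to centres.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline std::int64_t lin3(int i, int j, int k, int nx, int ny) {
  return (std::int64_t)i + (std::int64_t)nx * ((std::int64_t)j + (std::int64_t)ny * (std::int64_t)k);
}

// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, double pitch,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nf = F.nrow();
  // tiny deterministic ray offset avoids hitting triangle edges exactly
  const double eps = pitch * 1.234567e-4;
  std::vector< std::vector<double> > hits((std::size_t)ny * nz);

  for (int f = 0; f < nf; ++f) {
    const int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    const double ax = V(a,0), ay = V(a,1), az = V(a,2);
    const double bx = V(b,0), by = V(b,1), bz = V(b,2);
    const double cx = V(c,0), cy = V(c,1), cz = V(c,2);
    double ymin = std::min(ay, std::min(by, cy)), ymax = std::max(ay, std::max(by, cy));
    double zmin = std::min(az, std::min(bz, cz)), zmax = std::max(az, std::max(bz, cz));
    int j0 = (int)std::floor((ymin - origin[1]) / pitch - 0.5 - eps);
    int j1 = (int)std::ceil ((ymax - origin[1]) / pitch - 0.5 + eps);
    int k0 = (int)std::floor((zmin - origin[2]) / pitch - 0.5 - eps);
    int k1 = (int)std::ceil ((zmax - origin[2]) / pitch - 0.5 + eps);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    const double d1y = by - ay, d1z = bz - az;
    const double d2y = cy - ay, d2z = cz - az;
    const double det = d1y * d2z - d1z * d2y;
    if (std::fabs(det) < 1e-300) continue; // degenerate in y-z projection
    for (int k = k0; k <= k1; ++k) {
      const double rz = origin[2] + (k + 0.5) * pitch + eps;
      for (int j = j0; j <= j1; ++j) {
        const double ry = origin[1] + (j + 0.5) * pitch + eps;
        const double py = ry - ay, pz = rz - az;
        const double u = (py * d2z - pz * d2y) / det;
        const double v = (d1y * pz - d1z * py) / det;
        if (u < 0.0 || v < 0.0 || u + v > 1.0) continue;
        const double x = ax + u * (bx - ax) + v * (cx - ax);
        hits[(std::size_t)j + (std::size_t)ny * k].push_back(x);
      }
    }
  }

  LogicalVector occ((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      std::vector<double> &h = hits[(std::size_t)j + (std::size_t)ny * k];
      if (h.empty()) continue;
      std::sort(h.begin(), h.end());
      // drop an unpaired trailing crossing (rare degeneracy)
      const std::size_t npair = h.size() / 2;
      for (std::size_t p = 0; p < npair; ++p) {
        const double x0 = h[2 * p], x1 = h[2 * p + 1];
        int i0 = (int)std::ceil ((x0 - origin[0]) / pitch - 0.5);
        int i1 = (int)std::floor((x1 - origin[0]) / pitch - 0.5);
        i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
        for (int i = i0; i <= i1; ++i)
          occ[lin3(i, j, k, nx, ny)] = TRUE;
      }
    }
  }
  return occ;
}

static void chamfer_pass(std::vector<double> &d, int nx, int ny, int nz) {
  const double w1 = 1.0, w2 = std::sqrt(2.0), w3 = std::sqrt(3.0);
  // 13 forward neighbours (and mirrored backward ones)
  const int off[13][3] = {
    {-1, 0, 0}, {0, -1, 0}, {0, 0, -1},
    {-1, -1, 0}, {-1, 1, 0}, {-1, 0, -1}, {-1, 0, 1}, {0, -1, -1}, {0, -1, 1},
    {-1, -1, -1}, {-1, -1, 1}, {-1, 1, -1}, {-1, 1, 1}
  };
  const double w[13] = {w1, w1, w1, w2, w2, w2, w2, w2, w2, w3, w3, w3, w3};
  // forward
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double v = d[lin3(i, j, k, nx, ny)];
        for (int m = 0; m < 13; ++m) {
          const int ii = i + off[m][0], jj = j + off[m][1], kk = k + off[m][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          const double cand = d[lin3(ii, jj, kk, nx, ny)] + w[m];
          if (cand < v) v = cand;
        }
        d[lin3(i, j, k, nx, ny)] = v;
      }
  // backward
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        double v = d[lin3(i, j, k, nx, ny)];
        for (int m = 0; m < 13; ++m) {
          const int ii = i - off[m][0], jj = j - off[m][1], kk = k - off[m][2];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          const double cand = d[lin3(ii, jj, kk, nx, ny)] + w[m];
          if (cand < v) v = cand;
        }
        d[lin3(i, j, k, nx, ny)] = v;
      }
}

// Signed distance (in voxel units) from an occupancy grid: negative
// inside, positive outside, zero level midway between an occupied and
// an empty cell centre.
// [[Rcpp::export]]
NumericVector cpp_chamfer_sdf(LogicalVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const std::int64_t n = (std::int64_t)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> dout((std::size_t)n), din((std::size_t)n);
  for (std::int64_t t = 0; t < n; ++t) {
    dout[(std::size_t)t] = occ[t] ? INF : 0.0; // distance to nearest empty
    din [(std::size_t)t] = occ[t] ? 0.0 : INF; // distance to nearest occupied
  }
  chamfer_pass(dout, nx, ny, nz);
  chamfer_pass(din, nx, ny, nz);
  NumericVector sdf((R_xlen_t)n);
  for (std::int64_t t = 0; t < n; ++t) {
    if (occ[t]) sdf[t] = -(dout[(std::size_t)t] - 0.5);
    else        sdf[t] =  (din [(std::size_t)t] - 0.5);
  }
  return sdf;
}

// Marching tetrahedra over the cell-centre lattice. Triangles are
// oriented so normals point toward increasing field (field = signed
// distance, so outward). Vertices shared exactly via edge keys.
// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, IntegerVector dims,
                        NumericVector origin, double pitch, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::unordered_map<std::uint64_t, int> edge_vertex;
  std::vector<double> VX, VY, VZ;
  std::vector<int> FA, FB, FC;

  auto gp = [&](std::int64_t id, double *p) {
    const int i = (int)(id % nx);
    const int j = (int)((id / nx) % ny);
    const int k = (int)(id / ((std::int64_t)nx * ny));
    p[0] = origin[0] + (i + 0.5) * pitch;
    p[1] = origin[1] + (j + 0.5) * pitch;
    p[2] = origin[2] + (k + 0.5) * pitch;
  };

  auto edge_point = [&](std::int64_t a, std::int64_t b) -> int {
    std::int64_t lo = std::min(a, b), hi = std::max(a, b);
    // edges stay within one cube, so hi - lo < nx*ny + nx + 2 << 2^24
    const std::uint64_t key2 = ((std::uint64_t)lo << 24) | (std::uint64_t)(hi - lo);
    auto it = edge_vertex.find(key2);
    if (it != edge_vertex.end()) return it->second;
    double pa[3], pb[3];
    gp(a, pa); gp(b, pb);
    const double va = field[a], vb = field[b];
    double t = (iso - va) / (vb - va);
    if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
    VX.push_back(pa[0] + t * (pb[0] - pa[0]));
    VY.push_back(pa[1] + t * (pb[1] - pa[1]));
    VZ.push_back(pa[2] + t * (pb[2] - pa[2]));
    const int idx = (int)VX.size(); // 1-based
    edge_vertex.emplace(key2, idx);
    return idx;
  };

  auto emit = [&](int a, int b, int c, const double *g) {
    // orient so cross(B-A, C-A) . grad > 0
    const double ax = VX[a-1], ay = VY[a-1], az = VZ[a-1];
    const double bx = VX[b-1], by = VY[b-1], bz = VZ[b-1];
    const double cx = VX[c-1], cy = VY[c-1], cz = VZ[c-1];
    const double ux = bx-ax, uy = by-ay, uz = bz-az;
    const double vx = cx-ax, vy = cy-ay, vz = cz-az;
    const double nxn = uy*vz - uz*vy, nyn = uz*vx - ux*vz, nzn = ux*vy - uy*vx;
    if (nxn*g[0] + nyn*g[1] + nzn*g[2] < 0.0) std::swap(b, c);
    FA.push_back(a); FB.push_back(b); FC.push_back(c);
  };

  const int tets[6][4] = {
    {0,5,1,6}, {0,1,2,6}, {0,2,3,6}, {0,3,7,6}, {0,7,4,6}, {0,4,5,6}
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        const std::int64_t c[8] = {
          lin3(i,   j,   k,   nx, ny), lin3(i+1, j,   k,   nx, ny),
          lin3(i+1, j+1, k,   nx, ny), lin3(i,   j+1, k,   nx, ny),
          lin3(i,   j,   k+1, nx, ny), lin3(i+1, j,   k+1, nx, ny),
          lin3(i+1, j+1, k+1, nx, ny), lin3(i,   j+1, k+1, nx, ny)
        };
        // quick reject: all same side
        bool anyin = false, anyout = false;
        for (int m = 0; m < 8; ++m) {
          if (field[c[m]] < iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          const std::int64_t p[4] = {c[tets[t][0]], c[tets[t][1]], c[tets[t][2]], c[tets[t][3]]};
          const double v[4] = {field[p[0]], field[p[1]], field[p[2]], field[p[3]]};
          int in[4], nin = 0, out[4], nout = 0;
          for (int m = 0; m < 4; ++m) {
            if (v[m] < iso) in[nin++] = m; else out[nout++] = m;
          }
          if (nin == 0 || nin == 4) continue;
          // linear gradient of field within tet (for orientation)
          double P[4][3];
          for (int m = 0; m < 4; ++m) gp(p[m], P[m]);
          double M[3][3], rhs[3], g[3];
          for (int r = 0; r < 3; ++r) {
            for (int s = 0; s < 3; ++s) M[r][s] = P[r+1][s] - P[0][s];
            rhs[r] = v[r+1] - v[0];
          }
          const double det =
            M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1]) -
            M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0]) +
            M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
          if (std::fabs(det) < 1e-300) continue;
          g[0] = (rhs[0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1]) -
                  M[0][1]*(rhs[1]*M[2][2]-M[1][2]*rhs[2]) +
                  M[0][2]*(rhs[1]*M[2][1]-M[1][1]*rhs[2])) / det;
          g[1] = (M[0][0]*(rhs[1]*M[2][2]-M[1][2]*rhs[2]) -
                  rhs[0]*(M[1][0]*M[2][2]-M[1][2]*M[2][0]) +
                  M[0][2]*(M[1][0]*rhs[2]-rhs[1]*M[2][0])) / det;
          g[2] = (M[0][0]*(M[1][1]*rhs[2]-rhs[1]*M[2][1]) -
                  M[0][1]*(M[1][0]*rhs[2]-rhs[1]*M[2][0]) +
                  rhs[0]*(M[1][0]*M[2][1]-M[1][1]*M[2][0])) / det;

          if (nin == 1) {
            const int A = in[0];
            emit(edge_point(p[A], p[out[0]]),
                 edge_point(p[A], p[out[1]]),
                 edge_point(p[A], p[out[2]]), g);
          } else if (nin == 3) {
            const int A = out[0];
            emit(edge_point(p[A], p[in[0]]),
                 edge_point(p[A], p[in[1]]),
                 edge_point(p[A], p[in[2]]), g);
          } else { // nin == 2
            const int A = in[0], B = in[1], C = out[0], D = out[1];
            const int ac = edge_point(p[A], p[C]);
            const int ad = edge_point(p[A], p[D]);
            const int bc = edge_point(p[B], p[C]);
            const int bd = edge_point(p[B], p[D]);
            emit(ac, ad, bd, g);
            emit(ac, bd, bc, g);
          }
        }
      }

  const int nv = (int)VX.size(), nf = (int)FA.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int m = 0; m < nv; ++m) { V(m,0)=VX[m]; V(m,1)=VY[m]; V(m,2)=VZ[m]; }
  for (int m = 0; m < nf; ++m) { F(m,0)=FA[m]; F(m,1)=FB[m]; F(m,2)=FC[m]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Trilinear sampling of a cell-centred field at arbitrary points (mm).
// Points outside the grid interior are clamped to the border cells.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector field, IntegerVector dims,
                            NumericVector origin, double pitch,
                            NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = pts.nrow();
  NumericVector out(np);
  for (int m = 0; m < np; ++m) {
    double gx = (pts(m,0) - origin[0]) / pitch - 0.5;
    double gy = (pts(m,1) - origin[1]) / pitch - 0.5;
    double gz = (pts(m,2) - origin[2]) / pitch - 0.5;
    gx = std::min(std::max(gx, 0.0), (double)(nx - 1) - 1e-9);
    gy = std::min(std::max(gy, 0.0), (double)(ny - 1) - 1e-9);
    gz = std::min(std::max(gz, 0.0), (double)(nz - 1) - 1e-9);
    const int i = (int)gx, j = (int)gy, k = (int)gz;
    const double fx = gx - i, fy = gy - j, fz = gz - k;
    double acc = 0.0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          const double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          acc += w * field[lin3(i + di, j + dj, k + dk, nx, ny)];
        }
    out[m] = acc;
  }
  return out;
}
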