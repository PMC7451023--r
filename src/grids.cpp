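#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Accumulate unit-amplitude Gaussian kernels, one per atom, onto a regular
// grid. Truncation is a per-axis box of half-width cutoff_sigmas * sigma
// (a superset of the spherical cutoff; separable and slightly more exact).
// Grid linear index: ix + nx * (iy + ny * iz), matching R array layout.
static void accumulate_frame(std::vector<double> &buf,
                             const double *x, const double *y, const double *z,
                             int natoms,
                             const double *origin, double spacing,
                             int nx, int ny, int nz,
                             double sigma, double cutoff_sigmas) {
  const double r = cutoff_sigmas * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> gx, gy, gz;
  for (int a = 0; a < natoms; ++a) {
    const double cx = x[a], cy = y[a], cz = z[a];
    // 1e-6-voxel slack keeps box-edge inclusion stable under joint
    // translations of coordinates and origin (equivariance to 1e-9)
    const double eps = 1e-6;
    int lx = (int)std::ceil((cx - r - origin[0]) / spacing - eps);
    int hx = (int)std::floor((cx + r - origin[0]) / spacing + eps);
    int ly = (int)std::ceil((cy - r - origin[1]) / spacing - eps);
    int hy = (int)std::floor((cy + r - origin[1]) / spacing + eps);
    int lz = (int)std::ceil((cz - r - origin[2]) / spacing - eps);
    int hz = (int)std::floor((cz + r - origin[2]) / spacing + eps);
    if (lx < 0) lx = 0; if (hx > nx - 1) hx = nx - 1;
    if (ly < 0) ly = 0; if (hy > ny - 1) hy = ny - 1;
    if (lz < 0) lz = 0; if (hz > nz - 1) hz = nz - 1;
    if (lx > hx || ly > hy || lz > hz) continue;
    gx.resize(hx - lx + 1); gy.resize(hy - ly + 1); gz.resize(hz - lz + 1);
    for (int i = lx; i <= hx; ++i) {
      double d = origin[0] + i * spacing - cx;
      gx[i - lx] = std::exp(-d * d * inv2s2);
    }
    for (int j = ly; j <= hy; ++j) {
      double d = origin[1] + j * spacing - cy;
      gy[j - ly] = std::exp(-d * d * inv2s2);
    }
    for (int k = lz; k <= hz; ++k) {
      double d = origin[2] + k * spacing - cz;
      gz[k - lz] = std::exp(-d * d * inv2s2);
    }
    for (int k = lz; k <= hz; ++k) {
      const double wz = gz[k - lz];
      for (int j = ly; j <= hy; ++j) {
        const double wyz = gy[j - ly] * wz;
        double *row = buf.data() + (size_t)nx * (j + (size_t)ny * k);
        for (int i = lx; i <= hx; ++i)
          row[i] += gx[i - lx] * wyz;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector density_grid_cpp(NumericMatrix coords, NumericVector origin,
                               double spacing, IntegerVector dims,
                               double sigma, double cutoff_sigmas) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nv = (size_t)nx * ny * nz;
  std::vector<double> buf(nv, 0.0);
  const int natoms = coords.nrow();
  std::vector<double> x(natoms), y(natoms), z(natoms);
  for (int a = 0; a < natoms; ++a) {
    x[a] = coords(a, 0); y[a] = coords(a, 1); z[a] = coords(a, 2);
  }
  accumulate_frame(buf, x.data(), y.data(), z.data(), natoms,
                   origin.begin(), spacing, nx, ny, nz, sigma, cutoff_sigmas);
  NumericVector out(nv);
  std::copy(buf.begin(), buf.end(), out.begin());
  return out;
}

// Welford accumulation of per-voxel mean and M2 over frame densities.
// coords is a T x N x 3 array (R layout: t + T*(i + N*j)).
// [[Rcpp::export]]
List ensemble_grid_stats_cpp(NumericVector coords, int nframes, int natoms,
                             NumericVector origin, double spacing,
                             IntegerVector dims, double sigma,
                             double cutoff_sigmas) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nv = (size_t)nx * ny * nz;
  std::vector<double> mean(nv, 0.0), m2(nv, 0.0), buf(nv, 0.0);
  std::vector<double> x(natoms), y(natoms), z(natoms);
  const double *cd = coords.begin();
  for (int t = 0; t < nframes; ++t) {
    std::fill(buf.begin(), buf.end(), 0.0);
    for (int i = 0; i < natoms; ++i) {
      x[i] = cd[t + (size_t)nframes * i];
      y[i] = cd[t + (size_t)nframes * (i + (size_t)natoms)];
      z[i] = cd[t + (size_t)nframes * (i + 2 * (size_t)natoms)];
    }
    accumulate_frame(buf, x.data(), y.data(), z.data(), natoms,
                     origin.begin(), spacing, nx, ny, nz, sigma,
                     cutoff_sigmas);
    const double inv_t = 1.0 / (t + 1);
    for (size_t v = 0; v < nv; ++v) {
      const double delta = buf[v] - mean[v];
      mean[v] += delta * inv_t;
      m2[v] += delta * (buf[v] - mean[v]);
    }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector mean_out(nv), m2_out(nv);
  std::copy(mean.begin(), mean.end(), mean_out.begin());
  std::copy(m2.begin(), m2.end(), m2_out.begin());
  return List::create(_["mean"] = mean_out, _["m2"] = m2_out);
}

// ---- marching tetrahedra ---------------------------------------------------
// Cube corner c in 0..7 has offsets (c&1, (c>>1)&1, (c>>2)&1). Each cube is
// split into six tetrahedra sharing the 0-7 diagonal, which makes adjacent
// cubes agree on shared faces (watertight where the field is well-behaved).
static const int TETS[6][4] = {
  {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
  {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
};

struct MeshAcc {
  std::vector<double> verts; // x,y,z triples
  std::vector<int> faces;    // 1-based vertex indices, triples
  void tri(const double *p1, const double *p2, const double *p3) {
    int base = (int)(verts.size() / 3);
    verts.insert(verts.end(), p1, p1 + 3);
    verts.insert(verts.end(), p2, p2 + 3);
    verts.insert(verts.end(), p3, p3 + 3);
    faces.push_back(base + 1);
    faces.push_back(base + 2);
    faces.push_back(base + 3);
  }
};

static inline void interp(double iso, const double *pa, double fa,
                          const double *pb, double fb, double *out) {
  double t = (iso - fa) / (fb - fa);
  for (int d = 0; d < 3; ++d) out[d] = pa[d] + t * (pb[d] - pa[d]);
}

// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector values, IntegerVector dims,
                             NumericVector origin, double spacing,
                             double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *val = values.begin();
  MeshAcc mesh;
  double cpos[8][3], cval[8];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c) {
          const int ci = i + (c & 1), cj = j + ((c >> 1) & 1),
                    ck = k + ((c >> 2) & 1);
          cpos[c][0] = origin[0] + ci * spacing;
          cpos[c][1] = origin[1] + cj * spacing;
          cpos[c][2] = origin[2] + ck * spacing;
          cval[c] = val[ci + (size_t)nx * (cj + (size_t)ny * ck)];
        }
        for (int t = 0; t < 6; ++t) {
          const int *tv = TETS[t];
          int mask = 0;
          for (int v = 0; v < 4; ++v)
            if (cval[tv[v]] > iso) mask |= (1 << v);
          if (mask == 0 || mask == 15) continue;
          // indices of "above" and "below" corners within the tet
          int above[4], below[4], na = 0, nb = 0;
          for (int v = 0; v < 4; ++v) {
            if (mask & (1 << v)) above[na++] = tv[v];
            else below[nb++] = tv[v];
          }
          double p[4][3];
          if (na == 1 || nb == 1) {
            const int lone = (na == 1) ? above[0] : below[0];
            const int *oth = (na == 1) ? below : above;
            for (int e = 0; e < 3; ++e)
              interp(iso, cpos[lone], cval[lone], cpos[oth[e]],
                     cval[oth[e]], p[e]);
            mesh.tri(p[0], p[1], p[2]);
          } else { // 2-2 case: quad across the four crossing edges
            interp(iso, cpos[above[0]], cval[above[0]],
                   cpos[below[0]], cval[below[0]], p[0]);
            interp(iso, cpos[above[0]], cval[above[0]],
                   cpos[below[1]], cval[below[1]], p[1]);
            interp(iso, cpos[above[1]], cval[above[1]],
                   cpos[below[1]], cval[below[1]], p[2]);
            interp(iso, cpos[above[1]], cval[above[1]],
                   cpos[below[0]], cval[below[0]], p[3]);
            mesh.tri(p[0], p[1], p[2]);
            mesh.tri(p[0], p[2], p[3]);
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix v((int)(mesh.verts.size() / 3), 3);
  for (int r = 0; r < v.nrow(); ++r)
    for (int d = 0; d < 3; ++d) v(r, d) = mesh.verts[3 * r + d];
  IntegerMatrix f((int)(mesh.faces.size() / 3), 3);
  for (int r = 0; r < f.nrow(); ++r)
    for (int d = 0; d < 3; ++d) f(r, d) = mesh.faces[3 * r + d];
  return List::create(_["vertices"] = v, _["faces"] = f);
}
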