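#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 1D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher lower envelope of parabolas), physical sample spacing s.
// ---------------------------------------------------------------------------
static void dt1d(const double* f, double* d, int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sint;
    while (true) {
      double xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (sint <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector feature, IntegerVector dims,
                        NumericVector spacing) {
  // Squared Euclidean distance (um^2) from every voxel to the nearest TRUE
  // voxel. dims = (nz, ny, nx), first index fastest; spacing = (dz, dy, dx).
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : INF;

  int m = std::max(nz, std::max(ny, nx));
  std::vector<double> f(m), d(m);

  for (int i = 0; i < nx; ++i)           // along z (fastest axis)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nz * (j + (R_xlen_t)ny * i);
      for (int k = 0; k < nz; ++k) f[k] = out[base + k];
      dt1d(f.data(), d.data(), nz, dz);
      for (int k = 0; k < nz; ++k) out[base + k] = d[k];
    }
  for (int i = 0; i < nx; ++i)           // along y
    for (int k = 0; k < nz; ++k) {
      R_xlen_t base = k + (R_xlen_t)nz * ny * i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nz * j];
      dt1d(f.data(), d.data(), ny, dy);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nz * j] = d[j];
    }
  R_xlen_t stride = (R_xlen_t)nz * ny;
  for (int j = 0; j < ny; ++j)           // along x
    for (int k = 0; k < nz; ++k) {
      R_xlen_t base = k + (R_xlen_t)nz * j;
      for (int i = 0; i < nx; ++i) f[i] = out[base + stride * i];
      dt1d(f.data(), d.data(), nx, dx);
      for (int i = 0; i < nx; ++i) out[base + stride * i] = d[i];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra: isosurface of a scalar field on a regular grid.
// Each grid cube splits into 6 tetrahedra sharing the main diagonal; each
// tetrahedron contributes 0, 1 or 2 triangles with linearly interpolated
// edge crossings. Returns a raw triangle soup (deduplicated in R).
// ---------------------------------------------------------------------------
struct V3 { double x, y, z; };

static inline V3 lerp_vertex(const V3& a, const V3& b, double fa, double fb,
                             double iso) {
  double t = (iso - fa) / (fb - fa);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  V3 r;
  r.x = a.x + t * (b.x - a.x);
  r.y = a.y + t * (b.y - a.y);
  r.z = a.z + t * (b.z - a.z);
  return r;
}

// [[Rcpp::export(name = ".march_tetra_cpp")]]
List march_tetra_cpp(NumericVector field, IntegerVector dims,
                     NumericVector spacing, double iso) {
  // dims = (nz, ny, nx), first index fastest; spacing = (dz, dy, dx).
  // Vertex coordinates are physical (x, y, z) um: voxel (k,j,i) 0-based is
  // centered at ((i+0.5)dx, (j+0.5)dy, (k+0.5)dz).
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  static const int tets[6][4] = {
    {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
    {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
  };
  static const int corner[8][3] = { // (k, j, i) offsets
    {0,0,0}, {1,0,0}, {0,1,0}, {1,1,0}, {0,0,1}, {1,0,1}, {0,1,1}, {1,1,1}
  };
  std::vector<double> vx, vy, vz;
  vx.reserve(4096); vy.reserve(4096); vz.reserve(4096);
  double fc[8];
  V3 pc[8];
  for (int i = 0; i < nx - 1; ++i)
    for (int j = 0; j < ny - 1; ++j)
      for (int k = 0; k < nz - 1; ++k) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int kk = k + corner[c][0], jj = j + corner[c][1], ii = i + corner[c][2];
          double f = field[kk + (R_xlen_t)nz * (jj + (R_xlen_t)ny * ii)];
          fc[c] = f;
          pc[c].x = (ii + 0.5) * dx;
          pc[c].y = (jj + 0.5) * dy;
          pc[c].z = (kk + 0.5) * dz;
          if (f >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int* tv = tets[t];
          int inside[4], outside[4], nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (fc[tv[c]] >= iso) inside[nin++] = tv[c];
            else outside[nout++] = tv[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? inside[0] : outside[0];
            int* oth = (nin == 1) ? outside : inside;
            V3 p1 = lerp_vertex(pc[apex], pc[oth[0]], fc[apex], fc[oth[0]], iso);
            V3 p2 = lerp_vertex(pc[apex], pc[oth[1]], fc[apex], fc[oth[1]], iso);
            V3 p3 = lerp_vertex(pc[apex], pc[oth[2]], fc[apex], fc[oth[2]], iso);
            vx.push_back(p1.x); vy.push_back(p1.y); vz.push_back(p1.z);
            vx.push_back(p2.x); vy.push_back(p2.y); vz.push_back(p2.z);
            vx.push_back(p3.x); vy.push_back(p3.y); vz.push_back(p3.z);
          } else {
            int a = inside[0], b = inside[1], c = outside[0], d = outside[1];
            V3 p1 = lerp_vertex(pc[a], pc[c], fc[a], fc[c], iso);
            V3 p2 = lerp_vertex(pc[a], pc[d], fc[a], fc[d], iso);
            V3 p3 = lerp_vertex(pc[b], pc[d], fc[b], fc[d], iso);
            V3 p4 = lerp_vertex(pc[b], pc[c], fc[b], fc[c], iso);
            vx.push_back(p1.x); vy.push_back(p1.y); vz.push_back(p1.z);
            vx.push_back(p2.x); vy.push_back(p2.y); vz.push_back(p2.z);
            vx.push_back(p3.x); vy.push_back(p3.y); vz.push_back(p3.z);
            vx.push_back(p1.x); vy.push_back(p1.y); vz.push_back(p1.z);
            vx.push_back(p3.x); vy.push_back(p3.y); vz.push_back(p3.z);
            vx.push_back(p4.x); vy.push_back(p4.y); vz.push_back(p4.z);
          }
        }
      }
  R_xlen_t nv = vx.size();
  NumericMatrix verts(nv, 3);
  for (R_xlen_t q = 0; q < nv; ++q) {
    verts(q, 0) = vx[q]; verts(q, 1) = vy[q]; verts(q, 2) = vz[q];
  }
  IntegerMatrix tris(nv / 3, 3);
  for (R_xlen_t q = 0; q < nv / 3; ++q) {
    tris(q, 0) = 3 * q + 1; tris(q, 1) = 3 * q + 2; tris(q, 2) = 3 * q + 3;
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}

// ---------------------------------------------------------------------------
// Label-interface faces: every 6-connected voxel face separating two
// different labels (0 = background; faces on the grid boundary face label 0),
// with face-center physical coordinates and face orientation (1=z, 2=y, 3=x
// normal). Backbone of adjacency areas, wall patches and junction geometry.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".label_faces_cpp")]]
List label_faces_cpp(IntegerVector labels, IntegerVector dims,
                     NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  std::vector<int> la, lb, ax;
  std::vector<double> cx, cy, cz;
  la.reserve(1 << 16);
  auto at = [&](int k, int j, int i) -> int {
    if (k < 0 || j < 0 || i < 0 || k >= nz || j >= ny || i >= nx) return 0;
    return labels[k + (R_xlen_t)nz * (j + (R_xlen_t)ny * i)];
  };
  auto push = [&](int a, int b, int axis, double x, double y, double z) {
    la.push_back(a); lb.push_back(b); ax.push_back(axis);
    cx.push_back(x); cy.push_back(y); cz.push_back(z);
  };
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        int v = at(k, j, i);
        int wz = at(k + 1, j, i);
        if (v != wz) push(v, wz, 1, (i + 0.5) * dx, (j + 0.5) * dy, (k + 1.0) * dz);
        if (k == 0 && v != 0)
          push(0, v, 1, (i + 0.5) * dx, (j + 0.5) * dy, 0.0);
        int wy = at(k, j + 1, i);
        if (v != wy) push(v, wy, 2, (i + 0.5) * dx, (j + 1.0) * dy, (k + 0.5) * dz);
        if (j == 0 && v != 0)
          push(0, v, 2, (i + 0.5) * dx, 0.0, (k + 0.5) * dz);
        int wx = at(k, j, i + 1);
        if (v != wx) push(v, wx, 3, (i + 1.0) * dx, (j + 0.5) * dy, (k + 0.5) * dz);
        if (i == 0 && v != 0)
          push(0, v, 3, 0.0, (j + 0.5) * dy, (k + 0.5) * dz);
      }
  R_xlen_t n = la.size();
  IntegerVector A(n), B(n), AX(n);
  NumericVector X(n), Y(n), Z(n);
  for (R_xlen_t q = 0; q < n; ++q) {
    A[q] = la[q]; B[q] = lb[q]; AX[q] = ax[q];
    X[q] = cx[q]; Y[q] = cy[q]; Z[q] = cz[q];
  }
  return List::create(_["a"] = A, _["b"] = B, _["axis"] = AX,
                      _["x"] = X, _["y"] = Y, _["z"] = Z);
}
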