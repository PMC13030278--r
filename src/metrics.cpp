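#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <array>
using namespace Rcpp;

// ---- separable 3D Gaussian smoothing (sigma in voxel units) ----

static void smooth_axis(std::vector<double> &a, int nx, int ny, int nz,
                        int axis, const std::vector<double> &k) {
  int h = ((int)k.size() - 1) / 2;
  std::vector<double> out(a.size());
  int strides[3] = {1, nx, nx * ny};
  int dims[3] = {nx, ny, nz};
  int s = strides[axis], n = dims[axis];
  // iterate over all lines along `axis`
  int o1 = (axis == 0) ? 1 : 0, o2 = (axis == 2) ? 1 : 2;
  for (int j = 0; j < dims[o2]; ++j) {
    for (int i = 0; i < dims[o1]; ++i) {
      int base = i * strides[o1] + j * strides[o2];
      for (int t = 0; t < n; ++t) {
        double acc = 0.0;
        for (int u = -h; u <= h; ++u) {
          int tt = t + u;
          if (tt < 0 || tt >= n) continue; // zero boundary
          acc += k[u + h] * a[base + tt * s];
        }
        out[base + t * s] = acc;
      }
    }
  }
  a.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth3d(NumericVector arr, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  if (sigma > 0) {
    int h = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> k(2 * h + 1);
    double s2 = 2.0 * sigma * sigma, sum = 0.0;
    for (int u = -h; u <= h; ++u) { k[u + h] = std::exp(-u * u / s2); sum += k[u + h]; }
    for (auto &v : k) v /= sum;
    for (int ax = 0; ax < 3; ++ax) smooth_axis(a, nx, ny, nz, ax, k);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ---- isosurface area by marching tetrahedra ----
// Six-tetrahedron decomposition of each cell, all sharing the main diagonal
// (corner 0 to corner 6); vertices interpolated linearly on cell edges.

static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};
static const int CORN[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};

typedef std::array<double,3> P3;

static inline P3 interp(const P3 &pa, const P3 &pb, double va, double vb, double iso) {
  double t = (iso - va) / (vb - va);
  return {pa[0] + t * (pb[0] - pa[0]), pa[1] + t * (pb[1] - pa[1]),
          pa[2] + t * (pb[2] - pa[2])};
}

static inline double tri_area(const P3 &a, const P3 &b, const P3 &c) {
  double u0 = b[0]-a[0], u1 = b[1]-a[1], u2 = b[2]-a[2];
  double v0 = c[0]-a[0], v1 = c[1]-a[1], v2 = c[2]-a[2];
  double cx = u1*v2 - u2*v1, cy = u2*v0 - u0*v2, cz = u0*v1 - u1*v0;
  return 0.5 * std::sqrt(cx*cx + cy*cy + cz*cz);
}

// [[Rcpp::export]]
double cpp_mt_surface_area(NumericVector field, IntegerVector dim,
                           NumericVector spacing, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double *f = field.begin();
  double area = 0.0;
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        double vals[8];
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          vals[c] = f[(x + CORN[c][0]) + nx * ((y + CORN[c][1]) + (size_t)ny * (z + CORN[c][2]))];
          if (vals[c] > iso) ++nin;
        }
        if (nin == 0 || nin == 8) continue;
        P3 pts[8];
        for (int c = 0; c < 8; ++c)
          pts[c] = { (x + CORN[c][0]) * sx, (y + CORN[c][1]) * sy, (z + CORN[c][2]) * sz };
        for (int t = 0; t < 6; ++t) {
          double v[4]; P3 p[4];
          for (int c = 0; c < 4; ++c) { v[c] = vals[TETS[t][c]]; p[c] = pts[TETS[t][c]]; }
          int ins[4], outs[4], ki = 0, ko = 0;
          for (int c = 0; c < 4; ++c) { if (v[c] > iso) ins[ki++] = c; else outs[ko++] = c; }
          if (ki == 0 || ki == 4) continue;
          if (ki == 1 || ki == 3) {
            int a = (ki == 1) ? ins[0] : outs[0];
            P3 tri[3]; int m = 0;
            for (int c = 0; c < 4; ++c) {
              if (c == a) continue;
              tri[m++] = interp(p[a], p[c], v[a], v[c], iso);
            }
            area += tri_area(tri[0], tri[1], tri[2]);
          } else {
            int a = ins[0], b = ins[1], c0 = outs[0], d0 = outs[1];
            P3 q0 = interp(p[a], p[c0], v[a], v[c0], iso);
            P3 q1 = interp(p[a], p[d0], v[a], v[d0], iso);
            P3 q2 = interp(p[b], p[d0], v[b], v[d0], iso);
            P3 q3 = interp(p[b], p[c0], v[b], v[c0], iso);
            area += tri_area(q0, q1, q2) + tri_area(q0, q2, q3);
          }
        }
      }
  return area;
}

// ---- incremental 3D convex hull volume (voxel-center point clouds) ----

struct Face { int a, b, c; double nx, ny, nz, off; bool alive; };

static inline void face_plane(Face &F, const std::vector<P3> &P,
                              const P3 &interior) {
  const P3 &A = P[F.a], &B = P[F.b], &C = P[F.c];
  double u0 = B[0]-A[0], u1 = B[1]-A[1], u2 = B[2]-A[2];
  double v0 = C[0]-A[0], v1 = C[1]-A[1], v2 = C[2]-A[2];
  F.nx = u1*v2 - u2*v1; F.ny = u2*v0 - u0*v2; F.nz = u0*v1 - u1*v0;
  double d = F.nx*(interior[0]-A[0]) + F.ny*(interior[1]-A[1]) + F.nz*(interior[2]-A[2]);
  if (d > 0) { std::swap(F.b, F.c); F.nx = -F.nx; F.ny = -F.ny; F.nz = -F.nz; }
  F.off = F.nx*A[0] + F.ny*A[1] + F.nz*A[2];
  F.alive = true;
}

static double hull_build(NumericMatrix pts, std::vector<Face> &faces,
                         std::vector<P3> &P, P3 &interior) {
  int n = pts.nrow();
  if (n < 4) return -1.0;
  P.resize(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    P[i] = { pts(i,0), pts(i,1), pts(i,2) };
    for (int k = 0; k < 3; ++k) { lo[k] = std::min(lo[k], P[i][k]); hi[k] = std::max(hi[k], P[i][k]); }
  }
  double scale = std::max({hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2], 1e-12});
  double eps = 1e-9 * scale * scale; // plane offsets carry squared length units

  // initial tetrahedron: two extreme points, then farthest from line, then from plane
  int i0 = 0, i1 = 0;
  for (int i = 0; i < n; ++i) {
    if (P[i][0] < P[i0][0]) i0 = i;
    if (P[i][0] > P[i1][0]) i1 = i;
  }
  if (i0 == i1) { for (int i = 0; i < n; ++i) if (P[i][1] != P[i0][1] || P[i][2] != P[i0][2] || P[i][0] != P[i0][0]) { i1 = i; break; } }
  if (i0 == i1) return -1.0;
  P3 A = P[i0], B = P[i1];
  double ab[3] = {B[0]-A[0], B[1]-A[1], B[2]-A[2]};
  double abn = ab[0]*ab[0]+ab[1]*ab[1]+ab[2]*ab[2];
  int i2 = -1; double best = 1e-18 * scale * scale;
  for (int i = 0; i < n; ++i) {
    double w[3] = {P[i][0]-A[0], P[i][1]-A[1], P[i][2]-A[2]};
    double cx = ab[1]*w[2]-ab[2]*w[1], cy = ab[2]*w[0]-ab[0]*w[2], cz = ab[0]*w[1]-ab[1]*w[0];
    double d2 = (cx*cx+cy*cy+cz*cz) / abn;
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (i2 < 0) return -1.0;
  P3 C = P[i2];
  double u0 = C[0]-A[0], u1 = C[1]-A[1], u2 = C[2]-A[2];
  double nx0 = ab[1]*u2-ab[2]*u1, ny0 = ab[2]*u0-ab[0]*u2, nz0 = ab[0]*u1-ab[1]*u0;
  double nn = std::sqrt(nx0*nx0+ny0*ny0+nz0*nz0);
  int i3 = -1; best = 1e-9 * scale;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(nx0*(P[i][0]-A[0]) + ny0*(P[i][1]-A[1]) + nz0*(P[i][2]-A[2])) / nn;
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) return -1.0;

  interior = { (A[0]+B[0]+C[0]+P[i3][0])/4.0, (A[1]+B[1]+C[1]+P[i3][1])/4.0,
               (A[2]+B[2]+C[2]+P[i3][2])/4.0 };
  faces.clear();
  int init[4] = {i0, i1, i2, i3};
  int ftri[4][3] = {{0,1,2},{0,1,3},{0,2,3},{1,2,3}};
  for (int t = 0; t < 4; ++t) {
    Face F; F.a = init[ftri[t][0]]; F.b = init[ftri[t][1]]; F.c = init[ftri[t][2]];
    face_plane(F, P, interior);
    faces.push_back(F);
  }

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    const P3 &q = P[i];
    std::vector<int> vis;
    for (size_t fi = 0; fi < faces.size(); ++fi) {
      Face &F = faces[fi];
      if (!F.alive) continue;
      if (F.nx*q[0] + F.ny*q[1] + F.nz*q[2] - F.off > eps) vis.push_back((int)fi);
    }
    if (vis.empty()) continue;
    // horizon = edges of visible faces appearing exactly once
    std::vector<std::pair<int,int> > edges;
    for (int fi : vis) {
      Face &F = faces[fi];
      int e[3][2] = {{F.a,F.b},{F.b,F.c},{F.c,F.a}};
      for (int k = 0; k < 3; ++k) {
        int x = e[k][0], y = e[k][1];
        bool matched = false;
        for (size_t m = 0; m < edges.size(); ++m) {
          if (edges[m].first == y && edges[m].second == x) {
            edges.erase(edges.begin() + m); matched = true; break;
          }
        }
        if (!matched) edges.push_back(std::make_pair(x, y));
      }
      F.alive = false;
    }
    for (auto &e : edges) {
      Face F; F.a = e.first; F.b = e.second; F.c = i;
      face_plane(F, P, interior);
      faces.push_back(F);
    }
  }

  return 0.0;
}

// Returns hull volume, or -1 if the points are degenerate (rank < 3).
// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix pts) {
  std::vector<Face> faces;
  std::vector<P3> P;
  P3 interior;
  if (hull_build(pts, faces, P, interior) < 0) return -1.0;
  double vol = 0.0;
  for (const Face &F : faces) {
    if (!F.alive) continue;
    const P3 &a = P[F.a], &b = P[F.b], &c = P[F.c];
    double u[3] = {a[0]-interior[0], a[1]-interior[1], a[2]-interior[2]};
    double v[3] = {b[0]-interior[0], b[1]-interior[1], b[2]-interior[2]};
    double w[3] = {c[0]-interior[0], c[1]-interior[1], c[2]-interior[2]};
    vol += u[0]*(v[1]*w[2]-v[2]*w[1]) - u[1]*(v[0]*w[2]-v[2]*w[0]) + u[2]*(v[0]*w[1]-v[1]*w[0]);
  }
  return std::fabs(vol) / 6.0;
}

// 1-based indices of the hull vertices (empty when degenerate).
// [[Rcpp::export]]
IntegerVector cpp_hull_vertices(NumericMatrix pts) {
  std::vector<Face> faces;
  std::vector<P3> P;
  P3 interior;
  if (hull_build(pts, faces, P, interior) < 0) return IntegerVector(0);
  std::vector<bool> used(pts.nrow(), false);
  for (const Face &F : faces)
    if (F.alive) { used[F.a] = used[F.b] = used[F.c] = true; }
  std::vector<int> out;
  for (int i = 0; i < pts.nrow(); ++i) if (used[i]) out.push_back(i + 1);
  return wrap(out);
}

// ---- binary morphology, 6-connected structuring element ----
// op > 0: dilation, op < 0: erosion; |op| iterations
// [[Rcpp::export]]
IntegerVector cpp_morph3d(IntegerVector arr, IntegerVector dim, int op) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> a(arr.begin(), arr.end()), b(a.size());
  bool dil = op > 0;
  for (int it = 0; it < std::abs(op); ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          size_t k = x + (size_t)nx * (y + (size_t)ny * z);
          int v = a[k];
          if (dil) {
            if (!v) {
              v = (x > 0 && a[k-1]) || (x+1 < nx && a[k+1]) ||
                  (y > 0 && a[k-nx]) || (y+1 < ny && a[k+nx]) ||
                  (z > 0 && a[k-(size_t)nx*ny]) || (z+1 < nz && a[k+(size_t)nx*ny]);
            }
          } else {
            if (v) {
              v = (x > 0 ? a[k-1] : 0) && (x+1 < nx ? a[k+1] : 0) &&
                  (y > 0 ? a[k-nx] : 0) && (y+1 < ny ? a[k+nx] : 0) &&
                  (z > 0 ? a[k-(size_t)nx*ny] : 0) && (z+1 < nz ? a[k+(size_t)nx*ny] : 0);
            }
          }
          b[k] = v;
        }
    a.swap(b);
  }
  IntegerVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ---- GLCM pair accumulation ----
// levels: integer matrix, grey level in [0, nlevels) inside the mask, -1 outside.
// Counts ordered pairs (levels[r,c], levels[r+dr, c+dc]) with both pixels in
// the mask; returns nonzero cells as (i, j, count) with 0-based levels.

// Per-offset Haralick features of one masked slice: for each (dr, dc)
// offset row, accumulates the symmetric normalized co-occurrence
// distribution and evaluates contrast, dissimilarity, homogeneity, ASM,
// energy and correlation (zero-variance convention: correlation = 1).
// Returns n_offsets x 7 (six features + valid ordered-pair count).
// [[Rcpp::export]]
NumericMatrix cpp_haralick_slice(IntegerMatrix levels, IntegerMatrix offsets,
                                 int nlevels) {
  int nr = levels.nrow(), nc = levels.ncol(), no = offsets.nrow();
  NumericMatrix out(no, 7);
  std::vector<double> counts((size_t)nlevels * nlevels, 0.0);
  std::vector<size_t> touched;
  std::vector<double> rowp(nlevels, 0.0);
  std::vector<int> rowTouched;
  for (int o = 0; o < no; ++o) {
    int dr = offsets(o, 0), dc = offsets(o, 1);
    touched.clear();
    long npairs = 0;
    for (int c = 0; c < nc; ++c) {
      int c2 = c + dc;
      if (c2 < 0 || c2 >= nc) continue;
      for (int r = 0; r < nr; ++r) {
        int r2 = r + dr;
        if (r2 < 0 || r2 >= nr) continue;
        int a = levels(r, c), b = levels(r2, c2);
        if (a < 0 || b < 0) continue;
        size_t k1 = (size_t)a + (size_t)nlevels * b;
        size_t k2 = (size_t)b + (size_t)nlevels * a;
        if (counts[k1] == 0.0) touched.push_back(k1);
        counts[k1] += 1.0;
        if (counts[k2] == 0.0) touched.push_back(k2);
        counts[k2] += 1.0;  // transpose; doubles the diagonal as intended
        ++npairs;
      }
    }
    out(o, 6) = (double)npairs;
    if (npairs == 0) {
      for (int f = 0; f < 6; ++f) out(o, f) = NA_REAL;
      continue;
    }
    double tot = 2.0 * npairs;
    rowTouched.clear();
    for (size_t t = 0; t < touched.size(); ++t) {
      int i = (int)(touched[t] % nlevels);
      double p = counts[touched[t]] / tot;
      if (rowp[i] == 0.0) rowTouched.push_back(i);
      rowp[i] += p;
    }
    double mu = 0.0;
    for (int i : rowTouched) mu += i * rowp[i];
    double var = 0.0;
    for (int i : rowTouched) var += (i - mu) * (i - mu) * rowp[i];
    double sig = std::sqrt(var);
    double contrast = 0, dissim = 0, homog = 0, asm_ = 0, corr = 0;
    for (size_t t = 0; t < touched.size(); ++t) {
      int i = (int)(touched[t] % nlevels);
      int j = (int)(touched[t] / nlevels);
      double p = counts[touched[t]] / tot;
      double d = (double)(i - j), ad = std::fabs(d);
      contrast += d * d * p;
      dissim += ad * p;
      homog += p / (1.0 + ad);
      asm_ += p * p;
      corr += (i - mu) * (j - mu) * p;
      counts[touched[t]] = 0.0;  // reset for the next offset
    }
    for (int i : rowTouched) rowp[i] = 0.0;
    out(o, 0) = contrast; out(o, 1) = dissim; out(o, 2) = homog;
    out(o, 3) = asm_; out(o, 4) = std::sqrt(asm_);
    out(o, 5) = (sig * sig < 1e-12) ? 1.0 : corr / (sig * sig);
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_glcm_pairs(IntegerMatrix levels, int dr, int dc, int nlevels) {
  int nr = levels.nrow(), nc = levels.ncol();
  std::vector<int> counts((size_t)nlevels * nlevels, 0);
  std::vector<size_t> touched;
  touched.reserve(256);
  for (int c = 0; c < nc; ++c) {
    int c2 = c + dc;
    if (c2 < 0 || c2 >= nc) continue;
    for (int r = 0; r < nr; ++r) {
      int r2 = r + dr;
      if (r2 < 0 || r2 >= nr) continue;
      int a = levels(r, c), b = levels(r2, c2);
      if (a < 0 || b < 0) continue;
      size_t k = (size_t)a + (size_t)nlevels * b;
      if (counts[k] == 0) touched.push_back(k);
      counts[k] += 1;
    }
  }
  std::sort(touched.begin(), touched.end());
  IntegerMatrix out((int)touched.size(), 3);
  for (size_t m = 0; m < touched.size(); ++m) {
    out(m, 0) = (int)(touched[m] % nlevels);
    out(m, 1) = (int)(touched[m] / nlevels);
    out(m, 2) = counts[touched[m]];
  }
  return out;
}
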