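#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel-grid primitives used by the mask geometry layer. Arrays are column-major
// (R order) with dimensions dim[0] x dim[1] x dim[2]. All voxel coordinates
// exchanged with these routines are ZERO-based continuous indices.

inline R_xlen_t idx3(int i, int j, int k, const int* d) {
  return (R_xlen_t)i + (R_xlen_t)d[0] * ((R_xlen_t)j + (R_xlen_t)d[1] * (R_xlen_t)k);
}

// Separable Gaussian smoothing, kernel truncated at 3 sigma, zero-padded
// borders (background outside the volume).
// [[Rcpp::export(name = ".gauss_smooth3d")]]
NumericVector gauss_smooth3d(NumericVector arr, IntegerVector dim, double sigma) {
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  if (sigma <= 0) return clone(arr);
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    kern[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + radius];
  }
  for (double& k : kern) k /= s;

  std::vector<double> a(arr.begin(), arr.end()), b(n);
  int strides[3] = {1, d[0], d[0] * d[1]};
  for (int axis = 0; axis < 3; ++axis) {
    int len = d[axis], str = strides[axis];
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          int pos[3] = {i, j, k};
          R_xlen_t base = idx3(i, j, k, d);
          double acc = 0.0;
          int c = pos[axis];
          int lo = std::max(0, c - radius), hi = std::min(len - 1, c + radius);
          for (int q = lo; q <= hi; ++q)
            acc += kern[q - c + radius] * a[base + (R_xlen_t)(q - c) * str];
          b[base] = acc;
        }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// Trilinear sampling at zero-based continuous voxel coordinates; outside -> 0.
// [[Rcpp::export(name = ".trilinear_sample")]]
NumericVector trilinear_sample(NumericVector arr, IntegerVector dim, NumericMatrix pts) {
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t m = pts.nrow();
  NumericVector out(m);
  for (R_xlen_t p = 0; p < m; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0 || y < 0 || z < 0 || x > d[0] - 1 || y > d[1] - 1 || z > d[2] - 1) {
      out[p] = 0.0;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == d[0] - 1) --i0;
    if (j0 == d[1] - 1) --j0;
    if (k0 == d[2] - 1) --k0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double v = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          v += w * arr[idx3(i0 + di, j0 + dj, k0 + dk, d)];
        }
    out[p] = v;
  }
  return out;
}

// Nearest-neighbour sampling; outside -> 0. Used for binary mask resampling.
// [[Rcpp::export(name = ".nearest_sample")]]
NumericVector nearest_sample(NumericVector arr, IntegerVector dim, NumericMatrix pts) {
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t m = pts.nrow();
  NumericVector out(m);
  for (R_xlen_t p = 0; p < m; ++p) {
    int i = (int)std::lround(pts(p, 0));
    int j = (int)std::lround(pts(p, 1));
    int k = (int)std::lround(pts(p, 2));
    out[p] = (i < 0 || j < 0 || k < 0 || i >= d[0] || j >= d[1] || k >= d[2])
                 ? 0.0
                 : arr[idx3(i, j, k, d)];
  }
  return out;
}

namespace {
// Edge vertex by linear interpolation between two tetrahedron corners.
inline void edge_point(const double* p0, const double* p1, double v0, double v1,
                       double iso, double* out) {
  double t = (v1 != v0) ? (iso - v0) / (v1 - v0) : 0.5;
  for (int c = 0; c < 3; ++c) out[c] = p0[c] + t * (p1[c] - p0[c]);
}

void tet_triangles(const double pts[4][3], const double val[4], double iso,
                   std::vector<double>& tri) {
  int inside = 0, in_idx[4], out_idx[4], ni = 0, no = 0;
  for (int v = 0; v < 4; ++v) {
    if (val[v] >= iso) { in_idx[ni++] = v; ++inside; }
    else out_idx[no++] = v;
  }
  if (inside == 0 || inside == 4) return;
  double e[4][3];
  if (inside == 1 || inside == 3) {
    // one triangle between the lone vertex and the opposite face
    int lone = (inside == 1) ? in_idx[0] : out_idx[0];
    int oth[3], t = 0;
    for (int v = 0; v < 4; ++v)
      if (v != lone) oth[t++] = v;
    for (int q = 0; q < 3; ++q)
      edge_point(pts[lone], pts[oth[q]], val[lone], val[oth[q]], iso, e[q]);
    for (int q = 0; q < 3; ++q)
      for (int c = 0; c < 3; ++c) tri.push_back(e[q][c]);
  } else {
    // two-in/two-out: quad split into two triangles
    int a = in_idx[0], b = in_idx[1], c0 = out_idx[0], d0 = out_idx[1];
    edge_point(pts[a], pts[c0], val[a], val[c0], iso, e[0]);
    edge_point(pts[a], pts[d0], val[a], val[d0], iso, e[1]);
    edge_point(pts[b], pts[d0], val[b], val[d0], iso, e[2]);
    edge_point(pts[b], pts[c0], val[b], val[c0], iso, e[3]);
    int quads[2][3] = {{0, 1, 2}, {0, 2, 3}};
    for (int q = 0; q < 2; ++q)
      for (int v = 0; v < 3; ++v)
        for (int c = 0; c < 3; ++c) tri.push_back(e[quads[q][v]][c]);
  }
}
}  // namespace

// Marching tetrahedra over the scalar field: each cell is split into six
// tetrahedra sharing the main diagonal. Returns an (ntri x 9) matrix of
// triangle vertices (x1,y1,z1,x2,...) in zero-based voxel coordinates.
// [[Rcpp::export(name = ".march_tets")]]
NumericMatrix march_tets(NumericVector field, IntegerVector dim, double iso) {
  int d[3] = {dim[0], dim[1], dim[2]};
  static const int corner[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                   {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  static const int tets[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                                 {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  std::vector<double> tri;
  tri.reserve(1 << 16);
  for (int k = 0; k + 1 < d[2]; ++k)
    for (int j = 0; j + 1 < d[1]; ++j)
      for (int i = 0; i + 1 < d[0]; ++i) {
        double cv[8];
        bool any_in = false, any_out = false;
        for (int v = 0; v < 8; ++v) {
          cv[v] = field[idx3(i + corner[v][0], j + corner[v][1], k + corner[v][2], d)];
          (cv[v] >= iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          double pts[4][3], val[4];
          for (int v = 0; v < 4; ++v) {
            int cn = tets[t][v];
            pts[v][0] = i + corner[cn][0];
            pts[v][1] = j + corner[cn][1];
            pts[v][2] = k + corner[cn][2];
            val[v] = cv[cn];
          }
          tet_triangles(pts, val, iso, tri);
        }
      }
  R_xlen_t ntri = (R_xlen_t)tri.size() / 9;
  NumericMatrix out(ntri, 9);
  for (R_xlen_t r = 0; r < ntri; ++r)
    for (int c = 0; c < 9; ++c) out(r, c) = tri[r * 9 + c];
  return out;
}
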