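#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform, Felzenszwalb & Huttenlocher lower
// envelope of parabolas. f is the squared distance sampled along one line,
// step is the physical sample spacing.
// ---------------------------------------------------------------------------
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double step) {
  const int n = (int)f.size();
  d.assign(n, 0.0);
  if (n == 1) { d[0] = f[0]; return; }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * step, s;
    for (;;) {
      double vv = (double)v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * step;
    while (z[k + 1] < qq) ++k;
    double vv = (double)v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// squared distance to the nearest "true" voxel centre, 2D
static std::vector<double> edt2d_sq(const LogicalMatrix& mask,
                                    double dx, double dy) {
  const int nx = mask.nrow(), ny = mask.ncol();
  const double INF = 1e20;
  std::vector<double> g(nx * ny);
  std::vector<double> f, d;
  // columns: along x (rows of the matrix)
  f.resize(nx); d.resize(nx);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) f[i] = mask(i, j) ? 0.0 : INF;
    dt1d(f, d, dx);
    for (int i = 0; i < nx; ++i) g[i + (size_t)j * nx] = d[i];
  }
  // rows: along y
  f.resize(ny); d.resize(ny);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) f[j] = g[i + (size_t)j * nx];
    dt1d(f, d, dy);
    for (int j = 0; j < ny; ++j) g[i + (size_t)j * nx] = d[j];
  }
  return g;
}

// [[Rcpp::export(name = ".cpp_sedt2d")]]
NumericMatrix cpp_sedt2d(LogicalMatrix mask, double dx, double dy,
                         double cap) {
  // Signed in-plane distance (mm), positive inside the mask.  Values are
  // clamped to +/- cap so empty slices interpolate sanely across the stack.
  const int nx = mask.nrow(), ny = mask.ncol();
  LogicalMatrix inv(nx, ny);
  bool any_in = false, any_out = false;
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    inv(i, j) = !mask(i, j);
    if (mask(i, j)) any_in = true; else any_out = true;
  }
  NumericMatrix out(nx, ny);
  if (!any_in) { std::fill(out.begin(), out.end(), -cap); return out; }
  if (!any_out) { std::fill(out.begin(), out.end(),  cap); return out; }
  std::vector<double> dout = edt2d_sq(mask, dx, dy); // dist to inside
  std::vector<double> din  = edt2d_sq(inv,  dx, dy); // dist to outside
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    size_t k = i + (size_t)j * nx;
    double v = mask(i, j) ? std::sqrt(din[k]) : -std::sqrt(dout[k]);
    if (v >  cap) v =  cap;
    if (v < -cap) v = -cap;
    out(i, j) = v;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_sedt3d")]]
NumericVector cpp_sedt3d(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing, double cap) {
  // Full 3D signed distance for isotropic-ish grids (used on finely
  // rasterised phantoms, not on gapped acquisitions).
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  const double INF = 1e20;
  std::vector<double> g(n), h(n);
  bool any_in = false, any_out = false;
  for (size_t k = 0; k < n; ++k) { if (mask[k]) any_in = true; else any_out = true; }
  NumericVector out(n);
  out.attr("dim") = dim;
  if (!any_in) { std::fill(out.begin(), out.end(), -cap); return out; }
  if (!any_out) { std::fill(out.begin(), out.end(),  cap); return out; }
  std::vector<double> f, d;
  for (int pass = 0; pass < 2; ++pass) {
    // pass 0: distance to inside; pass 1: distance to outside
    for (size_t k = 0; k < n; ++k)
      g[k] = ((mask[k] != 0) == (pass == 0)) ? 0.0 : INF;
    f.resize(nx); d.resize(nx);
    for (int z = 0; z < nz; ++z) for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)z * nx * ny + (size_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, spacing[0]);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
    f.resize(ny); d.resize(ny);
    for (int z = 0; z < nz; ++z) for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)z * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (size_t)j * nx];
      dt1d(f, d, spacing[1]);
      for (int j = 0; j < ny; ++j) g[base + (size_t)j * nx] = d[j];
    }
    f.resize(nz); d.resize(nz);
    for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)j * nx + i;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (size_t)z * nx * ny];
      dt1d(f, d, spacing[2]);
      for (int z = 0; z < nz; ++z) g[base + (size_t)z * nx * ny] = d[z];
    }
    if (pass == 0) h = g; // h: squared distance to inside
  }
  for (size_t k = 0; k < n; ++k) {
    double v = mask[k] ? std::sqrt(g[k]) : -std::sqrt(h[k]);
    if (v >  cap) v =  cap;
    if (v < -cap) v = -cap;
    out[k] = v;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_blur3d")]]
NumericVector cpp_blur3d(NumericVector field, IntegerVector dim,
                         NumericVector sigma_vox) {
  // separable Gaussian blur (replicated edges); sigma per axis in voxels.
  // Used to suppress the half-voxel staircase of mask distance fields
  // before iso-surfacing.
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(field.begin(), field.end()), b(n);
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  const int len[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      ksum += k[i + r];
    }
    for (auto& v : k) v /= ksum;
    const size_t st = stride[ax];
    const int L = len[ax];
    // iterate over all lines along axis ax
    for (int z = 0; z < (ax == 2 ? 1 : nz); ++z)
    for (int y = 0; y < (ax == 1 ? 1 : ny); ++y)
    for (int x = 0; x < (ax == 0 ? 1 : nx); ++x) {
      size_t base = (size_t)x + (size_t)y * nx + (size_t)z * nx * ny;
      for (int p = 0; p < L; ++p) {
        double acc = 0;
        for (int i = -r; i <= r; ++i) {
          int q = p + i;
          if (q < 0) q = 0;
          if (q >= L) q = L - 1;
          acc += k[i + r] * a[base + (size_t)q * st];
        }
        b[base + (size_t)p * st] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a rectilinear scalar field. Each cell is split into
// 6 tetrahedra sharing the (0,0,0)-(1,1,1) diagonal; the iso-surface
// {field = level} is triangulated with vertices linearly interpolated along
// tet edges. Triangles are oriented with outward normals (away from the
// field > level side), so signed mesh volume is usable directly.
// ---------------------------------------------------------------------------
static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};

// [[Rcpp::export(name = ".cpp_march_tets")]]
NumericMatrix cpp_march_tets(NumericVector field, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  // cube corner offsets, Bourke ordering
  const int CX[8] = {0,1,1,0,0,1,1,0};
  const int CY[8] = {0,0,1,1,0,0,1,1};
  const int CZ[8] = {0,0,0,0,1,1,1,1};
  std::vector<double> verts; verts.reserve(1 << 16);
  double P[8][3], V[8];
  for (int z = 0; z + 1 < nz; ++z)
  for (int y = 0; y + 1 < ny; ++y)
  for (int x = 0; x + 1 < nx; ++x) {
    size_t base = x * sx + (size_t)y * sy + (size_t)z * sz;
    bool anyp = false, anym = false;
    for (int c = 0; c < 8; ++c) {
      size_t idx = base + CX[c] * sx + (size_t)CY[c] * sy + (size_t)CZ[c] * sz;
      V[c] = field[idx] - level;
      if (V[c] > 0) anyp = true; else anym = true;
      P[c][0] = origin[0] + (x + CX[c]) * spacing[0];
      P[c][1] = origin[1] + (y + CY[c]) * spacing[1];
      P[c][2] = origin[2] + (z + CZ[c]) * spacing[2];
    }
    if (!anyp || !anym) continue;
    for (int t = 0; t < 6; ++t) {
      const int* T = TETS[t];
      int inside[4], nin = 0;
      for (int c = 0; c < 4; ++c) if (V[T[c]] > 0) inside[nin++] = c;
      if (nin == 0 || nin == 4) continue;
      // interpolate along an edge of the tet
      auto ip = [&](int a, int b, double* out) {
        int ia = T[a], ib = T[b];
        double t0 = V[ia] / (V[ia] - V[ib]);
        for (int k = 0; k < 3; ++k)
          out[k] = P[ia][k] + t0 * (P[ib][k] - P[ia][k]);
      };
      auto push = [&](double* a, double* b, double* c, int insideCorner) {
        // orient: normal should point away from the inside corner
        double u[3], w[3], nrm[3], ctr[3], dir[3];
        for (int k = 0; k < 3; ++k) {
          u[k] = b[k] - a[k]; w[k] = c[k] - a[k];
          ctr[k] = (a[k] + b[k] + c[k]) / 3.0;
          dir[k] = ctr[k] - P[T[insideCorner]][k];
        }
        nrm[0] = u[1] * w[2] - u[2] * w[1];
        nrm[1] = u[2] * w[0] - u[0] * w[2];
        nrm[2] = u[0] * w[1] - u[1] * w[0];
        double dp = nrm[0] * dir[0] + nrm[1] * dir[1] + nrm[2] * dir[2];
        if (dp >= 0) {
          for (int k = 0; k < 3; ++k) verts.push_back(a[k]);
          for (int k = 0; k < 3; ++k) verts.push_back(b[k]);
          for (int k = 0; k < 3; ++k) verts.push_back(c[k]);
        } else {
          for (int k = 0; k < 3; ++k) verts.push_back(a[k]);
          for (int k = 0; k < 3; ++k) verts.push_back(c[k]);
          for (int k = 0; k < 3; ++k) verts.push_back(b[k]);
        }
      };
      double e0[3], e1[3], e2[3], e3[3];
      if (nin == 1 || nin == 3) {
        // single triangle separating one corner from the other three
        int lone = -1;
        if (nin == 1) lone = inside[0];
        else { for (int c = 0; c < 4; ++c) { bool in = false;
                 for (int k = 0; k < 3; ++k) if (inside[k] == c) in = true;
                 if (!in) { lone = c; break; } } }
        int others[3], m = 0;
        for (int c = 0; c < 4; ++c) if (c != lone) others[m++] = c;
        ip(lone, others[0], e0); ip(lone, others[1], e1); ip(lone, others[2], e2);
        push(e0, e1, e2, nin == 1 ? lone : inside[0]);
      } else {
        // two inside, two outside: quad -> two triangles
        int in0 = inside[0], in1 = inside[1];
        int out01[2], m = 0;
        for (int c = 0; c < 4; ++c)
          if (c != in0 && c != in1) out01[m++] = c;
        ip(in0, out01[0], e0); ip(in0, out01[1], e1);
        ip(in1, out01[1], e2); ip(in1, out01[0], e3);
        push(e0, e1, e2, in0);
        push(e0, e2, e3, in0);
      }
    }
  }
  const int ntri = (int)(verts.size() / 9);
  NumericMatrix out(ntri, 9);
  for (int i = 0; i < ntri; ++i)
    for (int k = 0; k < 9; ++k) out(i, k) = verts[(size_t)i * 9 + k];
  return out;
}
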