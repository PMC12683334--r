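#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Volumes are R arrays with dim c(nx, ny, nz), column-major:
// linear index = i + nx*(j + ny*k), 0-based here.

static inline int wrap_index(int i, int n, int mode) {
  // mode: 0 replicate, 1 wrap, 2 reflect (whole-sample)
  if (i >= 0 && i < n) return i;
  if (mode == 0) return i < 0 ? 0 : n - 1;
  if (mode == 1) { i %= n; return i < 0 ? i + n : i; }
  // reflect: ... 2 1 0 | 0' handled as mirror about edge samples
  if (n == 1) return 0;
  int p = 2 * (n - 1);
  i %= p; if (i < 0) i += p;
  return i < n ? i : p - i;
}

// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis, int mode) {
  // axis: 0 = x, 1 = y, 2 = z; kernel centred at (length-1)/2
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size(), kc = (kl - 1) / 2;
  NumericVector out(vol.size());
  const double *v = vol.begin(); double *o = out.begin();
  const double *kp = kernel.begin();
  const int n_axis = (axis == 0) ? nx : (axis == 1 ? ny : nz);
  const long stride = (axis == 0) ? 1L : (axis == 1 ? (long)nx : (long)nx * ny);
  // iterate over all lines along `axis`
  const int nu = (axis == 0) ? ny : nx;
  const int nv = (axis == 0) ? nz : (axis == 1 ? nz : ny);
  for (int b = 0; b < nv; ++b) {
    for (int a = 0; a < nu; ++a) {
      long base;
      if (axis == 0)      base = (long)nx * (a + (long)ny * b);
      else if (axis == 1) base = a + (long)nx * ny * b;
      else                base = a + (long)nx * b;
      for (int t = 0; t < n_axis; ++t) {
        double acc = 0.0;
        for (int q = 0; q < kl; ++q) {
          int s = wrap_index(t + q - kc, n_axis, mode);
          acc += kp[q] * v[base + (long)s * stride];
        }
        o[base + (long)t * stride] = acc;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Recursive Gaussian smoothing along one axis (Young & van Vliet),
// replicate boundary initialisation. Accurate to ~1% vs FIR for sigma >~ 2.
// [[Rcpp::export]]
NumericVector yvv_axis_cpp(NumericVector vol, IntegerVector dim,
                           double sigma, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double q;
  if (sigma >= 2.5) q = 0.98711 * sigma - 0.96330;
  else q = 3.97156 - 4.14554 * std::sqrt(1.0 - 0.26891 * sigma);
  const double b0 = 1.57825 + 2.44413 * q + 1.4281 * q * q + 0.422205 * q * q * q;
  const double b1 = 2.44413 * q + 2.85619 * q * q + 1.26661 * q * q * q;
  const double b2 = -(1.4281 * q * q + 1.26661 * q * q * q);
  const double b3 = 0.422205 * q * q * q;
  const double B = 1.0 - (b1 + b2 + b3) / b0;
  NumericVector out = clone(vol);
  double *v = out.begin();
  const int n_axis = (axis == 0) ? nx : (axis == 1 ? ny : nz);
  const long stride = (axis == 0) ? 1L : (axis == 1 ? (long)nx : (long)nx * ny);
  const int nu = (axis == 0) ? ny : nx;
  const int nv = (axis == 0) ? nz : (axis == 1 ? nz : ny);
  std::vector<double> w(n_axis);
  for (int b = 0; b < nv; ++b) {
    for (int a = 0; a < nu; ++a) {
      long base;
      if (axis == 0)      base = (long)nx * (a + (long)ny * b);
      else if (axis == 1) base = a + (long)nx * ny * b;
      else                base = a + (long)nx * b;
      double x0 = v[base];
      double wm1 = x0, wm2 = x0, wm3 = x0;
      for (int t = 0; t < n_axis; ++t) {
        double wt = B * v[base + (long)t * stride] +
          (b1 * wm1 + b2 * wm2 + b3 * wm3) / b0;
        w[t] = wt; wm3 = wm2; wm2 = wm1; wm1 = wt;
      }
      double yl = w[n_axis - 1];
      double yp1 = yl, yp2 = yl, yp3 = yl;
      for (int t = n_axis - 1; t >= 0; --t) {
        double yt = B * w[t] + (b1 * yp1 + b2 * yp2 + b3 * yp3) / b0;
        v[base + (long)t * stride] = yt;
        yp3 = yp2; yp2 = yp1; yp1 = yt;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, double fill) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz;
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        double val;
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          val = fill;
        else
          val = v[xx + (long)nx * (yy + (long)ny * zz)];
        acc += wx * wy * wz * val;
      }
    }
  }
  return acc;
}

// Backward affine sampling: src index = M %*% out index + t (0-based index space)
// [[Rcpp::export]]
NumericVector affine_sample_cpp(NumericVector vol, IntegerVector dim,
                                IntegerVector outdim, NumericMatrix M,
                                NumericVector t, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((long)ox * oy * oz);
  const double *v = vol.begin(); double *o = out.begin();
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2);
  const double t0 = t[0], t1 = t[1], t2 = t[2];
  long idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++idx) {
        double sx = m00 * i + m01 * j + m02 * k + t0;
        double sy = m10 * i + m11 * j + m12 * k + t1;
        double sz = m20 * i + m21 * j + m22 * k + t2;
        o[idx] = trilinear(v, nx, ny, nz, sx, sy, sz, fill);
      }
  out.attr("dim") = outdim;
  return out;
}

// Backward warp: out(p) = vol(p + d(p)); displacements in voxel units
// [[Rcpp::export]]
NumericVector warp_sample_cpp(NumericVector vol, IntegerVector dim,
                              NumericVector dx, NumericVector dy,
                              NumericVector dz, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  const double *v = vol.begin(); double *o = out.begin();
  long idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx)
        o[idx] = trilinear(v, nx, ny, nz,
                           i + dx[idx], j + dy[idx], k + dz[idx], fill);
  out.attr("dim") = dim;
  return out;
}

// The 13 unique 3D directions at Chebyshev distance 1 (positive half-space)
static const int DIR13[13][3] = {
  {0,0,1},{0,1,-1},{0,1,0},{0,1,1},
  {1,-1,-1},{1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},
  {1,1,-1},{1,1,0},{1,1,1}
};

// Symmetric co-occurrence counts: ng x ng x 13
// labels: 0 = outside ROI, 1..ng inside
// [[Rcpp::export]]
NumericVector glcm13_cpp(IntegerVector labels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((long)ng * ng * 13);
  const int *L = labels.begin(); double *o = out.begin();
  long idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int a = L[idx];
        if (a <= 0) continue;
        for (int d = 0; d < 13; ++d) {
          int ii = i + DIR13[d][0], jj = j + DIR13[d][1], kk = k + DIR13[d][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          int b = L[ii + (long)nx * (jj + (long)ny * kk)];
          if (b <= 0) continue;
          long off = (long)ng * ng * d;
          o[off + (a - 1) + (long)ng * (b - 1)] += 1.0;
          o[off + (b - 1) + (long)ng * (a - 1)] += 1.0;
        }
      }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Run-length counts: ng x maxlen x 13
// [[Rcpp::export]]
NumericVector glrlm13_cpp(IntegerVector labels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out((long)ng * maxlen * 13);
  const int *L = labels.begin(); double *o = out.begin();
  for (int d = 0; d < 13; ++d) {
    const int ddx = DIR13[d][0], ddy = DIR13[d][1], ddz = DIR13[d][2];
    long idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          int a = L[idx];
          if (a <= 0) continue;
          // run start: predecessor along -d absent or different
          int pi = i - ddx, pj = j - ddy, pk = k - ddz;
          if (pi >= 0 && pi < nx && pj >= 0 && pj < ny && pk >= 0 && pk < nz &&
              L[pi + (long)nx * (pj + (long)ny * pk)] == a)
            continue;
          int len = 1;
          int ci = i + ddx, cj = j + ddy, ck = k + ddz;
          while (ci >= 0 && ci < nx && cj >= 0 && cj < ny && ck >= 0 && ck < nz &&
                 L[ci + (long)nx * (cj + (long)ny * ck)] == a) {
            ++len; ci += ddx; cj += ddy; ck += ddz;
          }
          o[(long)ng * maxlen * d + (a - 1) + (long)ng * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// 26-connected zones: returns matrix with columns (gray level, zone size)
// [[Rcpp::export]]
IntegerMatrix glszm_cpp(IntegerVector labels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  const int *L = labels.begin();
  std::vector<char> seen(n, 0);
  std::vector<int> gl, sz;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (seen[s] || L[s] <= 0) continue;
    int g = L[s];
    int count = 0;
    stack.clear(); stack.push_back(s); seen[s] = 1;
    while (!stack.empty()) {
      long c = stack.back(); stack.pop_back();
      ++count;
      int ci = (int)(c % nx), cj = (int)((c / nx) % ny), ck = (int)(c / ((long)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int ii = ci + dx, jj = cj + dy, kk = ck + dz;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            long q = ii + (long)nx * (jj + (long)ny * kk);
            if (!seen[q] && L[q] == g) { seen[q] = 1; stack.push_back(q); }
          }
    }
    gl.push_back(g); sz.push_back(count);
  }
  IntegerMatrix out(gl.size(), 2);
  for (size_t r = 0; r < gl.size(); ++r) { out(r, 0) = gl[r]; out(r, 1) = sz[r]; }
  return out;
}

// Dependence counts: ng x 27; dependence j = 1 + #26-neighbours in ROI with
// |level difference| <= alpha (centre voxel counted)
// [[Rcpp::export]]
NumericMatrix gldm_cpp(IntegerVector labels, IntegerVector dim, int ng, double alpha) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27);
  const int *L = labels.begin();
  long idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int a = L[idx];
        if (a <= 0) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int ii = i + dx, jj = j + dy, kk = k + dz;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                continue;
              int b = L[ii + (long)nx * (jj + (long)ny * kk)];
              if (b > 0 && std::abs(a - b) <= alpha) ++dep;
            }
        out(a - 1, dep - 1) += 1.0;
      }
  return out;
}

// Neighbouring gray-tone difference: per level i, columns (n_i, s_i)
// [[Rcpp::export]]
NumericMatrix ngtdm_cpp(IntegerVector labels, IntegerVector dim, int ng) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2);
  const int *L = labels.begin();
  long idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int a = L[idx];
        if (a <= 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int ii = i + dx, jj = j + dy, kk = k + dz;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                continue;
              int b = L[ii + (long)nx * (jj + (long)ny * kk)];
              if (b > 0) { sum += b; ++cnt; }
            }
        if (cnt > 0) {
          out(a - 1, 0) += 1.0;
          out(a - 1, 1) += std::fabs(a - sum / cnt);
        }
      }
  return out;
}

// --- marching tetrahedra on a binary mask ------------------------------

static const int TET6[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
};
// cube corner offsets
static const int CUBE[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};

static inline void cross3(const double a[3], const double b[3], double r[3]) {
  r[0] = a[1]*b[2] - a[2]*b[1];
  r[1] = a[2]*b[0] - a[0]*b[2];
  r[2] = a[0]*b[1] - a[1]*b[0];
}

// Accumulate one outward-oriented triangle's area and signed volume
static inline void add_tri(const double p1[3], const double p2[3],
                           const double p3[3], const double inside[3],
                           double &area, double &vol) {
  double u[3] = {p2[0]-p1[0], p2[1]-p1[1], p2[2]-p1[2]};
  double v[3] = {p3[0]-p1[0], p3[1]-p1[1], p3[2]-p1[2]};
  double nrm[3]; cross3(u, v, nrm);
  double cx = (p1[0]+p2[0]+p3[0])/3.0 - inside[0];
  double cy = (p1[1]+p2[1]+p3[1])/3.0 - inside[1];
  double cz = (p1[2]+p2[2]+p3[2])/3.0 - inside[2];
  bool flip = (nrm[0]*cx + nrm[1]*cy + nrm[2]*cz) < 0.0;
  if (flip) { nrm[0] = -nrm[0]; nrm[1] = -nrm[1]; nrm[2] = -nrm[2]; }
  double a2 = std::sqrt(nrm[0]*nrm[0] + nrm[1]*nrm[1] + nrm[2]*nrm[2]);
  area += 0.5 * a2;
  // signed volume of tet (origin, p1, p2, p3) with outward orientation
  const double *q2 = flip ? p3 : p2;
  const double *q3 = flip ? p2 : p3;
  double c[3]; cross3(q2, q3, c);
  vol += (p1[0]*c[0] + p1[1]*c[1] + p1[2]*c[2]) / 6.0;
}

// Surface area (mm^2) and enclosed mesh volume (mm^3) of the `iso`
// isosurface of a scalar field (marching tetrahedra, linear interpolation
// of crossing points); the field is padded with zeros so the surface closes.
// [[Rcpp::export]]
NumericVector mesh_area_volume_cpp(NumericVector field, IntegerVector dim,
                                   NumericVector spacing, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double *F = field.begin();
  double area = 0.0, vol = 0.0;
  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        double val[8]; int inside[8]; int sum = 0;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CUBE[c][0], jj = j + CUBE[c][1], kk = k + CUBE[c][2];
          double v = 0.0;
          if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
            v = F[ii + (long)nx * (jj + (long)ny * kk)];
          val[c] = v; inside[c] = v > iso ? 1 : 0; sum += inside[c];
        }
        if (sum == 0 || sum == 8) continue;
        double pos[8][3];
        for (int c = 0; c < 8; ++c) {
          pos[c][0] = (i + CUBE[c][0]) * sx;
          pos[c][1] = (j + CUBE[c][1]) * sy;
          pos[c][2] = (k + CUBE[c][2]) * sz;
        }
        for (int tnum = 0; tnum < 6; ++tnum) {
          const int *T = TET6[tnum];
          int tv[4] = {inside[T[0]], inside[T[1]], inside[T[2]], inside[T[3]]};
          int tc = tv[0] + tv[1] + tv[2] + tv[3];
          if (tc == 0 || tc == 4) continue;
          // interpolated crossing points on edges between differing vertices
          double mid[4][4][3];
          for (int a = 0; a < 4; ++a)
            for (int b = a + 1; b < 4; ++b)
              if (tv[a] != tv[b]) {
                double va = val[T[a]], vb = val[T[b]];
                double t = (iso - va) / (vb - va);
                if (t < 0.0) t = 0.0; if (t > 1.0) t = 1.0;
                for (int c = 0; c < 3; ++c)
                  mid[a][b][c] = mid[b][a][c] =
                    pos[T[a]][c] + t * (pos[T[b]][c] - pos[T[a]][c]);
              }
          if (tc == 1 || tc == 3) {
            int apex = -1;
            for (int a = 0; a < 4; ++a)
              if ((tc == 1 && tv[a] == 1) || (tc == 3 && tv[a] == 0)) apex = a;
            int others[3], m = 0;
            for (int a = 0; a < 4; ++a) if (a != apex) others[m++] = a;
            double inside_pt[3];
            if (tc == 1) {
              for (int c = 0; c < 3; ++c) inside_pt[c] = pos[T[apex]][c];
            } else {
              for (int c = 0; c < 3; ++c)
                inside_pt[c] = (pos[T[others[0]]][c] + pos[T[others[1]]][c] +
                                pos[T[others[2]]][c]) / 3.0;
            }
            add_tri(mid[apex][others[0]], mid[apex][others[1]],
                    mid[apex][others[2]], inside_pt, area, vol);
          } else { // tc == 2: quad split into two triangles
            int pa = -1, pb = -1, na = -1, nb = -1;
            for (int a = 0; a < 4; ++a) {
              if (tv[a] == 1) { if (pa < 0) pa = a; else pb = a; }
              else            { if (na < 0) na = a; else nb = a; }
            }
            double inside_pt[3];
            for (int c = 0; c < 3; ++c)
              inside_pt[c] = 0.5 * (pos[T[pa]][c] + pos[T[pb]][c]);
            add_tri(mid[pa][na], mid[pa][nb], mid[pb][nb], inside_pt,
                    area, vol);
            add_tri(mid[pa][na], mid[pb][nb], mid[pb][na], inside_pt,
                    area, vol);
          }
        }
      }
  return NumericVector::create(area, std::fabs(vol));
}

// ROI voxels with at least one 6-neighbour outside the ROI (or the grid)
// [[Rcpp::export]]
IntegerMatrix boundary_voxels_cpp(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *Mk = mask.begin();
  std::vector<int> xs, ys, zs;
  long idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        if (Mk[idx] <= 0) continue;
        bool bd = false;
        const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
        for (int d = 0; d < 6 && !bd; ++d) {
          int ii = i + off[d][0], jj = j + off[d][1], kk = k + off[d][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            bd = true;
          else if (Mk[ii + (long)nx * (jj + (long)ny * kk)] <= 0)
            bd = true;
        }
        if (bd) { xs.push_back(i); ys.push_back(j); zs.push_back(k); }
      }
  IntegerMatrix out(xs.size(), 3);
  for (size_t r = 0; r < xs.size(); ++r) {
    out(r, 0) = xs[r]; out(r, 1) = ys[r]; out(r, 2) = zs[r];
  }
  return out;
}

// Maximum pairwise distances over boundary voxels (physical units):
// (3D, fixed z in-plane, fixed x, fixed y)
// [[Rcpp::export]]
NumericVector max_diameters_cpp(IntegerMatrix pts, NumericVector spacing) {
  const int n = pts.nrow();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  std::vector<double> px(n), py(n), pz(n);
  std::vector<int> ix(n), iy(n), iz(n);
  for (int r = 0; r < n; ++r) {
    ix[r] = pts(r, 0); iy[r] = pts(r, 1); iz[r] = pts(r, 2);
    px[r] = ix[r] * sx; py[r] = iy[r] * sy; pz[r] = iz[r] * sz;
  }
  double d3 = 0.0, dslice = 0.0, dcol = 0.0, drow = 0.0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      double dx = px[a] - px[b], dy = py[a] - py[b], dz = pz[a] - pz[b];
      double q3 = dx*dx + dy*dy + dz*dz;
      if (q3 > d3) d3 = q3;
      if (iz[a] == iz[b]) { double q = dx*dx + dy*dy; if (q > dslice) dslice = q; }
      if (ix[a] == ix[b]) { double q = dy*dy + dz*dz; if (q > dcol) dcol = q; }
      if (iy[a] == iy[b]) { double q = dx*dx + dz*dz; if (q > drow) drow = q; }
    }
  return NumericVector::create(std::sqrt(d3), std::sqrt(dslice),
                               std::sqrt(dcol), std::sqrt(drow));
}
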