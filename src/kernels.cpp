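#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Centered cardinal B-spline of order n (degree n), orders 0..3.
// Partition of unity over integer shifts holds exactly for every order,
// which is what conserves total joint-histogram weight in GPVE.
static inline double bspline(int order, double x) {
  double a = std::fabs(x);
  switch (order) {
  case 0:
    return (a < 0.5) ? 1.0 : (a == 0.5 ? 0.5 : 0.0);
  case 1:
    return (a < 1.0) ? 1.0 - a : 0.0;
  case 2:
    if (a < 0.5) return 0.75 - a * a;
    if (a < 1.5) { double t = 1.5 - a; return 0.5 * t * t; }
    return 0.0;
  case 3:
    if (a < 1.0) return 2.0 / 3.0 - a * a + 0.5 * a * a * a;
    if (a < 2.0) { double t = 2.0 - a; return t * t * t / 6.0; }
    return 0.0;
  default:
    stop("unsupported B-spline order (0..3)");
  }
  return 0.0; // not reached
}

// Separable Gaussian blur with reflective (mirror) boundaries.
// sd is in voxels per axis; kernel truncated at 4 sd.
// [[Rcpp::export]]
NumericVector gauss_blur3(NumericVector vol, IntegerVector dims, NumericVector sd) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume length does not match dims");
  std::vector<double> src(vol.begin(), vol.end()), dst(n);

  int strides[3] = {1, nx, nx * ny};
  int sizes[3] = {nx, ny, nz};

  for (int axis = 0; axis < 3; ++axis) {
    double s = sd[axis];
    if (s <= 0) continue;
    int radius = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * radius + 1);
    double sum = 0.0;
    for (int i = -radius; i <= radius; ++i) {
      k[i + radius] = std::exp(-0.5 * i * i / (s * s));
      sum += k[i + radius];
    }
    for (double &w : k) w /= sum;

    int len = sizes[axis], stride = strides[axis];
    int nlines = (int)(n / len);
    // iterate every line along `axis`
    int oa = (axis + 1) % 3, ob = (axis + 2) % 3;
    for (int b = 0; b < sizes[ob]; ++b) {
      for (int a = 0; a < sizes[oa]; ++a) {
        R_xlen_t base = (R_xlen_t)a * strides[oa] + (R_xlen_t)b * strides[ob];
        for (int i = 0; i < len; ++i) {
          double acc = 0.0;
          for (int j = -radius; j <= radius; ++j) {
            int idx = i + j;
            // mirror without repeating the edge sample twice
            while (idx < 0 || idx >= len) {
              if (idx < 0) idx = -idx;
              if (idx >= len) idx = 2 * (len - 1) - idx;
              if (len == 1) { idx = 0; break; }
            }
            acc += k[j + radius] * src[base + (R_xlen_t)idx * stride];
          }
          dst[base + (R_xlen_t)i * stride] = acc;
        }
      }
    }
    (void)nlines;
    std::swap(src, dst);
  }
  return NumericVector(src.begin(), src.end());
}

static inline double sample_trilinear(const double *v, const int *d,
                                      double x, double y, double z,
                                      double pad) {
  // x,y,z are 0-based continuous voxel indices
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > d[0] - 0.5 || y > d[1] - 0.5 || z > d[2] - 0.5) return pad;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    int zz = z0 + dz; if (zz < 0) zz = 0; if (zz >= d[2]) zz = d[2] - 1;
    for (int dy = 0; dy < 2; ++dy) {
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      int yy = y0 + dy; if (yy < 0) yy = 0; if (yy >= d[1]) yy = d[1] - 1;
      for (int dx = 0; dx < 2; ++dx) {
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        int xx = x0 + dx; if (xx < 0) xx = 0; if (xx >= d[0]) xx = d[0] - 1;
        acc += wx * wy * wz *
               v[(R_xlen_t)xx + (R_xlen_t)d[0] * (yy + (R_xlen_t)d[1] * zz)];
      }
    }
  }
  return acc;
}

// Resample a source volume at arbitrary world points laid out on a target
// grid. `inv` is the 4x4 matrix mapping target world coords -> source world
// coords (row-major 16 values). interp: 0 = nearest, 1 = trilinear.
// [[Rcpp::export]]
NumericVector resample_grid(NumericVector src, IntegerVector sdims,
                            NumericVector sspacing, NumericVector sorigin,
                            IntegerVector tdims, NumericVector tspacing,
                            NumericVector torigin, NumericVector inv,
                            int interp, double pad) {
  int d[3] = {sdims[0], sdims[1], sdims[2]};
  R_xlen_t nt = (R_xlen_t)tdims[0] * tdims[1] * tdims[2];
  NumericVector out(nt);
  const double *v = src.begin();
  const double *M = inv.begin(); // row-major 4x4
  R_xlen_t p = 0;
  for (int k = 0; k < tdims[2]; ++k) {
    double wz = torigin[2] + k * tspacing[2];
    for (int j = 0; j < tdims[1]; ++j) {
      double wy = torigin[1] + j * tspacing[1];
      for (int i = 0; i < tdims[0]; ++i, ++p) {
        double wx = torigin[0] + i * tspacing[0];
        double sx = M[0] * wx + M[1] * wy + M[2] * wz + M[3];
        double sy = M[4] * wx + M[5] * wy + M[6] * wz + M[7];
        double sz = M[8] * wx + M[9] * wy + M[10] * wz + M[11];
        double ux = (sx - sorigin[0]) / sspacing[0];
        double uy = (sy - sorigin[1]) / sspacing[1];
        double uz = (sz - sorigin[2]) / sspacing[2];
        if (interp == 0) {
          long xi = (long)std::floor(ux + 0.5), yi = (long)std::floor(uy + 0.5),
               zi = (long)std::floor(uz + 0.5);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= d[0] || yi >= d[1] || zi >= d[2])
            out[p] = pad;
          else
            out[p] = v[xi + (R_xlen_t)d[0] * (yi + (R_xlen_t)d[1] * zi)];
        } else {
          out[p] = sample_trilinear(v, d, ux, uy, uz, pad);
        }
      }
    }
  }
  return out;
}

// Joint histogram between a reference volume (pre-binned labels) and a
// floating volume (pre-binned labels), scattering each floating voxel's unit
// weight into reference bins after mapping through the 4x4 world transform
// `fwd` (floating world -> reference world, row-major).
// scheme: 0 = NN, 1 = PV (trilinear weights), 2 = GPVE (B-spline kernels with
// per-axis orders). A floating voxel contributes only if every neighbour that
// would receive nonzero weight lies inside the reference grid; total weight
// then equals the number of contributing voxels.
// [[Rcpp::export]]
NumericMatrix joint_hist_cpp(IntegerVector refbin, IntegerVector rdims,
                             NumericVector rspacing, NumericVector rorigin,
                             IntegerVector fltbin, IntegerVector fdims,
                             NumericVector fspacing, NumericVector forigin,
                             NumericVector fwd, int nbins, int scheme,
                             IntegerVector orders) {
  NumericMatrix H(nbins, nbins);
  const double *M = fwd.begin();
  const int *rb = refbin.begin();
  int rd[3] = {rdims[0], rdims[1], rdims[2]};

  // kernel support per axis for GPVE: offsets m with |m - frac| <= (n+1)/2
  int ord[3] = {1, 1, 1};
  if (scheme == 2) { ord[0] = orders[0]; ord[1] = orders[1]; ord[2] = orders[2]; }

  R_xlen_t p = 0;
  for (int k = 0; k < fdims[2]; ++k) {
    double wz = forigin[2] + k * fspacing[2];
    for (int j = 0; j < fdims[1]; ++j) {
      double wy = forigin[1] + j * fspacing[1];
      for (int i = 0; i < fdims[0]; ++i, ++p) {
        int fb = fltbin[p];
        if (fb < 0) continue; // invalid (masked) floating voxel
        double wx = forigin[0] + i * fspacing[0];
        double rx = M[0] * wx + M[1] * wy + M[2] * wz + M[3];
        double ry = M[4] * wx + M[5] * wy + M[6] * wz + M[7];
        double rz = M[8] * wx + M[9] * wy + M[10] * wz + M[11];
        double u[3] = {(rx - rorigin[0]) / rspacing[0],
                       (ry - rorigin[1]) / rspacing[1],
                       (rz - rorigin[2]) / rspacing[2]};

        if (scheme == 0) { // nearest neighbour
          int xi = (int)std::floor(u[0] + 0.5), yi = (int)std::floor(u[1] + 0.5),
              zi = (int)std::floor(u[2] + 0.5);
          if (xi < 0 || yi < 0 || zi < 0 ||
              xi >= rd[0] || yi >= rd[1] || zi >= rd[2]) continue;
          int bin = rb[xi + (R_xlen_t)rd[0] * (yi + (R_xlen_t)rd[1] * zi)];
          H(bin, fb) += 1.0;
          continue;
        }

        // PV (order 1) and GPVE: per-axis kernel weights over support
        double wax[3][6]; int idx[3][6]; int cnt[3];
        bool ok = true;
        for (int a = 0; a < 3 && ok; ++a) {
          int n = (scheme == 1) ? 1 : ord[a];
          int base = (int)std::floor(u[a]);
          double frac = u[a] - base;
          double half = 0.5 * (n + 1);
          cnt[a] = 0;
          int lo = (int)std::ceil(frac - half), hi = (int)std::floor(frac + half);
          for (int m = lo; m <= hi; ++m) {
            double w = bspline(n, (double)m - frac);
            if (w <= 0.0) continue;
            int gi = base + m;
            if (gi < 0 || gi >= rd[a]) { ok = false; break; }
            wax[a][cnt[a]] = w; idx[a][cnt[a]] = gi; ++cnt[a];
          }
          if (cnt[a] == 0) ok = false;
        }
        if (!ok) continue;
        for (int c = 0; c < cnt[2]; ++c) {
          double wzv = wax[2][c]; R_xlen_t zoff = (R_xlen_t)rd[1] * idx[2][c];
          for (int b = 0; b < cnt[1]; ++b) {
            double wyz = wzv * wax[1][b];
            R_xlen_t yoff = (R_xlen_t)rd[0] * (idx[1][b] + zoff);
            for (int a2 = 0; a2 < cnt[0]; ++a2) {
              int bin = rb[idx[0][a2] + yoff];
              H(bin, fb) += wyz * wax[0][a2];
            }
          }
        }
      }
    }
  }
  return H;
}

// [[Rcpp::export]]
double bspline_eval(int order, double x) { return bspline(order, x); }
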