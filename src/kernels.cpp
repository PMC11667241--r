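// Low-level numerical kernels: box filtering (with exact adjoint),
// trilinear warping and resampling (with gradients/adjoints), direct 3D
// convolution (forward and backward passes), Siddon ray tracing and
// voxel-driven FDK backprojection with optional per-voxel displacement.
// All arrays are column-major (x fastest), matching R's layout.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static inline int iclamp(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}
static inline double dclamp(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Replicate-padded box sum over a (2r+1)^3 window, separable sliding sums.
// ---------------------------------------------------------------------------

// sliding sum along the first axis of a conceptual (n0, nrest) array where
// the input has n0 + 2r rows and the output n0 rows.
static void slide_sum(const std::vector<double>& in, std::vector<double>& out,
                      int n0, long nrest, int r) {
  const int npad = n0 + 2 * r;
  const int w = 2 * r + 1;
  for (long s = 0; s < nrest; ++s) {
    const double* col = &in[(long)npad * s];
    double* oc = &out[(long)n0 * s];
    double acc = 0.0;
    for (int i = 0; i < w; ++i) acc += col[i];
    oc[0] = acc;
    for (int i = 1; i < n0; ++i) {
      acc += col[i + w - 1] - col[i - 1];
      oc[i] = acc;
    }
  }
}

// adjoint of slide_sum: maps core (n0) to padded (n0 + 2r)
static void slide_sum_adj(const std::vector<double>& g, std::vector<double>& out,
                          int n0, long nrest, int r) {
  const int npad = n0 + 2 * r;
  const int w = 2 * r + 1;
  for (long s = 0; s < nrest; ++s) {
    const double* gc = &g[(long)n0 * s];
    double* oc = &out[(long)npad * s];
    // out[k] = sum_{c : c <= k <= c + 2r} g[c], c in [0, n0)
    double acc = 0.0;
    for (int k = 0; k < npad; ++k) {
      if (k < n0) acc += gc[k];
      if (k - w >= 0) acc -= gc[k - w];
      oc[k] = acc;
    }
  }
}

// permute conceptual (a, b, c) -> (b, c, a) so each axis can take the lead
static void rotate_axes(const std::vector<double>& in, std::vector<double>& out,
                        long na, long nb, long nc) {
  for (long k = 0; k < nc; ++k)
    for (long j = 0; j < nb; ++j)
      for (long i = 0; i < na; ++i)
        out[j + nb * (k + nc * i)] = in[i + na * (j + nb * k)];
}

// [[Rcpp::export]]
NumericVector cpp_boxsum3(NumericVector x, IntegerVector dims, int r) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int px = nx + 2 * r, py = ny + 2 * r, pz = nz + 2 * r;
  // replicate pad
  std::vector<double> pad((long)px * py * pz);
  for (int k = 0; k < pz; ++k) {
    int kk = iclamp(k - r, 0, nz - 1);
    for (int j = 0; j < py; ++j) {
      int jj = iclamp(j - r, 0, ny - 1);
      const double* src = &x[(long)nx * (jj + (long)ny * kk)];
      double* dst = &pad[(long)px * (j + (long)py * k)];
      for (int i = 0; i < px; ++i) dst[i] = src[iclamp(i - r, 0, nx - 1)];
    }
  }
  // pass 1: x (pad: x,y,z) -> (nx, py, pz)
  std::vector<double> a((long)nx * py * pz);
  slide_sum(pad, a, nx, (long)py * pz, r);
  // rotate (nx, py, pz) -> (py, pz, nx), slide over y -> (ny, pz, nx)
  std::vector<double> b((long)py * pz * nx);
  rotate_axes(a, b, nx, py, pz);
  std::vector<double> c((long)ny * pz * nx);
  slide_sum(b, c, ny, (long)pz * nx, r);
  // rotate (ny, pz, nx) -> (pz, nx, ny), slide over z -> (nz, nx, ny)
  std::vector<double> d((long)pz * nx * ny);
  rotate_axes(c, d, ny, pz, nx);
  std::vector<double> e((long)nz * nx * ny);
  slide_sum(d, e, nz, (long)nx * ny, r);
  // rotate (nz, nx, ny) -> (nx, ny, nz)
  NumericVector out((long)nx * ny * nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      for (int k = 0; k < nz; ++k)
        out[i + (long)nx * (j + (long)ny * k)] = e[k + (long)nz * (i + (long)nx * j)];
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_boxsum3_adjoint(NumericVector g, IntegerVector dims, int r) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int px = nx + 2 * r, py = ny + 2 * r, pz = nz + 2 * r;
  // reverse of pass 3: z scatter; input conceptually (nz, nx, ny)
  std::vector<double> gz((long)nz * nx * ny);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        gz[k + (long)nz * (i + (long)nx * j)] = g[i + (long)nx * (j + (long)ny * k)];
  std::vector<double> d((long)pz * nx * ny);
  slide_sum_adj(gz, d, nz, (long)nx * ny, r);
  // un-rotate (pz, nx, ny) -> (ny, pz, nx): inverse of (ny,pz,nx)->(pz,nx,ny)
  std::vector<double> c((long)ny * pz * nx);
  for (long i = 0; i < (long)ny; ++i)
    for (long k = 0; k < (long)nx; ++k)
      for (long j = 0; j < (long)pz; ++j)
        c[i + (long)ny * (j + (long)pz * k)] = d[j + (long)pz * (k + (long)nx * i)];
  std::vector<double> b((long)py * pz * nx);
  slide_sum_adj(c, b, ny, (long)pz * nx, r);
  // un-rotate (py, pz, nx) -> (nx, py, pz)
  std::vector<double> a((long)nx * py * pz);
  for (long i = 0; i < (long)nx; ++i)
    for (long k = 0; k < (long)py; ++k)
      for (long j = 0; j < (long)pz; ++j)
        a[i + (long)nx * (k + (long)py * j)] = b[k + (long)py * (j + (long)pz * i)];
  std::vector<double> pad((long)px * py * pz);
  slide_sum_adj(a, pad, nx, (long)py * pz, r);
  // fold replicate padding back onto clamped source voxels
  NumericVector out((long)nx * ny * nz);
  for (int k = 0; k < pz; ++k) {
    int kk = iclamp(k - r, 0, nz - 1);
    for (int j = 0; j < py; ++j) {
      int jj = iclamp(j - r, 0, ny - 1);
      double* dst = &out[(long)nx * (jj + (long)ny * kk)];
      const double* src = &pad[(long)px * (j + (long)py * k)];
      for (int i = 0; i < px; ++i) dst[iclamp(i - r, 0, nx - 1)] += src[i];
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear interpolation: warping, resampling and their adjoints/gradients
// ---------------------------------------------------------------------------

// sample vol at continuous 0-based (x,y,z), clamped (border replicate);
// optionally fills d[3] with the derivative wrt (x,y,z) (0 where clamped)
static inline double trilerp(const double* vol, int nx, int ny, int nz,
                             double x, double y, double z, double* d) {
  bool cx0 = x <= 0.0, cx1 = x >= nx - 1.0;
  bool cy0 = y <= 0.0, cy1 = y >= ny - 1.0;
  bool cz0 = z <= 0.0, cz1 = z >= nz - 1.0;
  x = dclamp(x, 0.0, nx - 1.0);
  y = dclamp(y, 0.0, ny - 1.0);
  z = dclamp(z, 0.0, nz - 1.0);
  int i0 = std::min((int)std::floor(x), nx - 2); if (nx == 1) i0 = 0;
  int j0 = std::min((int)std::floor(y), ny - 2); if (ny == 1) j0 = 0;
  int k0 = std::min((int)std::floor(z), nz - 2); if (nz == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
      k1 = std::min(k0 + 1, nz - 1);
  #define V(i, j, k) vol[(i) + (long)nx * ((j) + (long)ny * (k))]
  double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
  double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
  double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
  double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  double val = c0 * (1 - fz) + c1 * fz;
  if (d) {
    double dx00 = V(i1, j0, k0) - V(i0, j0, k0);
    double dx10 = V(i1, j1, k0) - V(i0, j1, k0);
    double dx01 = V(i1, j0, k1) - V(i0, j0, k1);
    double dx11 = V(i1, j1, k1) - V(i0, j1, k1);
    double gx = ((dx00 * (1 - fy) + dx10 * fy) * (1 - fz) +
                 (dx01 * (1 - fy) + dx11 * fy) * fz);
    double gy = ((c10 - c00) * (1 - fz) + (c11 - c01) * fz);
    double gz = (c1 - c0);
    d[0] = (cx0 || cx1) ? 0.0 : gx;
    d[1] = (cy0 || cy1) ? 0.0 : gy;
    d[2] = (cz0 || cz1) ? 0.0 : gz;
  }
  #undef V
  return val;
}

// warp: out(p) = vol(p + D(p)); D in voxel units, dim (nx,ny,nz,3)
// [[Rcpp::export]]
List cpp_warp(NumericVector vol, IntegerVector dims, NumericVector disp,
              bool want_grad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  NumericVector out(nvox);
  NumericVector gx, gy, gz;
  if (want_grad) { gx = NumericVector(nvox); gy = NumericVector(nvox); gz = NumericVector(nvox); }
  const double* dX = &disp[0];
  const double* dY = &disp[nvox];
  const double* dZ = &disp[2 * nvox];
  double d[3];
  long idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + dX[idx], y = j + dY[idx], z = k + dZ[idx];
        out[idx] = trilerp(&vol[0], nx, ny, nz, x, y, z, want_grad ? d : nullptr);
        if (want_grad) { gx[idx] = d[0]; gy[idx] = d[1]; gz[idx] = d[2]; }
      }
  out.attr("dim") = dims;
  if (!want_grad) return List::create(_["value"] = out);
  gx.attr("dim") = dims; gy.attr("dim") = dims; gz.attr("dim") = dims;
  return List::create(_["value"] = out, _["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// map fine voxel index to coarse continuous coordinate for factor f = nf/nc
static inline double fine_to_coarse(int i, double f) {
  return (i + 0.5) / f - 0.5;
}

// trilinear resample a (possibly multi-channel) volume from dims_in to
// dims_out on the same physical domain
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dims_in,
                           IntegerVector dims_out, int nchan) {
  const int ax = dims_in[0], ay = dims_in[1], az = dims_in[2];
  const int bx = dims_out[0], by = dims_out[1], bz = dims_out[2];
  const long nin = (long)ax * ay * az, nout = (long)bx * by * bz;
  const double fx = (double)bx / ax, fy = (double)by / ay, fz = (double)bz / az;
  NumericVector out(nout * nchan);
  for (int c = 0; c < nchan; ++c) {
    const double* src = &vol[c * nin];
    double* dst = &out[c * nout];
    long idx = 0;
    for (int k = 0; k < bz; ++k) {
      double zc = fine_to_coarse(k, fz);
      for (int j = 0; j < by; ++j) {
        double yc = fine_to_coarse(j, fy);
        for (int i = 0; i < bx; ++i, ++idx)
          dst[idx] = trilerp(src, ax, ay, az, fine_to_coarse(i, fx), yc, zc, nullptr);
      }
    }
  }
  if (nchan == 1) out.attr("dim") = dims_out;
  else out.attr("dim") = IntegerVector::create(bx, by, bz, nchan);
  return out;
}

// exact adjoint of cpp_resample (scatter with the same weights)
// [[Rcpp::export]]
NumericVector cpp_resample_adjoint(NumericVector g, IntegerVector dims_fine,
                                   IntegerVector dims_coarse, int nchan) {
  const int bx = dims_fine[0], by = dims_fine[1], bz = dims_fine[2];
  const int ax = dims_coarse[0], ay = dims_coarse[1], az = dims_coarse[2];
  const long nfine = (long)bx * by * bz, ncoarse = (long)ax * ay * az;
  const double fx = (double)bx / ax, fy = (double)by / ay, fz = (double)bz / az;
  NumericVector out(ncoarse * nchan);
  for (int c = 0; c < nchan; ++c) {
    const double* gc = &g[c * nfine];
    double* dst = &out[c * ncoarse];
    long idx = 0;
    for (int k = 0; k < bz; ++k) {
      double z = dclamp(fine_to_coarse(k, fz), 0.0, az - 1.0);
      int k0 = az == 1 ? 0 : std::min((int)std::floor(z), az - 2);
      double wz = z - k0; int k1 = std::min(k0 + 1, az - 1);
      for (int j = 0; j < by; ++j) {
        double y = dclamp(fine_to_coarse(j, fy), 0.0, ay - 1.0);
        int j0 = ay == 1 ? 0 : std::min((int)std::floor(y), ay - 2);
        double wy = y - j0; int j1 = std::min(j0 + 1, ay - 1);
        for (int i = 0; i < bx; ++i, ++idx) {
          double x = dclamp(fine_to_coarse(i, fx), 0.0, ax - 1.0);
          int i0 = ax == 1 ? 0 : std::min((int)std::floor(x), ax - 2);
          double wx = x - i0; int i1 = std::min(i0 + 1, ax - 1);
          double gv = gc[idx];
          #define ACC(ii, jj, kk, w) dst[(ii) + (long)ax * ((jj) + (long)ay * (kk))] += gv * (w)
          ACC(i0, j0, k0, (1 - wx) * (1 - wy) * (1 - wz));
          ACC(i1, j0, k0, wx * (1 - wy) * (1 - wz));
          ACC(i0, j1, k0, (1 - wx) * wy * (1 - wz));
          ACC(i1, j1, k0, wx * wy * (1 - wz));
          ACC(i0, j0, k1, (1 - wx) * (1 - wy) * wz);
          ACC(i1, j0, k1, wx * (1 - wy) * wz);
          ACC(i0, j1, k1, (1 - wx) * wy * wz);
          ACC(i1, j1, k1, wx * wy * wz);
          #undef ACC
        }
      }
    }
  }
  if (nchan == 1) out.attr("dim") = dims_coarse;
  else out.attr("dim") = IntegerVector::create(ax, ay, az, nchan);
  return out;
}

// non-overlapping average pooling by integer factor (dims divisible)
// [[Rcpp::export]]
NumericVector cpp_avgpool(NumericVector vol, IntegerVector dims, int nchan, int f) {
  const int ax = dims[0], ay = dims[1], az = dims[2];
  const int bx = ax / f, by = ay / f, bz = az / f;
  const long nin = (long)ax * ay * az, nout = (long)bx * by * bz;
  const double inv = 1.0 / ((double)f * f * f);
  NumericVector out(nout * nchan);
  for (int c = 0; c < nchan; ++c) {
    const double* src = &vol[c * nin];
    double* dst = &out[c * nout];
    for (int k = 0; k < bz; ++k)
      for (int j = 0; j < by; ++j)
        for (int i = 0; i < bx; ++i) {
          double acc = 0.0;
          for (int dk = 0; dk < f; ++dk)
            for (int dj = 0; dj < f; ++dj)
              for (int di = 0; di < f; ++di)
                acc += src[(i * f + di) + (long)ax * ((j * f + dj) + (long)ay * (k * f + dk))];
          dst[i + (long)bx * (j + (long)by * k)] = acc * inv;
        }
  }
  if (nchan == 1) out.attr("dim") = IntegerVector::create(bx, by, bz);
  else out.attr("dim") = IntegerVector::create(bx, by, bz, nchan);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_adjoint(NumericVector g, IntegerVector dims_out,
                                  int nchan, int f) {
  const int bx = dims_out[0], by = dims_out[1], bz = dims_out[2];
  const int ax = bx * f, ay = by * f, az = bz * f;
  const long nout = (long)bx * by * bz, nin = (long)ax * ay * az;
  const double inv = 1.0 / ((double)f * f * f);
  NumericVector out(nin * nchan);
  for (int c = 0; c < nchan; ++c) {
    const double* gc = &g[c * nout];
    double* dst = &out[c * nin];
    for (int k = 0; k < az; ++k)
      for (int j = 0; j < ay; ++j)
        for (int i = 0; i < ax; ++i)
          dst[i + (long)ax * (j + (long)ay * k)] =
            gc[(i / f) + (long)bx * ((j / f) + (long)by * (k / f))] * inv;
  }
  if (nchan == 1) out.attr("dim") = IntegerVector::create(ax, ay, az);
  else out.attr("dim") = IntegerVector::create(ax, ay, az, nchan);
  return out;
}

// ---------------------------------------------------------------------------
// Direct 3D convolution, kernel 3, zero padding 1, plus backward passes.
// x: (nx,ny,nz,cin); w: (3,3,3,cin,cout); b: (cout)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv3(NumericVector x, IntegerVector dims, int cin,
                        NumericVector w, NumericVector b, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  NumericVector out(nvox * cout);
  for (int co = 0; co < cout; ++co) {
    double* o = &out[co * nvox];
    const double bias = b[co];
    for (long v = 0; v < nvox; ++v) o[v] = bias;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xi = &x[ci * nvox];
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const double wv = w[(di + 1) + 3 * ((dj + 1) + 3 * ((dk + 1) + 3 * (ci + (long)cin * co)))];
            if (wv == 0.0) continue;
            const int k0 = std::max(0, -dk), k1 = std::min(nz, nz - dk);
            const int j0 = std::max(0, -dj), j1 = std::min(ny, ny - dj);
            const int i0 = std::max(0, -di), i1 = std::min(nx, nx - di);
            for (int k = k0; k < k1; ++k)
              for (int j = j0; j < j1; ++j) {
                double* orow = &o[(long)nx * (j + (long)ny * k)];
                const double* xrow = &xi[(long)nx * ((j + dj) + (long)ny * (k + dk)) + di];
                for (int i = i0; i < i1; ++i) orow[i] += wv * xrow[i];
              }
          }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// gradient wrt input: correlate gout with kernel flipped, channels swapped
// [[Rcpp::export]]
NumericVector cpp_conv3_bwd_input(NumericVector gout, IntegerVector dims,
                                  int cout, NumericVector w, int cin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  NumericVector gin(nvox * cin);
  for (int ci = 0; ci < cin; ++ci) {
    double* o = &gin[ci * nvox];
    for (int co = 0; co < cout; ++co) {
      const double* g = &gout[co * nvox];
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const double wv = w[(di + 1) + 3 * ((dj + 1) + 3 * ((dk + 1) + 3 * (ci + (long)cin * co)))];
            if (wv == 0.0) continue;
            // out(p) += w * x(p + d)  =>  gin(q) += w * gout(q - d)
            const int k0 = std::max(0, dk), k1 = std::min(nz, nz + dk);
            const int j0 = std::max(0, dj), j1 = std::min(ny, ny + dj);
            const int i0 = std::max(0, di), i1 = std::min(nx, nx + di);
            for (int k = k0; k < k1; ++k)
              for (int j = j0; j < j1; ++j) {
                double* orow = &o[(long)nx * (j + (long)ny * k)];
                const double* grow = &g[(long)nx * ((j - dj) + (long)ny * (k - dk)) - di];
                for (int i = i0; i < i1; ++i) orow[i] += wv * grow[i];
              }
          }
    }
  }
  gin.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  return gin;
}

// gradient wrt weights and bias
// [[Rcpp::export]]
List cpp_conv3_bwd_weights(NumericVector x, IntegerVector dims, int cin,
                           NumericVector gout, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  NumericVector gw(27L * cin * cout);
  NumericVector gb(cout);
  for (int co = 0; co < cout; ++co) {
    const double* g = &gout[co * nvox];
    double acc_b = 0.0;
    for (long v = 0; v < nvox; ++v) acc_b += g[v];
    gb[co] = acc_b;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xi = &x[ci * nvox];
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int k0 = std::max(0, -dk), k1 = std::min(nz, nz - dk);
            const int j0 = std::max(0, -dj), j1 = std::min(ny, ny - dj);
            const int i0 = std::max(0, -di), i1 = std::min(nx, nx - di);
            double acc = 0.0;
            for (int k = k0; k < k1; ++k)
              for (int j = j0; j < j1; ++j) {
                const double* grow = &g[(long)nx * (j + (long)ny * k)];
                const double* xrow = &xi[(long)nx * ((j + dj) + (long)ny * (k + dk)) + di];
                for (int i = i0; i < i1; ++i) acc += grow[i] * xrow[i];
              }
            gw[(di + 1) + 3 * ((dj + 1) + 3 * ((dk + 1) + 3 * (ci + (long)cin * co)))] = acc;
          }
    }
  }
  gw.attr("dim") = IntegerVector::create(3, 3, 3, cin, cout);
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Bending energy of a displacement-field set: sum of squared second forward
// differences along each spatial axis, plus the gradient of that sum.
// x has dims (nx, ny, nz, 3, N); returns unweighted value and gradient.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_second_diff_energy(NumericVector x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  const long nfields = (long)dims[3] * dims[4];
  NumericVector grad(x.size());
  double total = 0.0;
  const long stride[3] = { 1, nx, (long)nx * ny };
  const int n[3] = { nx, ny, nz };
  for (long f = 0; f < nfields; ++f) {
    const double* xf = &x[f * nvox];
    double* gf = &grad[f * nvox];
    for (int ax = 0; ax < 3; ++ax) {
      if (n[ax] < 3) continue;
      const long st = stride[ax];
      long idx = 0;
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i, ++idx) {
            const int pos = ax == 0 ? i : (ax == 1 ? j : k);
            if (pos > n[ax] - 3) continue;
            const double s = xf[idx + 2 * st] - 2.0 * xf[idx + st] + xf[idx];
            total += s * s;
            gf[idx] += 2.0 * s;
            gf[idx + st] -= 4.0 * s;
            gf[idx + 2 * st] += 2.0 * s;
          }
    }
  }
  grad.attr("dim") = dims;
  return List::create(_["value"] = total, _["grad"] = grad);
}

// ---------------------------------------------------------------------------
// Cone-beam forward projection (Siddon exact ray/voxel traversal)
// ---------------------------------------------------------------------------

// line integral of vol along segment p0 -> p1 (world coords, mm)
static double siddon_ray(const double* vol, const int* n, const double* sp,
                         const double* org, const double p0[3], const double p1[3]) {
  // voxel i spans [org + (i - 0.5) sp, org + (i + 0.5) sp]
  double d[3], bmin[3], bmax[3];
  for (int a = 0; a < 3; ++a) {
    d[a] = p1[a] - p0[a];
    bmin[a] = org[a] - 0.5 * sp[a];
    bmax[a] = org[a] + (n[a] - 0.5) * sp[a];
  }
  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p0[a] < bmin[a] || p0[a] > bmax[a]) return 0.0;
    } else {
      double ta = (bmin[a] - p0[a]) / d[a];
      double tb = (bmax[a] - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta); t1 = std::min(t1, tb);
    }
  }
  if (t0 >= t1) return 0.0;
  const double len = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  // traversal state
  int idx[3], step[3];
  double tnext[3], dt[3];
  const double eps = 1e-9;
  double tmid = t0;
  for (int a = 0; a < 3; ++a) {
    double pa = p0[a] + (t0 + eps) * d[a];
    int i = (int)std::floor((pa - (org[a] - 0.5 * sp[a])) / sp[a]);
    idx[a] = iclamp(i, 0, n[a] - 1);
    if (d[a] > 0) {
      step[a] = 1;
      tnext[a] = ((org[a] + (idx[a] + 0.5) * sp[a]) - p0[a]) / d[a];
      dt[a] = sp[a] / d[a];
    } else if (d[a] < 0) {
      step[a] = -1;
      tnext[a] = ((org[a] + (idx[a] - 0.5) * sp[a]) - p0[a]) / d[a];
      dt[a] = -sp[a] / d[a];
    } else {
      step[a] = 0; tnext[a] = 2.0; dt[a] = 2.0;
    }
  }
  double acc = 0.0, t = t0;
  (void)tmid;
  const int nxl = n[0], nyl = n[1];
  while (t < t1 - 1e-12) {
    int a = 0;
    if (tnext[1] < tnext[a]) a = 1;
    if (tnext[2] < tnext[a]) a = 2;
    double te = std::min(tnext[a], t1);
    double seg = (te - t) * len;
    if (seg > 0)
      acc += seg * vol[idx[0] + (long)nxl * (idx[1] + (long)nyl * idx[2])];
    t = te;
    if (tnext[a] >= t1) break;
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= n[a]) break;
    tnext[a] += dt[a];
  }
  return acc;
}

// project one volume for a set of gantry angles
// geometry: source at SID*(-sin th, cos th, 0); flat detector centered on the
// central ray at distance SDD from the source; eu = (cos th, sin th, 0),
// ev = (0,0,1); pixel (iu,iv) at offsets (iu - (nu-1)/2)*du etc.
// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, IntegerVector dims,
                          NumericVector spacing, NumericVector origin,
                          NumericVector angles, double sid, double sdd,
                          int nu, int nv, double du, double dv) {
  const int n[3] = { dims[0], dims[1], dims[2] };
  const double sp[3] = { spacing[0], spacing[1], spacing[2] };
  const double org[3] = { origin[0], origin[1], origin[2] };
  const int nproj = angles.size();
  NumericVector out((long)nu * nv * nproj);
  for (int p = 0; p < nproj; ++p) {
    const double th = angles[p];
    const double src[3] = { -sid * std::sin(th), sid * std::cos(th), 0.0 };
    const double ew[3] = { std::sin(th), -std::cos(th), 0.0 };
    const double eu[3] = { std::cos(th), std::sin(th), 0.0 };
    const double dc[3] = { src[0] + sdd * ew[0], src[1] + sdd * ew[1], 0.0 };
    double* op = &out[(long)nu * nv * p];
    for (int iv = 0; iv < nv; ++iv) {
      const double vv = (iv - 0.5 * (nv - 1)) * dv;
      for (int iu = 0; iu < nu; ++iu) {
        const double uu = (iu - 0.5 * (nu - 1)) * du;
        const double pix[3] = { dc[0] + uu * eu[0], dc[1] + uu * eu[1], vv };
        op[iu + (long)nu * iv] = siddon_ray(&vol[0], n, sp, org, src, pix);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nu, nv, nproj);
  return out;
}

// ---------------------------------------------------------------------------
// Voxel-driven FDK backprojection (optionally with per-voxel displacement)
// ---------------------------------------------------------------------------

// filtered: (nu, nv, nproj) ramp-filtered, cosine-weighted projections.
// disp: either length 0 (identity) or (nx,ny,nz,3) voxel-unit displacement
// applied to each voxel before projecting onto the detector.
// weights: per-projection scale (angular step / 2 folded in by caller).
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector filtered, IntegerVector pdims,
                              NumericVector angles, NumericVector weights,
                              IntegerVector dims, NumericVector spacing,
                              NumericVector origin, double sid, double sdd,
                              double du, double dv, NumericVector disp) {
  const int nu = pdims[0], nv = pdims[1], nproj = pdims[2];
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  const bool warped = disp.size() == nvox * 3;
  NumericVector out(nvox);
  const double cu = 0.5 * (nu - 1), cv = 0.5 * (nv - 1);
  for (int p = 0; p < nproj; ++p) {
    const double th = angles[p], wproj = weights[p];
    const double sx = -sid * std::sin(th), sy = sid * std::cos(th);
    const double ewx = std::sin(th), ewy = -std::cos(th);
    const double eux = std::cos(th), euy = std::sin(th);
    const double* q = &filtered[(long)nu * nv * p];
    long idx = 0;
    for (int k = 0; k < nz; ++k) {
      const double z0 = origin[2] + k * spacing[2];
      for (int j = 0; j < ny; ++j) {
        const double y0 = origin[1] + j * spacing[1];
        for (int i = 0; i < nx; ++i, ++idx) {
          double x = origin[0] + i * spacing[0], y = y0, z = z0;
          if (warped) {
            x += disp[idx] * spacing[0];
            y += disp[idx + nvox] * spacing[1];
            z += disp[idx + 2 * nvox] * spacing[2];
          }
          const double rx = x - sx, ry = y - sy;
          const double w = rx * ewx + ry * ewy;   // distance along central ray
          if (w <= 1e-6) continue;
          const double uu = sdd * (rx * eux + ry * euy) / w;
          const double vv = sdd * z / w;
          const double fu = uu / du + cu, fv = vv / dv + cv;
          if (fu < 0 || fu > nu - 1 || fv < 0 || fv > nv - 1) continue;
          int iu0 = std::min((int)std::floor(fu), nu - 2);
          int iv0 = std::min((int)std::floor(fv), nv - 2);
          const double au = fu - iu0, av = fv - iv0;
          const double q00 = q[iu0 + (long)nu * iv0];
          const double q10 = q[iu0 + 1 + (long)nu * iv0];
          const double q01 = q[iu0 + (long)nu * (iv0 + 1)];
          const double q11 = q[iu0 + 1 + (long)nu * (iv0 + 1)];
          const double val = (q00 * (1 - au) + q10 * au) * (1 - av) +
                             (q01 * (1 - au) + q11 * au) * av;
          out[idx] += wproj * (sid * sid / (w * w)) * val;
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// MoCo variant: each projection carries a 0-based phase label selecting one
// of nphase displacement fields (nx,ny,nz,3,nphase, voxel units) applied to
// the voxel before projecting. Projections are processed in acquisition
// order so that an all-zero motion model reproduces plain FDK bit for bit.
// [[Rcpp::export]]
NumericVector cpp_backproject_moco(NumericVector filtered, IntegerVector pdims,
                                   NumericVector angles, NumericVector weights,
                                   IntegerVector labels, IntegerVector dims,
                                   NumericVector spacing, NumericVector origin,
                                   double sid, double sdd, double du, double dv,
                                   NumericVector disp, int nphase) {
  const int nu = pdims[0], nv = pdims[1], nproj = pdims[2];
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  NumericVector out(nvox);
  const double cu = 0.5 * (nu - 1), cv = 0.5 * (nv - 1);
  for (int p = 0; p < nproj; ++p) {
    const double th = angles[p], wproj = weights[p];
    const int lab = labels[p];
    const double* dX = &disp[(long)3 * nvox * lab];
    const double* dY = dX + nvox;
    const double* dZ = dY + nvox;
    const double sx = -sid * std::sin(th), sy = sid * std::cos(th);
    const double ewx = std::sin(th), ewy = -std::cos(th);
    const double eux = std::cos(th), euy = std::sin(th);
    const double* q = &filtered[(long)nu * nv * p];
    long idx = 0;
    for (int k = 0; k < nz; ++k) {
      const double z0 = origin[2] + k * spacing[2];
      for (int j = 0; j < ny; ++j) {
        const double y0 = origin[1] + j * spacing[1];
        for (int i = 0; i < nx; ++i, ++idx) {
          const double x = origin[0] + i * spacing[0] + dX[idx] * spacing[0];
          const double y = y0 + dY[idx] * spacing[1];
          const double z = z0 + dZ[idx] * spacing[2];
          const double rx = x - sx, ry = y - sy;
          const double w = rx * ewx + ry * ewy;
          if (w <= 1e-6) continue;
          const double uu = sdd * (rx * eux + ry * euy) / w;
          const double vv = sdd * z / w;
          const double fu = uu / du + cu, fv = vv / dv + cv;
          if (fu < 0 || fu > nu - 1 || fv < 0 || fv > nv - 1) continue;
          int iu0 = std::min((int)std::floor(fu), nu - 2);
          int iv0 = std::min((int)std::floor(fv), nv - 2);
          const double au = fu - iu0, av = fv - iv0;
          const double q00 = q[iu0 + (long)nu * iv0];
          const double q10 = q[iu0 + 1 + (long)nu * iv0];
          const double q01 = q[iu0 + (long)nu * (iv0 + 1)];
          const double q11 = q[iu0 + 1 + (long)nu * (iv0 + 1)];
          const double val = (q00 * (1 - au) + q10 * au) * (1 - av) +
                             (q01 * (1 - au) + q11 * au) * av;
          out[idx] += wproj * (sid * sid / (w * w)) * val;
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian filter, replicate borders (SSIM windowing)
// ---------------------------------------------------------------------------

static void gauss_axis(std::vector<double>& buf, int nx, int ny, int nz,
                       const std::vector<double>& kern, int axis) {
  const int r = ((int)kern.size() - 1) / 2;
  std::vector<double> tmp(buf.size());
  const int n[3] = { nx, ny, nz };
  const long stride[3] = { 1, nx, (long)nx * ny };
  long idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        const int pos[3] = { i, j, k };
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int pt = iclamp(pos[axis] + t, 0, n[axis] - 1);
          acc += kern[t + r] * buf[idx + (long)(pt - pos[axis]) * stride[axis]];
        }
        tmp[idx] = acc;
      }
  buf.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector x, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) { kern[t + r] = std::exp(-0.5 * t * t / (sigma * sigma)); s += kern[t + r]; }
  for (auto& v : kern) v /= s;
  std::vector<double> buf(x.begin(), x.end());
  gauss_axis(buf, nx, ny, nz, kern, 0);
  gauss_axis(buf, nx, ny, nz, kern, 1);
  if (nz > 1) gauss_axis(buf, nx, ny, nz, kern, 2);
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = dims;
  return out;
}
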