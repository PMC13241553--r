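#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Layout convention: volumes are column-major arrays dim (nx, ny, nz, C),
// x fastest. All indices 0-based in C++.

static inline int vox(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// im2col for 3D convolution with cubic kernel k, isotropic stride and
// zero padding. Transposed layout: the returned matrix is
// (Nout x k^3*Cin) with columns ordered (kx, ky, kz, ci) fastest-first,
// matching matrix(W, k^3*Cin, Cout) from a (k,k,k,Cin,Cout) array.
// Inner x-spans are contiguous in both source and destination.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims,
                         int k, int stride, int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int ox = (nx + 2 * pad - k) / stride + 1;
  const int oy = (ny + 2 * pad - k) / stride + 1;
  const int oz = (nz + 2 * pad - k) / stride + 1;
  const R_xlen_t N = (R_xlen_t)ox * oy * oz;
  NumericMatrix col(N, (R_xlen_t)k * k * k * C);
  const double* px = x.begin();
  double* pc = col.begin();
  const R_xlen_t plane = (R_xlen_t)nx * ny * nz;
  int r = 0;
  for (int ci = 0; ci < C; ++ci)
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx, ++r) {
          // re-order r to (kx,ky,kz,ci) fastest-first
          const int rr = kx + k * (ky + k * (kz + k * ci));
          double* dcol = pc + (R_xlen_t)rr * N;
          const double* src0 = px + ci * plane;
          // xo range with x = xo*stride + kx - pad inside [0, nx)
          const int off = kx - pad;
          int xo_lo = (off < 0) ? ((-off + stride - 1) / stride) : 0;
          int xo_hi = (nx - 1 - off) / stride;
          if (xo_hi > ox - 1) xo_hi = ox - 1;
          for (int zo = 0; zo < oz; ++zo) {
            const int z = zo * stride + kz - pad;
            for (int yo = 0; yo < oy; ++yo) {
              const int y = yo * stride + ky - pad;
              double* dst = dcol + (R_xlen_t)ox * (yo + (R_xlen_t)oy * zo);
              if (z < 0 || z >= nz || y < 0 || y >= ny || xo_lo > xo_hi)
                continue;  // stays zero
              const double* src = src0 + vox(0, y, z, nx, ny);
              if (stride == 1) {
                memcpy(dst + xo_lo, src + off + xo_lo,
                       (xo_hi - xo_lo + 1) * sizeof(double));
              } else {
                for (int xo = xo_lo; xo <= xo_hi; ++xo)
                  dst[xo] = src[xo * stride + off];
              }
            }
          }
        }
  return col;
}

// Scatter-add adjoint of cpp_im2col: given an (Nout x k^3*Cin) matrix,
// accumulate back into an (nx,ny,nz,Cin) array.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix col, IntegerVector dims,
                         int k, int stride, int pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int ox = (nx + 2 * pad - k) / stride + 1;
  const int oy = (ny + 2 * pad - k) / stride + 1;
  const int oz = (nz + 2 * pad - k) / stride + 1;
  const R_xlen_t N = (R_xlen_t)ox * oy * oz;
  const R_xlen_t plane = (R_xlen_t)nx * ny * nz;
  NumericVector out((R_xlen_t)plane * C);
  const double* pc = col.begin();
  double* po = out.begin();
  for (int ci = 0; ci < C; ++ci)
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int rr = kx + k * (ky + k * (kz + k * ci));
          const double* scol = pc + (R_xlen_t)rr * N;
          double* dst0 = po + ci * plane;
          const int off = kx - pad;
          int xo_lo = (off < 0) ? ((-off + stride - 1) / stride) : 0;
          int xo_hi = (nx - 1 - off) / stride;
          if (xo_hi > ox - 1) xo_hi = ox - 1;
          for (int zo = 0; zo < oz; ++zo) {
            const int z = zo * stride + kz - pad;
            if (z < 0 || z >= nz) continue;
            for (int yo = 0; yo < oy; ++yo) {
              const int y = yo * stride + ky - pad;
              if (y < 0 || y >= ny || xo_lo > xo_hi) continue;
              const double* src =
                scol + (R_xlen_t)ox * (yo + (R_xlen_t)oy * zo);
              double* dst = dst0 + vox(0, y, z, nx, ny);
              for (int xo = xo_lo; xo <= xo_hi; ++xo)
                dst[xo * stride + off] += src[xo];
            }
          }
        }
  return out;
}

static void neighbor_offsets(int connectivity, std::vector<int>& dx,
                             std::vector<int>& dy, std::vector<int>& dz) {
  for (int z = -1; z <= 1; ++z)
    for (int y = -1; y <= 1; ++y)
      for (int x = -1; x <= 1; ++x) {
        const int m = std::abs(x) + std::abs(y) + std::abs(z);
        if (m == 0) continue;
        const bool keep = (connectivity == 26) ||
                          (connectivity == 18 && m <= 2) ||
                          (connectivity == 6 && m == 1);
        if (keep) { dx.push_back(x); dy.push_back(y); dz.push_back(z); }
      }
}

// Connected-component labelling of a binary mask; labels 1..n in
// first-encounter (column-major scan) order, 0 elsewhere.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  const int noff = (int)dx.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back(); stack.pop_back();
      const int cz = (int)(cur / ((R_xlen_t)nx * ny));
      const int rem = (int)(cur % ((R_xlen_t)nx * ny));
      const int cy = rem / nx, cx = rem % nx;
      for (int o = 0; o < noff; ++o) {
        const int x = cx + dx[o], y = cy + dy[o], z = cz + dz[o];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        const R_xlen_t j = vox(x, y, z, nx, ny);
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// 1D lower-envelope squared distance transform (Felzenszwalb & Huttenlocher),
// sample positions i*sp, in place on f (length n) using work arrays.
static void dt1d(std::vector<double>& f, int n, double sp,
                 std::vector<int>& v, std::vector<double>& zr,
                 std::vector<double>& out) {
  const double INF = std::numeric_limits<double>::infinity();
  int kk = 0;
  v[0] = 0;
  zr[0] = -INF;
  zr[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[kk]] == INF) { v[kk] = q; continue; }
    double s;
    while (true) {
      const double pq = q * sp, pv = v[kk] * sp;
      s = ((f[q] + pq * pq) - (f[v[kk]] + pv * pv)) / (2 * pq - 2 * pv);
      if (s <= zr[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    zr[kk] = s;
    zr[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    const double pq = q * sp;
    while (zr[kk + 1] < pq) ++kk;
    const double d = pq - v[kk] * sp;
    out[q] = (f[v[kk]] == INF) ? INF : d * d + f[v[kk]];
  }
  for (int q = 0; q < n; ++q) f[q] = out[q];
}

// Exact squared Euclidean distance (mm^2) from every voxel to the nearest
// TRUE voxel, with anisotropic spacing. Inf where the mask is empty.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? 0.0 : INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), zr(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[vox(x, y, z, nx, ny)];
      dt1d(f, nx, spacing[0], v, zr, out);
      for (int x = 0; x < nx; ++x) d[vox(x, y, z, nx, ny)] = f[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = d[vox(x, y, z, nx, ny)];
      dt1d(f, ny, spacing[1], v, zr, out);
      for (int y = 0; y < ny; ++y) d[vox(x, y, z, nx, ny)] = f[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = d[vox(x, y, z, nx, ny)];
      dt1d(f, nz, spacing[2], v, zr, out);
      for (int z = 0; z < nz; ++z) d[vox(x, y, z, nx, ny)] = f[z];
    }
  return d;
}

// Binary dilation by an explicit list of integer offsets (rows: dx,dy,dz).
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dims,
                         IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  const int noff = offsets.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    const int cz = (int)(i / ((R_xlen_t)nx * ny));
    const int rem = (int)(i % ((R_xlen_t)nx * ny));
    const int cy = rem / nx, cx = rem % nx;
    for (int o = 0; o < noff; ++o) {
      const int x = cx + offsets(o, 0), y = cy + offsets(o, 1),
                z = cz + offsets(o, 2);
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      out[vox(x, y, z, nx, ny)] = true;
    }
  }
  return out;
}

// Surface voxels: mask voxels with at least one 6-neighbour outside the
// mask (voxels beyond the image edge count as outside).
// [[Rcpp::export]]
LogicalVector cpp_surface(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  static const int ox[6] = {1, -1, 0, 0, 0, 0};
  static const int oy[6] = {0, 0, 1, -1, 0, 0};
  static const int oz[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    const int cz = (int)(i / ((R_xlen_t)nx * ny));
    const int rem = (int)(i % ((R_xlen_t)nx * ny));
    const int cy = rem / nx, cx = rem % nx;
    for (int o = 0; o < 6; ++o) {
      const int x = cx + ox[o], y = cy + oy[o], z = cz + oz[o];
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz ||
          !mask[vox(x, y, z, nx, ny)]) {
        out[i] = true;
        break;
      }
    }
  }
  return out;
}

// ---- direct convolution (no im2col temporaries) ---------------------------
// Weight layout matches an R array dim (k,k,k,Cin,Cout), column-major.

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dims,
                             NumericVector W, NumericVector b,
                             int k, int stride, int pad, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int ox = (nx + 2 * pad - k) / stride + 1;
  const int oy = (ny + 2 * pad - k) / stride + 1;
  const int oz = (nz + 2 * pad - k) / stride + 1;
  const R_xlen_t N = (R_xlen_t)ox * oy * oz;
  const R_xlen_t plane = (R_xlen_t)nx * ny * nz;
  NumericVector yv(N * cout);
  double* py = yv.begin();
  const double* px = x.begin();
  const double* pw = W.begin();
  for (int co = 0; co < cout; ++co) {
    double* yc = py + co * N;
    const double bc = b[co];
    for (R_xlen_t i = 0; i < N; ++i) yc[i] = bc;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xc = px + ci * plane;
      for (int kz = 0; kz < k; ++kz)
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx) {
            const double w =
              pw[kx + k * (ky + (R_xlen_t)k * (kz + k * (ci + (R_xlen_t)cin * co)))];
            const int off = kx - pad;
            int xo_lo = (off < 0) ? ((-off + stride - 1) / stride) : 0;
            int xo_hi = (nx - 1 - off) / stride;
            if (xo_hi > ox - 1) xo_hi = ox - 1;
            if (xo_lo > xo_hi) continue;
            for (int zo = 0; zo < oz; ++zo) {
              const int z = zo * stride + kz - pad;
              if (z < 0 || z >= nz) continue;
              for (int yo = 0; yo < oy; ++yo) {
                const int y = yo * stride + ky - pad;
                if (y < 0 || y >= ny) continue;
                double* dst = yc + (R_xlen_t)ox * (yo + (R_xlen_t)oy * zo);
                const double* src = xc + vox(0, y, z, nx, ny);
                if (stride == 1) {
                  const double* s = src + off;
                  for (int xo = xo_lo; xo <= xo_hi; ++xo)
                    dst[xo] += w * s[xo];
                } else {
                  for (int xo = xo_lo; xo <= xo_hi; ++xo)
                    dst[xo] += w * src[xo * stride + off];
                }
              }
            }
          }
    }
  }
  return yv;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_input(NumericVector dy, IntegerVector dims,
                                   NumericVector W, int k, int stride,
                                   int pad, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int ox = (nx + 2 * pad - k) / stride + 1;
  const int oy = (ny + 2 * pad - k) / stride + 1;
  const int oz = (nz + 2 * pad - k) / stride + 1;
  const R_xlen_t N = (R_xlen_t)ox * oy * oz;
  const R_xlen_t plane = (R_xlen_t)nx * ny * nz;
  NumericVector dxv(plane * cin);
  double* pdx = dxv.begin();
  const double* pdy = dy.begin();
  const double* pw = W.begin();
  for (int co = 0; co < cout; ++co) {
    const double* dyc = pdy + co * N;
    for (int ci = 0; ci < cin; ++ci) {
      double* dxc = pdx + ci * plane;
      for (int kz = 0; kz < k; ++kz)
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx) {
            const double w =
              pw[kx + k * (ky + (R_xlen_t)k * (kz + k * (ci + (R_xlen_t)cin * co)))];
            const int off = kx - pad;
            int xo_lo = (off < 0) ? ((-off + stride - 1) / stride) : 0;
            int xo_hi = (nx - 1 - off) / stride;
            if (xo_hi > ox - 1) xo_hi = ox - 1;
            if (xo_lo > xo_hi) continue;
            for (int zo = 0; zo < oz; ++zo) {
              const int z = zo * stride + kz - pad;
              if (z < 0 || z >= nz) continue;
              for (int yo = 0; yo < oy; ++yo) {
                const int y = yo * stride + ky - pad;
                if (y < 0 || y >= ny) continue;
                const double* src =
                  dyc + (R_xlen_t)ox * (yo + (R_xlen_t)oy * zo);
                double* dst = dxc + vox(0, y, z, nx, ny);
                if (stride == 1) {
                  double* d = dst + off;
                  for (int xo = xo_lo; xo <= xo_hi; ++xo)
                    d[xo] += w * src[xo];
                } else {
                  for (int xo = xo_lo; xo <= xo_hi; ++xo)
                    dst[xo * stride + off] += w * src[xo];
                }
              }
            }
          }
    }
  }
  return dxv;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_weight(NumericVector x, NumericVector dy,
                                    IntegerVector dims, int k, int stride,
                                    int pad, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int ox = (nx + 2 * pad - k) / stride + 1;
  const int oy = (ny + 2 * pad - k) / stride + 1;
  const int oz = (nz + 2 * pad - k) / stride + 1;
  const R_xlen_t N = (R_xlen_t)ox * oy * oz;
  const R_xlen_t plane = (R_xlen_t)nx * ny * nz;
  NumericVector dW((R_xlen_t)k * k * k * cin * cout);
  double* pdw = dW.begin();
  const double* px = x.begin();
  const double* pdy = dy.begin();
  for (int co = 0; co < cout; ++co) {
    const double* dyc = pdy + co * N;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xc = px + ci * plane;
      for (int kz = 0; kz < k; ++kz)
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx) {
            const int off = kx - pad;
            int xo_lo = (off < 0) ? ((-off + stride - 1) / stride) : 0;
            int xo_hi = (nx - 1 - off) / stride;
            if (xo_hi > ox - 1) xo_hi = ox - 1;
            if (xo_lo > xo_hi) continue;
            double acc = 0.0;
            for (int zo = 0; zo < oz; ++zo) {
              const int z = zo * stride + kz - pad;
              if (z < 0 || z >= nz) continue;
              for (int yo = 0; yo < oy; ++yo) {
                const int y = yo * stride + ky - pad;
                if (y < 0 || y >= ny) continue;
                const double* src =
                  dyc + (R_xlen_t)ox * (yo + (R_xlen_t)oy * zo);
                const double* xs = xc + vox(0, y, z, nx, ny);
                if (stride == 1) {
                  const double* s = xs + off;
                  for (int xo = xo_lo; xo <= xo_hi; ++xo)
                    acc += s[xo] * src[xo];
                } else {
                  for (int xo = xo_lo; xo <= xo_hi; ++xo)
                    acc += xs[xo * stride + off] * src[xo];
                }
              }
            }
            pdw[kx + k * (ky + (R_xlen_t)k * (kz + k * (ci + (R_xlen_t)cin * co)))] = acc;
          }
    }
  }
  return dW;
}

// Nearest-neighbour 2x upsampling of an (nx,ny,nz,C) array.
// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const R_xlen_t plane = (R_xlen_t)nx * ny * nz;
  const R_xlen_t oplane = plane * 8;
  NumericVector out(oplane * C);
  const double* px = x.begin();
  double* po = out.begin();
  const int ox = 2 * nx, oy2 = 2 * ny;
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const double* src = px + c * plane + vox(0, y, z, nx, ny);
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy) {
            double* dst = po + c * oplane +
              (R_xlen_t)(2 * z + dz) * ox * oy2 + (R_xlen_t)(2 * y + dy) * ox;
            for (int xx = 0; xx < nx; ++xx) {
              dst[2 * xx] = src[xx];
              dst[2 * xx + 1] = src[xx];
            }
          }
      }
  return out;
}

// Adjoint: sum each 2x2x2 block of dy into the coarse grid.
// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy, IntegerVector odims) {
  const int ox = odims[0], oy = odims[1], oz = odims[2], C = odims[3];
  const int nx = ox / 2, ny = oy / 2, nz = oz / 2;
  const R_xlen_t plane = (R_xlen_t)nx * ny * nz;
  const R_xlen_t oplane = (R_xlen_t)ox * oy * oz;
  NumericVector out(plane * C);
  const double* pd = dy.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        double* dst = po + c * plane + vox(0, y, z, nx, ny);
        for (int dz = 0; dz < 2; ++dz)
          for (int dyi = 0; dyi < 2; ++dyi) {
            const double* src = pd + c * oplane +
              (R_xlen_t)(2 * z + dz) * ox * oy + (R_xlen_t)(2 * y + dyi) * ox;
            for (int xx = 0; xx < nx; ++xx)
              dst[xx] += src[2 * xx] + src[2 * xx + 1];
          }
      }
  return out;
}
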