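// Numerical kernels: 3D convolution (im2col + GEMM), pooling/upsampling,
// and an anisotropic squared Euclidean distance transform.
// Array layout follows R: column-major, dims (nx, ny, nz, channels).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& nx, int& ny, int& nz, int& nc) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4D array (x, y, z, channel)");
  nx = d[0]; ny = d[1]; nz = d[2]; nc = d[3];
}

// Build the im2col matrix: rows = voxels (column-major order), columns
// indexed as c * k^3 + (kz * k + ky) * k + kx.  Zero padding keeps 'same'
// output size; pad = (k - 1) / 2 * dilation, k odd.
static arma::mat im2col3(const double* x, int nx, int ny, int nz, int nc,
                         int k, int dil) {
  const int k3 = k * k * k;
  const int pad = (k - 1) / 2 * dil;
  const arma::uword N = (arma::uword)nx * ny * nz;
  arma::mat col(N, (arma::uword)k3 * nc, arma::fill::zeros);
  const size_t plane = (size_t)nx * ny, vol = plane * nz;
  for (int c = 0; c < nc; ++c) {
    const double* xc = x + (size_t)c * vol;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const arma::uword jcol = (arma::uword)c * k3 + (kz * k + ky) * k + kx;
          double* dst = col.colptr(jcol);
          const int ox = kx * dil - pad, oy = ky * dil - pad, oz = kz * dil - pad;
          const int z0 = std::max(0, -oz), z1 = std::min(nz, nz - oz);
          const int y0 = std::max(0, -oy), y1 = std::min(ny, ny - oy);
          const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
          for (int z = z0; z < z1; ++z) {
            for (int y = y0; y < y1; ++y) {
              const double* src = xc + (size_t)(z + oz) * plane + (size_t)(y + oy) * nx + (x0 + ox);
              double* d = dst + (size_t)z * plane + (size_t)y * nx + x0;
              std::copy(src, src + (x1 - x0), d);
            }
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add of a column matrix back onto the input grid (adjoint of im2col3).
static void col2im3(const arma::mat& col, double* dx, int nx, int ny, int nz, int nc,
                    int k, int dil) {
  const int k3 = k * k * k;
  const int pad = (k - 1) / 2 * dil;
  const size_t plane = (size_t)nx * ny, vol = plane * nz;
  for (int c = 0; c < nc; ++c) {
    double* xc = dx + (size_t)c * vol;
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const arma::uword jcol = (arma::uword)c * k3 + (kz * k + ky) * k + kx;
          const double* src0 = col.colptr(jcol);
          const int ox = kx * dil - pad, oy = ky * dil - pad, oz = kz * dil - pad;
          const int z0 = std::max(0, -oz), z1 = std::min(nz, nz - oz);
          const int y0 = std::max(0, -oy), y1 = std::min(ny, ny - oy);
          const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
          for (int z = z0; z < z1; ++z) {
            for (int y = y0; y < y1; ++y) {
              double* dst = xc + (size_t)(z + oz) * plane + (size_t)(y + oy) * nx + (x0 + ox);
              const double* s = src0 + (size_t)z * plane + (size_t)y * nx + x0;
              for (int i = 0; i < x1 - x0; ++i) dst[i] += s[i];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward(NumericVector x, NumericMatrix w, NumericVector b,
                             int k, int dilation) {
  int nx, ny, nz, nc;
  get_dims4(x, nx, ny, nz, nc);
  const int k3 = k * k * k;
  if ((int)w.nrow() != k3 * nc) stop("weight rows must equal k^3 * in_channels");
  const int cout = w.ncol();
  if (b.size() != cout) stop("bias length must equal out_channels");
  const arma::uword N = (arma::uword)nx * ny * nz;
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat out;
  if (k == 1) {  // pointwise conv: the input matrix is its own im2col
    arma::mat X(REAL(x), N, nc, false);
    out = X * W;
  } else {
    arma::mat col = im2col3(REAL(x), nx, ny, nz, nc, k, dilation);
    out = col * W;
  }
  out.each_row() += arma::rowvec(b.begin(), cout, false);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return res;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward(NumericVector x, NumericMatrix w, NumericVector gout,
                     int k, int dilation) {
  int nx, ny, nz, nc;
  get_dims4(x, nx, ny, nz, nc);
  int gx, gy, gz, cout;
  get_dims4(gout, gx, gy, gz, cout);
  if (gx != nx || gy != ny || gz != nz) stop("gradient grid mismatch");
  const arma::uword N = (arma::uword)nx * ny * nz;
  arma::mat G(REAL(gout), N, cout, false);
  arma::mat W(w.begin(), w.nrow(), w.ncol(), false);
  arma::rowvec db = arma::sum(G, 0);
  arma::mat dW;
  NumericVector dx(x.size());
  if (k == 1) {
    arma::mat X(REAL(x), N, nc, false);
    dW = X.t() * G;
    arma::mat DX(REAL(dx), N, nc, false, true);
    DX = G * W.t();
  } else {
    arma::mat col = im2col3(REAL(x), nx, ny, nz, nc, k, dilation);
    dW = col.t() * G;
    arma::mat dcol = G * W.t();
    col2im3(dcol, REAL(dx), nx, ny, nz, nc, k, dilation);
  }
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return List::create(_["dx"] = dx,
                      _["dw"] = NumericMatrix(dW.n_rows, dW.n_cols, dW.begin()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Average pooling with factor 2 along each spatial axis (dims must be even).
// [[Rcpp::export(name = ".avgpool2_forward")]]
NumericVector avgpool2_forward(NumericVector x) {
  int nx, ny, nz, nc;
  get_dims4(x, nx, ny, nz, nc);
  if (nx % 2 || ny % 2 || nz % 2) stop("pooled dims must be even");
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  NumericVector out((size_t)mx * my * mz * nc);
  const double* xp = REAL(x);
  double* op = REAL(out);
  const size_t plane = (size_t)nx * ny, vol = plane * nz;
  const size_t oplane = (size_t)mx * my, ovol = oplane * mz;
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y)
        for (int xi = 0; xi < mx; ++xi) {
          double s = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dxi = 0; dxi < 2; ++dxi)
                s += xp[(size_t)c * vol + (size_t)(2 * z + dz) * plane +
                        (size_t)(2 * y + dy) * nx + (2 * xi + dxi)];
          op[(size_t)c * ovol + (size_t)z * oplane + (size_t)y * mx + xi] = s / 8.0;
        }
  out.attr("dim") = IntegerVector::create(mx, my, mz, nc);
  return out;
}

// [[Rcpp::export(name = ".avgpool2_backward")]]
NumericVector avgpool2_backward(NumericVector gout, IntegerVector in_dim) {
  int mx, my, mz, nc;
  get_dims4(gout, mx, my, mz, nc);
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  NumericVector dx((size_t)nx * ny * nz * nc);
  const double* gp = REAL(gout);
  double* dp = REAL(dx);
  const size_t plane = (size_t)nx * ny, vol = plane * nz;
  const size_t oplane = (size_t)mx * my, ovol = oplane * mz;
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y)
        for (int xi = 0; xi < mx; ++xi) {
          const double g = gp[(size_t)c * ovol + (size_t)z * oplane + (size_t)y * mx + xi] / 8.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dxi = 0; dxi < 2; ++dxi)
                dp[(size_t)c * vol + (size_t)(2 * z + dz) * plane +
                   (size_t)(2 * y + dy) * nx + (2 * xi + dxi)] += g;
        }
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return dx;
}

// Nearest-neighbour upsampling by factor 2.
// [[Rcpp::export(name = ".upsample2_forward")]]
NumericVector upsample2_forward(NumericVector x) {
  int mx, my, mz, nc;
  get_dims4(x, mx, my, mz, nc);
  const int nx = 2 * mx, ny = 2 * my, nz = 2 * mz;
  NumericVector out((size_t)nx * ny * nz * nc);
  const double* xp = REAL(x);
  double* op = REAL(out);
  const size_t plane = (size_t)nx * ny, vol = plane * nz;
  const size_t iplane = (size_t)mx * my, ivol = iplane * mz;
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int xi = 0; xi < nx; ++xi)
          op[(size_t)c * vol + (size_t)z * plane + (size_t)y * nx + xi] =
            xp[(size_t)c * ivol + (size_t)(z / 2) * iplane + (size_t)(y / 2) * mx + xi / 2];
  out.attr("dim") = IntegerVector::create(nx, ny, nz, nc);
  return out;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
NumericVector upsample2_backward(NumericVector gout) {
  int nx, ny, nz, nc;
  get_dims4(gout, nx, ny, nz, nc);
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  NumericVector dx((size_t)mx * my * mz * nc);
  const double* gp = REAL(gout);
  double* dp = REAL(dx);
  const size_t plane = (size_t)nx * ny, vol = plane * nz;
  const size_t iplane = (size_t)mx * my, ivol = iplane * mz;
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int xi = 0; xi < nx; ++xi)
          dp[(size_t)c * ivol + (size_t)(z / 2) * iplane + (size_t)(y / 2) * mx + xi / 2] +=
            gp[(size_t)c * vol + (size_t)z * plane + (size_t)y * nx + xi];
  dx.attr("dim") = IntegerVector::create(mx, my, mz, nc);
  return dx;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), sample
// spacing s.  f holds squared distances; writes the transform back to f.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb, int n, double s) {
  const double s2 = s * s;
  int kk = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double sp;
    while (true) {
      const int p = v[kk];
      sp = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sp <= zb[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    zb[kk] = sp;
    zb[kk + 1] = INFINITY;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[kk + 1] < q) ++kk;
    const double dq = s * (q - v[kk]);
    d[q] = dq * dq + f[v[kk]];
  }
  std::copy(d.begin(), d.begin() + n, f.begin());
}

// Euclidean distance (mm) from every voxel to the nearest voxel where
// mask != 0, honouring anisotropic spacing.  Empty mask -> all Inf.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(NumericVector mask, NumericVector spacing) {
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("expected a 3D mask");
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector out((size_t)nx * ny * nz);
  double* o = REAL(out);
  const double* m = REAL(mask);
  const size_t N = (size_t)nx * ny * nz;
  const double BIG = 1e20;  // finite sentinel: Inf breaks the parabola intersections
  for (size_t i = 0; i < N; ++i) o[i] = (m[i] != 0.0) ? 0.0 : BIG;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  const size_t plane = (size_t)nx * ny;
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double* row = o + (size_t)z * plane + (size_t)y * nx;
      std::copy(row, row + nx, f.begin());
      dt1d(f, d, v, zb, nx, sx);
      std::copy(f.begin(), f.begin() + nx, row);
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = o[(size_t)z * plane + (size_t)y * nx + x];
      dt1d(f, d, v, zb, ny, sy);
      for (int y = 0; y < ny; ++y) o[(size_t)z * plane + (size_t)y * nx + x] = f[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = o[(size_t)z * plane + (size_t)y * nx + x];
      dt1d(f, d, v, zb, nz, sz);
      for (int z = 0; z < nz; ++z) o[(size_t)z * plane + (size_t)y * nx + x] = f[z];
    }
  for (size_t i = 0; i < N; ++i) o[i] = (o[i] >= 1e18) ? R_PosInf : std::sqrt(o[i]);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}
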