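// Low-level voxel-grid kernels. Feature maps are (nvox, C) matrices with
// column-major voxel linearization i = x + nx*(y + ny*z), matching R arrays.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Build the im2col matrix (nvox_out, 27*C) for a 3x3x3 kernel, zero padding
// 1, given stride; column index o + 27*c with o = ox + 3*(oy + 3*oz).
// Contiguous x-runs are copied with memcpy for stride 1. Convolutions are
// computed in single precision: the networks are trained with noisy
// stochastic gradients, and halving the memory traffic roughly doubles
// throughput of this memory-bound step.
// Writes the im2col block of one sample (rows [xrow0, xrow0+nvox) of x)
// into rows [orow0, orow0+nout) of the preallocated output matrix.
template <typename MT>
static void im2col3_block(const MT& x, size_t xrow0, int nx, int ny, int nz,
                          int stride, MT& out, size_t orow0) {
  typedef typename MT::elem_type eT;
  const int C = x.n_cols;
  const int ox = (nx + stride - 1) / stride;
  const int oy = (ny + stride - 1) / stride;
  for (int c = 0; c < C; ++c) {
    const eT* col = x.colptr(c) + xrow0;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int o = (kx + 1) + 3 * ((ky + 1) + 3 * (kz + 1));
          eT* dst = out.colptr(o + 27 * c) + orow0;
          const int x0 = std::max(0, -kx), x1 = std::min(nx - 1, nx - 1 - kx);
          size_t zrow = 0;
          for (int z = 0; z < nz; z += stride, zrow += oy) {
            const int sz = z + kz;
            if (sz < 0 || sz >= nz) continue;
            size_t r0 = zrow * ox;
            for (int y = 0; y < ny; y += stride, r0 += ox) {
              const int sy = y + ky;
              if (sy < 0 || sy >= ny) continue;
              const eT* src = col + lin(0, sy, sz, nx, ny);
              if (stride == 1) {
                if (x1 >= x0)
                  std::memcpy(dst + r0 + x0, src + x0 + kx,
                              (x1 - x0 + 1) * sizeof(eT));
              } else {
                size_t r = r0;
                for (int xg = 0; xg < nx; xg += stride, ++r) {
                  const int sx = xg + kx;
                  if (sx >= 0 && sx < nx) dst[r] = src[sx];
                }
              }
            }
          }
        }
  }
}

// Scatter rows [grow0, grow0+nout) of the column gradient back onto rows
// [drow0, drow0+nvox) of dx (adds in place; dx must be zeroed beforehand).
template <typename MT>
static void col2im3_scatter(const MT& dxc, size_t grow0, int nx, int ny, int nz,
                            int stride, int C, MT& dx, size_t drow0) {
  typedef typename MT::elem_type eT;
  const int ox = (nx + stride - 1) / stride;
  const int oy = (ny + stride - 1) / stride;
  for (int c = 0; c < C; ++c) {
    eT* dst = dx.colptr(c) + drow0;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int o = (kx + 1) + 3 * ((ky + 1) + 3 * (kz + 1));
          const eT* src = dxc.colptr(o + 27 * c) + grow0;
          size_t zrow = 0;
          for (int z = 0; z < nz; z += stride, zrow += oy) {
            const int sz = z + kz;
            if (sz < 0 || sz >= nz) continue;
            size_t r0 = zrow * ox;
            for (int y = 0; y < ny; y += stride, r0 += ox) {
              const int sy = y + ky;
              if (sy < 0 || sy >= ny) continue;
              eT* drow = dst + lin(0, sy, sz, nx, ny);
              size_t r = r0;
              for (int xg = 0; xg < nx; xg += stride, ++r) {
                const int sx = xg + kx;
                if (sx >= 0 && sx < nx) drow[sx] += src[r];
              }
            }
          }
        }
  }
}

// Convolution over B stacked samples, processed one sample at a time so the
// im2col buffer stays cache-resident; the buffer is reused across samples.
template <typename MT>
static void conv3_fwd_batched(const MT& x, int nx, int ny, int nz, int stride,
                              int B, const MT& W,
                              const arma::Row<typename MT::elem_type>& b,
                              MT& y) {
  const size_t nin = static_cast<size_t>(nx) * ny * nz;
  const int ox = (nx + stride - 1) / stride;
  const int oy = (ny + stride - 1) / stride;
  const int oz = (nz + stride - 1) / stride;
  const size_t nout = static_cast<size_t>(ox) * oy * oz;
  y.set_size(nout * B, W.n_cols);
  MT xc(nout, 27 * x.n_cols);
  for (int bi = 0; bi < B; ++bi) {
    xc.zeros();
    im2col3_block(x, bi * nin, nx, ny, nz, stride, xc, 0);
    MT yb = xc * W;
    yb.each_row() += b;
    y.rows(bi * nout, (bi + 1) * nout - 1) = yb;
  }
}

template <typename MT>
static void conv3_bwd_batched(const MT& x, const MT& dy, int nx, int ny, int nz,
                              int stride, int B, const MT& W, bool need_dx,
                              MT& dW, arma::Row<typename MT::elem_type>& db,
                              MT& dx) {
  const size_t nin = static_cast<size_t>(nx) * ny * nz;
  const int ox = (nx + stride - 1) / stride;
  const int oy = (ny + stride - 1) / stride;
  const int oz = (nz + stride - 1) / stride;
  const size_t nout = static_cast<size_t>(ox) * oy * oz;
  const int C = x.n_cols;
  dW.zeros(27 * C, W.n_cols);
  db = arma::sum(dy, 0);
  if (need_dx) dx.zeros(nin * B, C);
  MT xc(nout, 27 * C);
  for (int bi = 0; bi < B; ++bi) {
    xc.zeros();
    im2col3_block(x, bi * nin, nx, ny, nz, stride, xc, 0);
    MT dyb = dy.rows(bi * nout, (bi + 1) * nout - 1);
    dW += xc.t() * dyb;
    if (need_dx) {
      MT dxc = dyb * W.t();
      col2im3_scatter(dxc, 0, nx, ny, nz, stride, C, dx, bi * nin);
    }
  }
}

// Fused convolution forward: y = im2col(x) * W + b for B stacked samples.
// `single` selects the fast single-precision path; the double path exists
// for exact checks.
// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat& x, IntegerVector dims,
                        const arma::mat& W, const arma::vec& b, int stride,
                        bool single, int B) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (single) {
    arma::fmat xf = arma::conv_to<arma::fmat>::from(x);
    arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
    arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b.t());
    arma::fmat yf;
    conv3_fwd_batched(xf, nx, ny, nz, stride, B, Wf, bf, yf);
    return arma::conv_to<arma::mat>::from(yf);
  }
  arma::rowvec br = b.t();
  arma::mat y;
  conv3_fwd_batched(x, nx, ny, nz, stride, B, W, br, y);
  return y;
}

// Fused convolution backward: recomputes the im2col matrix and returns
// dW = xc' dy, db = colsums(dy) and (optionally) dx = col2im(dy W').
// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::mat& x, IntegerVector dims, const arma::mat& W,
                   const arma::mat& dy, int stride, bool need_dx, bool single,
                   int B) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (single) {
    arma::fmat xf = arma::conv_to<arma::fmat>::from(x);
    arma::fmat dyf = arma::conv_to<arma::fmat>::from(dy);
    arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
    arma::fmat dW, dx;
    arma::frowvec db;
    conv3_bwd_batched(xf, dyf, nx, ny, nz, stride, B, Wf, need_dx, dW, db, dx);
    List out = List::create(
      _["dW"] = arma::conv_to<arma::mat>::from(dW),
      _["db"] = arma::conv_to<arma::rowvec>::from(db));
    if (need_dx) out["dx"] = arma::conv_to<arma::mat>::from(dx);
    return out;
  }
  arma::mat dW, dx;
  arma::rowvec db;
  conv3_bwd_batched(x, dy, nx, ny, nz, stride, B, W, need_dx, dW, db, dx);
  List out = List::create(_["dW"] = dW, _["db"] = db);
  if (need_dx) out["dx"] = dx;
  return out;
}

struct TrilinWeights {
  int i0[3], i1[3];
  double w0[3], w1[3];
};

static inline TrilinWeights trilin_setup(const double* u, const int* n) {
  TrilinWeights t;
  for (int a = 0; a < 3; ++a) {
    double ua = u[a];
    if (ua < 0) ua = 0;
    if (ua > n[a] - 1) ua = n[a] - 1;
    int i0 = static_cast<int>(std::floor(ua));
    if (i0 > n[a] - 2) i0 = n[a] > 1 ? n[a] - 2 : 0;
    int i1 = n[a] > 1 ? i0 + 1 : i0;
    double f = ua - i0;
    t.i0[a] = i0; t.i1[a] = i1; t.w1[a] = f; t.w0[a] = 1.0 - f;
  }
  return t;
}

// Trilinear resampling between two grids sharing the same physical center.
// Voxel centers along axis a sit at (i + 0.5)*spacing[a] - extent[a]/2.
// B stacked samples are resampled independently.
// [[Rcpp::export]]
arma::mat cpp_resample3(const arma::mat& x, IntegerVector dims_src, NumericVector sp_src,
                        IntegerVector dims_dst, NumericVector sp_dst, int B) {
  if (B > 1) {
    const size_t nin = static_cast<size_t>(dims_src[0]) * dims_src[1] * dims_src[2];
    const size_t nout = static_cast<size_t>(dims_dst[0]) * dims_dst[1] * dims_dst[2];
    arma::mat out(nout * B, x.n_cols);
    for (int bi = 0; bi < B; ++bi)
      out.rows(bi * nout, (bi + 1) * nout - 1) =
        cpp_resample3(x.rows(bi * nin, (bi + 1) * nin - 1), dims_src, sp_src,
                      dims_dst, sp_dst, 1);
    return out;
  }
  const int ns[3] = {dims_src[0], dims_src[1], dims_src[2]};
  const int nd[3] = {dims_dst[0], dims_dst[1], dims_dst[2]};
  const int C = x.n_cols;
  arma::mat out(static_cast<size_t>(nd[0]) * nd[1] * nd[2], C, arma::fill::zeros);
  double off[3];
  for (int a = 0; a < 3; ++a)
    off[a] = 0.5 * (ns[a] * sp_src[a] - nd[a] * sp_dst[a]);
  size_t r = 0;
  for (int z = 0; z < nd[2]; ++z)
    for (int y = 0; y < nd[1]; ++y)
      for (int xg = 0; xg < nd[0]; ++xg, ++r) {
        const int idx[3] = {xg, y, z};
        double u[3];
        for (int a = 0; a < 3; ++a)
          u[a] = ((idx[a] + 0.5) * sp_dst[a] + off[a]) / sp_src[a] - 0.5;
        TrilinWeights t = trilin_setup(u, ns);
        const int corners[8][3] = {
          {t.i0[0], t.i0[1], t.i0[2]}, {t.i1[0], t.i0[1], t.i0[2]},
          {t.i0[0], t.i1[1], t.i0[2]}, {t.i1[0], t.i1[1], t.i0[2]},
          {t.i0[0], t.i0[1], t.i1[2]}, {t.i1[0], t.i0[1], t.i1[2]},
          {t.i0[0], t.i1[1], t.i1[2]}, {t.i1[0], t.i1[1], t.i1[2]}};
        const double wts[8] = {
          t.w0[0]*t.w0[1]*t.w0[2], t.w1[0]*t.w0[1]*t.w0[2],
          t.w0[0]*t.w1[1]*t.w0[2], t.w1[0]*t.w1[1]*t.w0[2],
          t.w0[0]*t.w0[1]*t.w1[2], t.w1[0]*t.w0[1]*t.w1[2],
          t.w0[0]*t.w1[1]*t.w1[2], t.w1[0]*t.w1[1]*t.w1[2]};
        for (int k = 0; k < 8; ++k) {
          if (wts[k] == 0.0) continue;
          const size_t s = lin(corners[k][0], corners[k][1], corners[k][2], ns[0], ns[1]);
          for (int c = 0; c < C; ++c) out(r, c) += wts[k] * x(s, c);
        }
      }
  return out;
}

// Adjoint of cpp_resample3 (same weights, scatter instead of gather).
// [[Rcpp::export]]
arma::mat cpp_resample3_adj(const arma::mat& g, IntegerVector dims_src, NumericVector sp_src,
                            IntegerVector dims_dst, NumericVector sp_dst, int B) {
  if (B > 1) {
    const size_t nin = static_cast<size_t>(dims_src[0]) * dims_src[1] * dims_src[2];
    const size_t nout = static_cast<size_t>(dims_dst[0]) * dims_dst[1] * dims_dst[2];
    arma::mat out(nin * B, g.n_cols);
    for (int bi = 0; bi < B; ++bi)
      out.rows(bi * nin, (bi + 1) * nin - 1) =
        cpp_resample3_adj(g.rows(bi * nout, (bi + 1) * nout - 1), dims_src,
                          sp_src, dims_dst, sp_dst, 1);
    return out;
  }
  const int ns[3] = {dims_src[0], dims_src[1], dims_src[2]};
  const int nd[3] = {dims_dst[0], dims_dst[1], dims_dst[2]};
  const int C = g.n_cols;
  arma::mat out(static_cast<size_t>(ns[0]) * ns[1] * ns[2], C, arma::fill::zeros);
  double off[3];
  for (int a = 0; a < 3; ++a)
    off[a] = 0.5 * (ns[a] * sp_src[a] - nd[a] * sp_dst[a]);
  size_t r = 0;
  for (int z = 0; z < nd[2]; ++z)
    for (int y = 0; y < nd[1]; ++y)
      for (int xg = 0; xg < nd[0]; ++xg, ++r) {
        const int idx[3] = {xg, y, z};
        double u[3];
        for (int a = 0; a < 3; ++a)
          u[a] = ((idx[a] + 0.5) * sp_dst[a] + off[a]) / sp_src[a] - 0.5;
        TrilinWeights t = trilin_setup(u, ns);
        const int corners[8][3] = {
          {t.i0[0], t.i0[1], t.i0[2]}, {t.i1[0], t.i0[1], t.i0[2]},
          {t.i0[0], t.i1[1], t.i0[2]}, {t.i1[0], t.i1[1], t.i0[2]},
          {t.i0[0], t.i0[1], t.i1[2]}, {t.i1[0], t.i0[1], t.i1[2]},
          {t.i0[0], t.i1[1], t.i1[2]}, {t.i1[0], t.i1[1], t.i1[2]}};
        const double wts[8] = {
          t.w0[0]*t.w0[1]*t.w0[2], t.w1[0]*t.w0[1]*t.w0[2],
          t.w0[0]*t.w1[1]*t.w0[2], t.w1[0]*t.w1[1]*t.w0[2],
          t.w0[0]*t.w0[1]*t.w1[2], t.w1[0]*t.w0[1]*t.w1[2],
          t.w0[0]*t.w1[1]*t.w1[2], t.w1[0]*t.w1[1]*t.w1[2]};
        for (int k = 0; k < 8; ++k) {
          if (wts[k] == 0.0) continue;
          const size_t s = lin(corners[k][0], corners[k][1], corners[k][2], ns[0], ns[1]);
          for (int c = 0; c < C; ++c) out(s, c) += wts[k] * g(r, c);
        }
      }
  return out;
}

// Separable Gaussian smoothing (reflected boundaries), sigma in voxels per axis.
// [[Rcpp::export]]
arma::mat cpp_smooth3(const arma::mat& x, IntegerVector dims, NumericVector sigma) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  const int C = x.n_cols;
  arma::mat cur = x;
  for (int a = 0; a < 3; ++a) {
    const double s = sigma[a];
    if (s <= 0) continue;
    const int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * rad + 1);
    double ksum = 0;
    for (int i = -rad; i <= rad; ++i) { k[i + rad] = std::exp(-0.5 * i * i / (s * s)); ksum += k[i + rad]; }
    for (auto& v : k) v /= ksum;
    arma::mat nxt(cur.n_rows, C, arma::fill::zeros);
    for (int c = 0; c < C; ++c) {
      const double* src = cur.colptr(c);
      double* dst = nxt.colptr(c);
      for (int z = 0; z < n[2]; ++z)
        for (int y = 0; y < n[1]; ++y)
          for (int xg = 0; xg < n[0]; ++xg) {
            const int idx0[3] = {xg, y, z};
            double acc = 0;
            for (int i = -rad; i <= rad; ++i) {
              int idx[3] = {idx0[0], idx0[1], idx0[2]};
              int p = idx[a] + i;
              if (p < 0) p = -p - 1;
              if (p > n[a] - 1) p = 2 * n[a] - 1 - p;
              idx[a] = p;
              acc += k[i + rad] * src[lin(idx[0], idx[1], idx[2], n[0], n[1])];
            }
            dst[lin(idx0[0], idx0[1], idx0[2], n[0], n[1])] = acc;
          }
    }
    cur = nxt;
  }
  return cur;
}

// Eigendecomposition of a field of symmetric 3x3 matrices (rows of x, row-major
// 9 channels). Values returned in descending order.
// [[Rcpp::export]]
List cpp_sym_eig_field(const arma::mat& x) {
  const size_t n = x.n_rows;
  arma::mat vals(n, 3), vecs(n, 9);
  arma::mat33 M;
  arma::vec3 ev;
  arma::mat33 V;
  for (size_t i = 0; i < n; ++i) {
    M = {{x(i,0), x(i,1), x(i,2)}, {x(i,3), x(i,4), x(i,5)}, {x(i,6), x(i,7), x(i,8)}};
    M = 0.5 * (M + M.t());
    arma::eig_sym(ev, V, M);  // ascending
    for (int j = 0; j < 3; ++j) {
      vals(i, j) = ev(2 - j);
      for (int r = 0; r < 3; ++r) vecs(i, 3 * j + r) = V(r, 2 - j);
    }
  }
  return List::create(_["values"] = vals, _["vectors"] = vecs);
}

// Apply f to eigenvalues of each symmetric 3x3 row: mode 0 = log(clamp(., floor)),
// mode 1 = exp.
// [[Rcpp::export]]
arma::mat cpp_sym_func_field(const arma::mat& x, int mode, double eig_floor) {
  const size_t n = x.n_rows;
  arma::mat out(n, 9);
  arma::mat33 M, R;
  arma::vec3 ev;
  arma::mat33 V;
  for (size_t i = 0; i < n; ++i) {
    M = {{x(i,0), x(i,1), x(i,2)}, {x(i,3), x(i,4), x(i,5)}, {x(i,6), x(i,7), x(i,8)}};
    M = 0.5 * (M + M.t());
    arma::eig_sym(ev, V, M);
    for (int j = 0; j < 3; ++j) {
      double v = ev(j);
      if (mode == 0) v = std::log(std::max(v, eig_floor));
      else v = std::exp(v);
      ev(j) = v;
    }
    R = V * arma::diagmat(ev) * V.t();
    R = 0.5 * (R + R.t());
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) out(i, 3 * r + c) = R(r, c);
  }
  return out;
}

// 2x cube average pooling (dims must be even), B stacked samples.
// [[Rcpp::export]]
arma::mat cpp_avgpool2(const arma::mat& x, IntegerVector dims, int B) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (B > 1) {
    const size_t nin = static_cast<size_t>(nx) * ny * nz;
    const size_t nout = nin / 8;
    arma::mat out(nout * B, x.n_cols);
    for (int bi = 0; bi < B; ++bi)
      out.rows(bi * nout, (bi + 1) * nout - 1) =
        cpp_avgpool2(x.rows(bi * nin, (bi + 1) * nin - 1), dims, 1);
    return out;
  }
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const int C = x.n_cols;
  arma::mat out(static_cast<size_t>(ox) * oy * oz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = out.colptr(c);
    size_t r = 0;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xg = 0; xg < ox; ++xg, ++r) {
          double acc = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                acc += src[lin(2*xg+dx, 2*y+dy, 2*z+dz, nx, ny)];
          dst[r] = acc / 8.0;
        }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_avgpool2_adj(const arma::mat& g, IntegerVector dims, int B) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (B > 1) {
    const size_t nin = static_cast<size_t>(nx) * ny * nz;
    const size_t nout = nin / 8;
    arma::mat out(nin * B, g.n_cols);
    for (int bi = 0; bi < B; ++bi)
      out.rows(bi * nin, (bi + 1) * nin - 1) =
        cpp_avgpool2_adj(g.rows(bi * nout, (bi + 1) * nout - 1), dims, 1);
    return out;
  }
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const int C = g.n_cols;
  arma::mat out(static_cast<size_t>(nx) * ny * nz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = g.colptr(c);
    double* dst = out.colptr(c);
    size_t r = 0;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xg = 0; xg < ox; ++xg, ++r) {
          const double v = src[r] / 8.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                dst[lin(2*xg+dx, 2*y+dy, 2*z+dz, nx, ny)] += v;
        }
  }
  return out;
}

// Nearest-neighbor 2x upsampling and its adjoint, B stacked samples.
// [[Rcpp::export]]
arma::mat cpp_upsample2(const arma::mat& x, IntegerVector dims, int B) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (B > 1) {
    const size_t nin = static_cast<size_t>(nx) * ny * nz;
    const size_t nout = nin * 8;
    arma::mat out(nout * B, x.n_cols);
    for (int bi = 0; bi < B; ++bi)
      out.rows(bi * nout, (bi + 1) * nout - 1) =
        cpp_upsample2(x.rows(bi * nin, (bi + 1) * nin - 1), dims, 1);
    return out;
  }
  const int ox = nx * 2, oy = ny * 2, oz = nz * 2;
  const int C = x.n_cols;
  arma::mat out(static_cast<size_t>(ox) * oy * oz, C);
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    double* dst = out.colptr(c);
    size_t r = 0;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xg = 0; xg < ox; ++xg, ++r)
          dst[r] = src[lin(xg/2, y/2, z/2, nx, ny)];
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_upsample2_adj(const arma::mat& g, IntegerVector dims, int B) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (B > 1) {
    const size_t nin = static_cast<size_t>(nx) * ny * nz;
    const size_t nout = nin * 8;
    arma::mat out(nin * B, g.n_cols);
    for (int bi = 0; bi < B; ++bi)
      out.rows(bi * nin, (bi + 1) * nin - 1) =
        cpp_upsample2_adj(g.rows(bi * nout, (bi + 1) * nout - 1), dims, 1);
    return out;
  }
  const int ox = nx * 2, oy = ny * 2, oz = nz * 2;
  const int C = g.n_cols;
  arma::mat out(static_cast<size_t>(nx) * ny * nz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* src = g.colptr(c);
    double* dst = out.colptr(c);
    size_t r = 0;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int xg = 0; xg < ox; ++xg, ++r)
          dst[lin(xg/2, y/2, z/2, nx, ny)] += src[r];
  }
  return out;
}

static inline bool interp_dir(const arma::mat& logf, const int* n, const double* sp,
                              const double* p, double deg_tol, arma::vec3& dir) {
  double u[3];
  for (int a = 0; a < 3; ++a) {
    u[a] = p[a] / sp[a];
    if (u[a] < 0 || u[a] > n[a] - 1) return false;
  }
  TrilinWeights t = trilin_setup(u, n);
  double m[9] = {0,0,0,0,0,0,0,0,0};
  const int cx[2] = {t.i0[0], t.i1[0]}, cy[2] = {t.i0[1], t.i1[1]}, cz[2] = {t.i0[2], t.i1[2]};
  const double wx[2] = {t.w0[0], t.w1[0]}, wy[2] = {t.w0[1], t.w1[1]}, wz[2] = {t.w0[2], t.w1[2]};
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2; ++b)
      for (int c = 0; c < 2; ++c) {
        const double w = wx[a] * wy[b] * wz[c];
        if (w == 0) continue;
        const size_t s = lin(cx[a], cy[b], cz[c], n[0], n[1]);
        for (int k = 0; k < 9; ++k) m[k] += w * logf(s, k);
      }
  arma::mat33 M = {{m[0], m[1], m[2]}, {m[3], m[4], m[5]}, {m[6], m[7], m[8]}};
  M = 0.5 * (M + M.t());
  arma::vec3 ev;
  arma::mat33 V;
  arma::eig_sym(ev, V, M);
  // principal direction of exp(M) = eigenvector of largest eigenvalue of M
  const double l1 = std::exp(ev(2)), l2 = std::exp(ev(1));
  if (l1 <= 0 || (l1 - l2) / l1 < deg_tol) return false;
  dir = V.col(2);
  return true;
}

static inline bool peak_dir(const arma::mat& peaks, const int* n, const double* sp,
                            const double* p, const arma::vec3* prev, arma::vec3& dir) {
  int idx[3];
  for (int a = 0; a < 3; ++a) {
    const double u = p[a] / sp[a];
    if (u < -0.5 || u > n[a] - 0.5) return false;
    idx[a] = std::min(n[a] - 1, std::max(0, (int)std::lround(u)));
  }
  const size_t s = lin(idx[0], idx[1], idx[2], n[0], n[1]);
  const int npk = peaks.n_cols / 3;
  double best = -1;
  for (int k = 0; k < npk; ++k) {
    arma::vec3 v = {peaks(s, 3*k), peaks(s, 3*k+1), peaks(s, 3*k+2)};
    const double nv = arma::norm(v);
    if (!std::isfinite(nv) || nv < 1e-8) continue;
    v /= nv;
    double score = prev ? std::abs(arma::dot(v, *prev)) : (npk - k);  // first peak = strongest
    if (score > best) { best = score; dir = v; }
  }
  return best > 0;
}

// Deterministic streamline propagation. Seeds are world-mm points (voxel center
// i maps to world i*spacing). mode 0: DT (field = log-tensor, 9 channels),
// mode 1: discrete peaks (field = up to 3 peak vectors per voxel, NaN padded).
// [[Rcpp::export]]
List cpp_track(const arma::mat& field, IntegerVector dims, NumericVector spacing,
               const arma::uvec& mask, const arma::mat& seeds, int mode,
               double step, double max_angle_deg, double min_len, double max_len,
               double deg_tol) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double cos_thresh = std::cos(max_angle_deg * M_PI / 180.0);
  const int max_steps = (int)std::ceil(max_len / step) + 2;
  List out;
  for (size_t si = 0; si < seeds.n_rows; ++si) {
    double p0[3] = {seeds(si,0), seeds(si,1), seeds(si,2)};
    arma::vec3 d0;
    bool ok = (mode == 0) ? interp_dir(field, n, sp, p0, deg_tol, d0)
                          : peak_dir(field, n, sp, p0, nullptr, d0);
    if (!ok) continue;
    std::vector<arma::vec3> half[2];
    for (int h = 0; h < 2; ++h) {
      arma::vec3 d = (h == 0) ? d0 : arma::vec3(-d0);
      arma::vec3 p = {p0[0], p0[1], p0[2]};
      for (int stp = 0; stp < max_steps; ++stp) {
        arma::vec3 pn = p + step * d;
        // mask / grid check at the new point (nearest voxel)
        int vi[3];
        bool inside = true;
        for (int a = 0; a < 3; ++a) {
          const double u = pn(a) / sp[a];
          if (u < -0.5 || u > n[a] - 0.5) { inside = false; break; }
          vi[a] = std::min(n[a] - 1, std::max(0, (int)std::lround(u)));
        }
        if (!inside) break;
        if (!mask(lin(vi[0], vi[1], vi[2], n[0], n[1]))) break;
        half[h].push_back(pn);
        // next direction
        arma::vec3 dn;
        double pc[3] = {pn(0), pn(1), pn(2)};
        ok = (mode == 0) ? interp_dir(field, n, sp, pc, deg_tol, dn)
                         : peak_dir(field, n, sp, pc, &d, dn);
        if (!ok) break;
        if (arma::dot(dn, d) < 0) dn = -dn;
        if (arma::dot(dn, d) < cos_thresh) break;
        d = dn;
        p = pn;
      }
    }
    const size_t npts = half[0].size() + half[1].size() + 1;
    if (npts < 2) continue;
    arma::mat line(npts, 3);
    size_t r = 0;
    for (size_t i = half[1].size(); i-- > 0;) { line.row(r++) = half[1][i].t(); }
    line(r, 0) = p0[0]; line(r, 1) = p0[1]; line(r, 2) = p0[2]; ++r;
    for (size_t i = 0; i < half[0].size(); ++i) line.row(r++) = half[0][i].t();
    double len = 0;
    for (size_t i = 1; i < npts; ++i) len += arma::norm(line.row(i) - line.row(i - 1));
    if (len >= min_len && len <= max_len) out.push_back(line);
  }
  return out;
}

// Instance normalization forward: per-sample, per-channel standardization
// with learned scale g and shift b over B stacked samples; returns y, xhat
// and the per-sample invsd rows for the backward pass.
// [[Rcpp::export]]
List cpp_in_fwd(const arma::mat& x, const arma::rowvec& g, const arma::rowvec& b,
                double eps, int B) {
  const size_t n = x.n_rows / B;
  arma::mat xhat(x.n_rows, x.n_cols);
  arma::mat invsd(B, x.n_cols);
  for (int bi = 0; bi < B; ++bi) {
    arma::mat xb = x.rows(bi * n, (bi + 1) * n - 1);
    arma::rowvec mu = arma::mean(xb, 0);
    arma::mat xc = xb.each_row() - mu;
    arma::rowvec is = 1.0 / arma::sqrt(arma::mean(arma::square(xc), 0) + eps);
    invsd.row(bi) = is;
    xhat.rows(bi * n, (bi + 1) * n - 1) = xc.each_row() % is;
  }
  arma::mat y = xhat.each_row() % g;
  y.each_row() += b;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invsd"] = invsd);
}

// Instance normalization backward (B stacked samples).
// [[Rcpp::export]]
List cpp_in_bwd(const arma::mat& dy, const arma::mat& xhat,
                const arma::mat& invsd, const arma::rowvec& g, int B) {
  const size_t n = dy.n_rows / B;
  arma::rowvec dg = arma::sum(dy % xhat, 0);
  arma::rowvec db = arma::sum(dy, 0);
  arma::mat dxhat = dy.each_row() % g;
  arma::mat dx(dy.n_rows, dy.n_cols);
  for (int bi = 0; bi < B; ++bi) {
    arma::mat dxb = dxhat.rows(bi * n, (bi + 1) * n - 1);
    arma::mat xhb = xhat.rows(bi * n, (bi + 1) * n - 1);
    arma::rowvec m1 = arma::mean(dxb, 0);
    arma::rowvec m2 = arma::mean(dxb % xhb, 0);
    arma::mat d = dxb.each_row() - m1;
    d -= xhb.each_row() % m2;
    d.each_row() %= invsd.row(bi);
    dx.rows(bi * n, (bi + 1) * n - 1) = d;
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}
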