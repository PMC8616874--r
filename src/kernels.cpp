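// Low-level compute kernels for the tiny volumetric conv-nets and mask
// post-processing. Volumes cross the R/C++ boundary as (channels x voxels)
// matrices in R's column-major linear voxel order, with the grid dims passed
// alongside; this keeps all layer bookkeeping in R while the O(N) loops and
// the big matrix products (BLAS gemm) run here.

#include <RcppArmadillo.h>
#include <vector>

using namespace arma;

// Fill `buf` (C x N) with x shifted by offset (dx,dy,dz), zero padded.
static void fill_shifted(mat& buf, const mat& x, int d1, int d2, int d3,
                         int dx, int dy, int dz) {
  const int C = x.n_rows;
  buf.zeros();
  for (int z = 0; z < d3; ++z) {
    const int zz = z + dz;
    if (zz < 0 || zz >= d3) continue;
    for (int y = 0; y < d2; ++y) {
      const int yy = y + dy;
      if (yy < 0 || yy >= d2) continue;
      const int x0 = std::max(0, -dx);
      const int x1 = std::min(d1, d1 - dx);
      if (x1 <= x0) continue;
      const int j  = x0 + d1 * (y + d2 * z);
      const int jj = (x0 + dx) + d1 * (yy + d2 * zz);
      std::memcpy(buf.colptr(j), x.colptr(jj),
                  (size_t)(x1 - x0) * C * sizeof(double));
    }
  }
}

// Scatter-add `buf` (C x N) shifted by (dx,dy,dz) onto `acc` (the adjoint
// of fill_shifted).
static void add_shifted(mat& acc, const mat& buf, int d1, int d2, int d3,
                        int dx, int dy, int dz) {
  const int C = buf.n_rows;
  for (int z = 0; z < d3; ++z) {
    const int zz = z + dz;
    if (zz < 0 || zz >= d3) continue;
    for (int y = 0; y < d2; ++y) {
      const int yy = y + dy;
      if (yy < 0 || yy >= d2) continue;
      const int x0 = std::max(0, -dx);
      const int x1 = std::min(d1, d1 - dx);
      if (x1 <= x0) continue;
      const int j  = x0 + d1 * (y + d2 * z);
      const int jj = (x0 + dx) + d1 * (yy + d2 * zz);
      double* dst = acc.colptr(jj);
      const double* src = buf.colptr(j);
      const size_t len = (size_t)(x1 - x0) * C;
      for (size_t k = 0; k < len; ++k) dst[k] += src[k];
    }
  }
}

// 3x3x3 zero-padded convolution, accumulated offset by offset so no
// 27C x N im2col matrix is ever materialised. W is O x 27C with the
// columns of offset o (x-fastest over (-1,0,1)^3) in block o*C..o*C+C-1.
// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat& x, const Rcpp::IntegerVector& dims,
                        const arma::mat& W, const arma::vec& b) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int C = x.n_rows;
  const int N = d1 * d2 * d3;
  mat y(W.n_rows, N);
  y.each_col() = b;
  mat buf(C, N);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        fill_shifted(buf, x, d1, d2, d3, dx, dy, dz);
        y += W.cols(o * C, o * C + C - 1) * buf;
      }
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3_bwd(const arma::mat& x, const Rcpp::IntegerVector& dims,
                         const arma::mat& W, const arma::mat& gy) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int C = x.n_rows;
  const int N = d1 * d2 * d3;
  mat gW(W.n_rows, W.n_cols);
  vec gb = sum(gy, 1);
  mat gx(C, N, fill::zeros);
  mat buf(C, N);
  int o = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++o) {
        fill_shifted(buf, x, d1, d2, d3, dx, dy, dz);
        gW.cols(o * C, o * C + C - 1) = gy * buf.t();
        buf = W.cols(o * C, o * C + C - 1).t() * gy;
        add_shifted(gx, buf, d1, d2, d3, dx, dy, dz);
      }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// 2x2x2 max pooling; dims must be even. Returns pooled values and the
// 0-based linear input index of each max (per channel) for the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_pool2_fwd(const arma::mat& x, const Rcpp::IntegerVector& dims) {
  const int C = x.n_rows;
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  const int M = o1 * o2 * o3;
  mat y(C, M);
  imat idx(C, M);
  for (int z = 0; z < o3; ++z) {
    for (int yv = 0; yv < o2; ++yv) {
      for (int xv = 0; xv < o1; ++xv) {
        const int j = xv + o1 * (yv + o2 * z);
        for (int c = 0; c < C; ++c) {
          double best = -datum::inf;
          int besti = -1;
          for (int bz = 0; bz < 2; ++bz)
            for (int by = 0; by < 2; ++by)
              for (int bx = 0; bx < 2; ++bx) {
                const int jj = (2 * xv + bx) + d1 * ((2 * yv + by) + d2 * (2 * z + bz));
                const double v = x(c, jj);
                if (v > best) { best = v; besti = jj; }
              }
          y(c, j) = best;
          idx(c, j) = besti;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::mat cpp_pool2_bwd(const arma::mat& gy, const arma::imat& idx, int N) {
  const int C = gy.n_rows;
  mat gx(C, N, fill::zeros);
  for (uword j = 0; j < gy.n_cols; ++j)
    for (int c = 0; c < C; ++c)
      gx(c, idx(c, j)) += gy(c, j);
  return gx;
}

// Nearest-neighbour x2 upsampling and its adjoint (block sum).
// [[Rcpp::export]]
arma::mat cpp_up2_fwd(const arma::mat& x, const Rcpp::IntegerVector& dims) {
  const int C = x.n_rows;
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int u1 = 2 * d1, u2 = 2 * d2, u3 = 2 * d3;
  mat y(C, u1 * u2 * u3);
  for (int z = 0; z < u3; ++z)
    for (int yv = 0; yv < u2; ++yv)
      for (int xv = 0; xv < u1; ++xv) {
        const int j  = xv + u1 * (yv + u2 * z);
        const int jj = (xv / 2) + d1 * ((yv / 2) + d2 * (z / 2));
        std::memcpy(y.colptr(j), x.colptr(jj), C * sizeof(double));
      }
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_up2_bwd(const arma::mat& gy, const Rcpp::IntegerVector& dims) {
  const int C = gy.n_rows;
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int u1 = 2 * d1, u2 = 2 * d2;
  const int u3 = 2 * d3;
  mat gx(C, d1 * d2 * d3, fill::zeros);
  for (int z = 0; z < u3; ++z)
    for (int yv = 0; yv < u2; ++yv)
      for (int xv = 0; xv < u1; ++xv) {
        const int j  = xv + u1 * (yv + u2 * z);
        const int jj = (xv / 2) + d1 * ((yv / 2) + d2 * (z / 2));
        double* dst = gx.colptr(jj);
        const double* src = gy.colptr(j);
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  return gx;
}

// 26-connected component labelling of a binary volume. Returns integer
// labels (0 = background), components numbered in scan order.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_label26(const Rcpp::LogicalVector& mask,
                                const Rcpp::IntegerVector& dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int N = d1 * d2 * d3;
  Rcpp::IntegerVector lab(N, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < N; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const int j = stack.back();
      stack.pop_back();
      const int x = j % d1, y = (j / d1) % d2, z = j / (d1 * d2);
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= d3) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= d2) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int xx = x + dx;
            if (xx < 0 || xx >= d1) continue;
            const int jj = xx + d1 * (yy + d2 * zz);
            if (mask[jj] && lab[jj] == 0) {
              lab[jj] = next;
              stack.push_back(jj);
            }
          }
        }
      }
    }
  }
  return lab;
}
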