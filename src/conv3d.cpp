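// Dilated 3x3x3 3D convolution with "same" zero padding, im2col + GEMM.
// Feature maps are (nx*ny*nz) x C matrices, voxel index i = x + nx*(y + ny*z)
// (R array order). Weight layout: (27*Cin) x Cout with row t*Cin + c for tap
// t = (dx+1) + 3*(dy+1) + 9*(dz+1), dx/dy/dz in {-1,0,1} scaled by dilation.
// Work proceeds in z-slabs to bound the im2col buffer.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int MAX_COL_DOUBLES = 8 * 1024 * 1024;  // ~64 MB buffer

static void fill_col_slab(const mat& input, int nx, int ny, int nz, int dil,
                          int z0, int z1, mat& col) {
  const int cin = input.n_cols;
  const int slab_rows = nx * ny * (z1 - z0);
  col.zeros(slab_rows, 27 * cin);
  for (int t = 0; t < 27; ++t) {
    const int dx = (t % 3 - 1) * dil;
    const int dy = ((t / 3) % 3 - 1) * dil;
    const int dz = (t / 9 - 1) * dil;
    for (int z = z0; z < z1; ++z) {
      const int zs = z + dz;
      if (zs < 0 || zs >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        const int ys = y + dy;
        if (ys < 0 || ys >= ny) continue;
        const int x_lo = std::max(0, -dx), x_hi = std::min(nx, nx - dx);
        if (x_lo >= x_hi) continue;
        const int dst0 = x_lo + nx * (y + ny * (z - z0));
        const int src0 = (x_lo + dx) + nx * (ys + ny * zs);
        for (int c = 0; c < cin; ++c) {
          std::copy(input.colptr(c) + src0, input.colptr(c) + src0 + (x_hi - x_lo),
                    col.colptr(t * cin + c) + dst0);
        }
      }
    }
  }
}

static int slab_height(int nx, int ny, int cin) {
  int h = MAX_COL_DOUBLES / std::max(1, nx * ny * 27 * cin);
  return std::max(1, h);
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_fwd(const arma::mat& input, Rcpp::IntegerVector dims,
                         int dil, const arma::mat& W, const arma::vec& b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cout = W.n_cols;
  mat out(input.n_rows, cout);
  mat col;
  const int step = slab_height(nx, ny, input.n_cols);
  for (int z0 = 0; z0 < nz; z0 += step) {
    const int z1 = std::min(nz, z0 + step);
    fill_col_slab(input, nx, ny, nz, dil, z0, z1, col);
    out.rows(nx * ny * z0, nx * ny * z1 - 1) = col * W;
  }
  out.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3d_bwd(const arma::mat& input, Rcpp::IntegerVector dims,
                          int dil, const arma::mat& W, const arma::mat& gout,
                          bool want_din) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cin = input.n_cols;
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db = sum(gout, 0).t();
  mat din;
  if (want_din) din.zeros(input.n_rows, cin);
  mat col, m;
  const int step = slab_height(nx, ny, cin);
  for (int z0 = 0; z0 < nz; z0 += step) {
    const int z1 = std::min(nz, z0 + step);
    fill_col_slab(input, nx, ny, nz, dil, z0, z1, col);
    const mat gslab = gout.rows(nx * ny * z0, nx * ny * z1 - 1);
    dW += col.t() * gslab;
    if (!want_din) continue;
    m = gslab * W.t();  // slab_rows x 27*cin
    // scatter-add: tap t of m contributes to input at position + offset
    for (int t = 0; t < 27; ++t) {
      const int dx = (t % 3 - 1) * dil;
      const int dy = ((t / 3) % 3 - 1) * dil;
      const int dz = (t / 9 - 1) * dil;
      for (int z = z0; z < z1; ++z) {
        const int zs = z + dz;
        if (zs < 0 || zs >= nz) continue;
        for (int y = 0; y < ny; ++y) {
          const int ys = y + dy;
          if (ys < 0 || ys >= ny) continue;
          const int x_lo = std::max(0, -dx), x_hi = std::min(nx, nx - dx);
          if (x_lo >= x_hi) continue;
          const int src0 = x_lo + nx * (y + ny * (z - z0));
          const int dst0 = (x_lo + dx) + nx * (ys + ny * zs);
          for (int c = 0; c < cin; ++c) {
            double* dp = din.colptr(c) + dst0;
            const double* sp = m.colptr(t * cin + c) + src0;
            for (int k = 0; k < x_hi - x_lo; ++k) dp[k] += sp[k];
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("din") = din);
}
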