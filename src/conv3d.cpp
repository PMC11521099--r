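// im2col/col2im for 3x3x3 3D convolution with same-padding.
// Column order matches R's column-major flattening of a (3,3,3,Cin) kernel
// block; row order matches column-major flattening of the output grid, so
// the convolution itself is a single BLAS matrix product on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static inline int out_extent(int n, int stride) {
  return (n + 2 - 3) / stride + 1;  // kernel 3, pad 1
}

// [[Rcpp::export]]
arma::mat im2col3d(const arma::vec& x, const arma::ivec& dims, int stride) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2], C = dims[3];
  const int o1 = out_extent(n1, stride);
  const int o2 = out_extent(n2, stride);
  const int o3 = out_extent(n3, stride);
  arma::mat out(static_cast<size_t>(o1) * o2 * o3, 27 * C,
                arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.memptr() + static_cast<size_t>(c) * n1 * n2 * n3;
    for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
        for (int kx = 0; kx < 3; ++kx) {
          double* ocol = out.colptr(kx + 3 * ky + 9 * kz + 27 * c);
          for (int i3 = 0; i3 < o3; ++i3) {
            const int z = i3 * stride + kz - 1;
            if (z < 0 || z >= n3) continue;
            for (int i2 = 0; i2 < o2; ++i2) {
              const int y = i2 * stride + ky - 1;
              if (y < 0 || y >= n2) continue;
              for (int i1 = 0; i1 < o1; ++i1) {
                const int xx = i1 * stride + kx - 1;
                if (xx < 0 || xx >= n1) continue;
                ocol[i1 + static_cast<size_t>(o1) * (i2 + static_cast<size_t>(o2) * i3)] =
                  xc[xx + static_cast<size_t>(n1) * (y + static_cast<size_t>(n2) * z)];
              }
            }
          }
        }
  }
  return out;
}

// [[Rcpp::export]]
arma::vec col2im3d(const arma::mat& gcol, const arma::ivec& dims, int stride) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2], C = dims[3];
  const int o1 = out_extent(n1, stride);
  const int o2 = out_extent(n2, stride);
  const int o3 = out_extent(n3, stride);
  arma::vec gx(static_cast<size_t>(n1) * n2 * n3 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xc = gx.memptr() + static_cast<size_t>(c) * n1 * n2 * n3;
    for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
        for (int kx = 0; kx < 3; ++kx) {
          const double* ocol = gcol.colptr(kx + 3 * ky + 9 * kz + 27 * c);
          for (int i3 = 0; i3 < o3; ++i3) {
            const int z = i3 * stride + kz - 1;
            if (z < 0 || z >= n3) continue;
            for (int i2 = 0; i2 < o2; ++i2) {
              const int y = i2 * stride + ky - 1;
              if (y < 0 || y >= n2) continue;
              for (int i1 = 0; i1 < o1; ++i1) {
                const int xx = i1 * stride + kx - 1;
                if (xx < 0 || xx >= n1) continue;
                xc[xx + static_cast<size_t>(n1) * (y + static_cast<size_t>(n2) * z)] +=
                  ocol[i1 + static_cast<size_t>(o1) * (i2 + static_cast<size_t>(o2) * i3)];
              }
            }
          }
        }
  }
  return gx;
}
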