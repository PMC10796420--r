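#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Seeded 26-connected component of a 3D logical mask.
// mask: logical vector in column-major order with dims nx*ny*nz;
// seed: 1-based (i, j, k). Returns a logical vector of the same length
// marking the component that contains the seed.
// [[Rcpp::export]]
LogicalVector cc26_from_seed(LogicalVector mask, IntegerVector dims,
                             IntegerVector seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  const int si = seed[0] - 1, sj = seed[1] - 1, sk = seed[2] - 1;
  if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz)
    stop("seed point outside the volume");
  LogicalVector out(n, false);
  const R_xlen_t start = si + (R_xlen_t)nx * (sj + (R_xlen_t)ny * sk);
  if (!mask[start]) stop("seed point is not an on-voxel");

  std::vector<R_xlen_t> stack;
  stack.push_back(start);
  out[start] = true;
  while (!stack.empty()) {
    const R_xlen_t cur = stack.back();
    stack.pop_back();
    const int k = cur / ((R_xlen_t)nx * ny);
    const int rem = cur - (R_xlen_t)k * nx * ny;
    const int j = rem / nx;
    const int i = rem - j * nx;
    for (int dk = -1; dk <= 1; ++dk) {
      const int kk = k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          const int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          const R_xlen_t idx = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (mask[idx] && !out[idx]) {
            out[idx] = true;
            stack.push_back(idx);
          }
        }
      }
    }
  }
  return out;
}
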