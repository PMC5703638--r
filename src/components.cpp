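#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling of a logical mask under 6/18/26
// connectivity. Mask is a logical array in R's column-major layout with
// dims (nz, ny, nx). Returns an integer array of the same shape with
// background 0 and components labeled 1..N (attribute "n").
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dims,
                      int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask size does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int nn = (int)dz.size();

  IntegerVector labels(n, 0);
  int current = 0;
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int z = (int)(idx % nz);
      int y = (int)((idx / nz) % ny);
      int x = (int)(idx / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nn; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
            xx < 0 || xx >= nx) continue;
        R_xlen_t j = (R_xlen_t)xx * nz * ny + (R_xlen_t)yy * nz + zz;
        if (mask[j] && labels[j] == 0) {
          labels[j] = current;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  labels.attr("n") = current;
  return labels;
}
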