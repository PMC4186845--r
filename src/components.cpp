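#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling on a logical volume.
// connectivity: 6 (faces), 18 (faces+edges), or 26 (faces+edges+corners).
// Returns an integer volume; 0 = background, components numbered from 1
// in order of first (column-major) encounter.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int nn = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (nn == 0) continue;
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int noff = (int)dx.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++current;
    labels[i] = current;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int k = 0; k < noff; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}
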