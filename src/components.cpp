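#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of an integer class image.
// Cells with cls < 0 are unlabeled (output 0); two adjacent cells (8-neighbour)
// belong to the same component iff they carry the same class value. Labels are
// assigned in raster-scan discovery order starting at 1.
// [[Rcpp::export(name = ".labelComponents8")]]
IntegerMatrix labelComponents8(IntegerMatrix cls) {
  const int nr = cls.nrow(), nc = cls.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (cls(i, j) < 0 || lab(i, j) != 0) continue;
      const int cval = cls(i, j);
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int pos = stack.back();
        stack.pop_back();
        const int ci = pos % nr, cj = pos / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (lab(ni, nj) == 0 && cls(ni, nj) == cval) {
              lab(ni, nj) = next;
              stack.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
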