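#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

//' 8-connected component labelling of a binary image
//'
//' Labels connected foreground regions using 8-connectivity (the default
//' of the particle-analysis workflow this package reproduces). Labels are
//' assigned consecutively in raster scan order (down columns, matching R's
//' column-major storage).
//'
//' @param mask logical matrix; \code{TRUE}/nonzero pixels are foreground.
//' @return integer matrix of the same shape; 0 is background, objects are
//'   numbered 1..n.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix cc_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next_label = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next_label;
      lab(r, c) = next_label;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next_label;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
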