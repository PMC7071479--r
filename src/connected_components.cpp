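#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask.
//
// Labels are assigned in row-major scan order: the component whose
// first (topmost, then leftmost) foreground pixel comes first gets
// label 1, and so on. Depth-first flood fill; connectivity 4 or 8.
// NA pixels are treated as background.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) {
      if (mask(i, j) == TRUE && lab(i, j) == 0) {
        ++next;
        lab(i, j) = next;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          const int p = stack.back();
          stack.pop_back();
          const int pi = p % nr, pj = p / nr;
          for (int k = 0; k < nn; k++) {
            const int qi = pi + dr[k], qj = pj + dc[k];
            if (qi >= 0 && qi < nr && qj >= 0 && qj < nc &&
                mask(qi, qj) == TRUE && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
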