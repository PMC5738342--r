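// Connected-component labelling of same-valued regions of an integer
// matrix (iterative flood fill). Pixels whose value equals `background`
// receive label 0; other connected same-value regions get labels 1..k in
// scan order.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".labelRegions")]]
IntegerMatrix label_regions_cpp(IntegerMatrix values, int connectivity,
                                int background, bool useBackground) {
  const int h = values.nrow(), w = values.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  stack.reserve(1024);
  const bool diag = connectivity == 8;
  int next = 0;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (lab(r, c) != 0) continue;
      int v = values(r, c);
      if (useBackground && v == background) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(c * h + r);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % h, pc = p / h;
        const int dr[8] = {1, -1, 0, 0, 1, 1, -1, -1};
        const int dc[8] = {0, 0, 1, -1, 1, -1, 1, -1};
        int nn = diag ? 8 : 4;
        for (int k = 0; k < nn; ++k) {
          int r2 = pr + dr[k], c2 = pc + dc[k];
          if (r2 < 0 || r2 >= h || c2 < 0 || c2 >= w) continue;
          if (lab(r2, c2) != 0) continue;
          if (values(r2, c2) != v) continue;
          lab(r2, c2) = next;
          stack.push_back(c2 * h + r2);
        }
      }
    }
  }
  return lab;
}
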