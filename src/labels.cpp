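#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labelling of a logical matrix, 4-connectivity.
// Returns an integer matrix; 0 = background, components numbered from 1
// in discovery (column-major) order.
// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  int cur = 0;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (m(i, j) && lab(i, j) == 0) {
        ++cur;
        lab(i, j) = cur;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          int idx = stack.back();
          stack.pop_back();
          int ci = idx % nr, cj = idx / nr;
          for (int t = 0; t < 4; ++t) {
            int ni = ci + di[t], nj = cj + dj[t];
            if (ni >= 0 && ni < nr && nj >= 0 && nj < nc &&
                m(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = cur;
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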