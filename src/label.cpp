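#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of a logical matrix (iterative flood fill).

// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int cur = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++cur;
      stack.clear();
      stack.push_back(j * nr + i);
      lab(i, j) = cur;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = cur;
              stack.push_back(qj * nr + qi);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Per-position M-base depth over a window [start, end] (1-based, inclusive)
// from alignment left positions and M lengths on one contig.

// [[Rcpp::export(name = ".cpp_depth")]]
IntegerVector cpp_depth(IntegerVector pos, IntegerVector mlen, int start, int end) {
  int w = end - start + 1;
  if (w <= 0) stop("empty window");
  std::vector<int> diff((size_t)w + 1, 0);
  for (int i = 0; i < pos.size(); ++i) {
    int a = pos[i], b = pos[i] + mlen[i] - 1;
    if (b < start || a > end) continue;
    int lo = std::max(a, start) - start, hi = std::min(b, end) - start;
    diff[(size_t)lo] += 1;
    diff[(size_t)hi + 1] -= 1;
  }
  IntegerVector out(w);
  int c = 0;
  for (int i = 0; i < w; ++i) {
    c += diff[(size_t)i];
    out[i] = c;
  }
  return out;
}
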