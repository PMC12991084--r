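#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Traceback tie-break: diagonal (match/mismatch) beats a gap in A
// (consume B only) which beats a gap in B (consume A only).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  int match = 1, int mismatch = -1, int gap = -2) {
  const int n = a.size(), m = b.size();
  std::vector<int> H((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int i = 0; i <= n; ++i) H[at(i, 0)] = i * gap;
  for (int j = 0; j <= m; ++j) H[at(0, j)] = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int d = H[at(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int l = H[at(i, j - 1)] + gap;   // gap in A
      int u = H[at(i - 1, j)] + gap;   // gap in B
      int best = d >= l ? d : l;
      if (u > best) best = u;
      H[at(i, j)] = best;
    }
  }
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int h = H[at(i, j)];
    if (i > 0 && j > 0 &&
        h == H[at(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch)) {
      ai.push_back(i); bi.push_back(j); --i; --j;
    } else if (j > 0 && h == H[at(i, j - 1)] + gap) {
      ai.push_back(NA_INTEGER); bi.push_back(j); --j;
    } else {
      ai.push_back(i); bi.push_back(NA_INTEGER); --i;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = H[at(n, m)],
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi.begin(), bi.end()));
}
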