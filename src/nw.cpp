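#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Needleman-Wunsch global alignment with linear gap penalties.
// Traceback tie-break is fixed: diagonal, then up (gap in b), then left
// (gap in a), so alignments are bit-reproducible.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b, double match, double mismatch,
              double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> F((n + 1) * (m + 1));
  std::vector<unsigned char> tb((n + 1) * (m + 1)); // 0 diag, 1 up, 2 left
  const int W = m + 1;
  F[0] = 0.0;
  for (int j = 1; j <= m; ++j) { F[j] = j * gap; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) { F[i * W] = i * gap; tb[i * W] = 1; }
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      double diag = F[(i - 1) * W + j - 1] + (ai == b[j - 1] ? match : mismatch);
      double up = F[(i - 1) * W + j] + gap;
      double left = F[i * W + j - 1] + gap;
      double best = diag;
      unsigned char dir = 0;
      if (up > best) { best = up; dir = 1; }
      if (left > best) { best = left; dir = 2; }
      F[i * W + j] = best;
      tb[i * W + j] = dir;
    }
  }
  std::string ag, bg;
  ag.reserve(n + m);
  bg.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[i * W + j];
    if (i > 0 && j > 0 && dir == 0) {
      ag.push_back(a[i - 1]);
      bg.push_back(b[j - 1]);
      --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      ag.push_back(a[i - 1]);
      bg.push_back('-');
      --i;
    } else {
      ag.push_back('-');
      bg.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(ag.begin(), ag.end());
  std::reverse(bg.begin(), bg.end());
  return List::create(_["a_gapped"] = ag, _["b_gapped"] = bg,
                      _["score"] = F[n * W + m]);
}
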