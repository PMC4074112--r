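#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (end-gap penalized) Needleman-Wunsch with fixed scoring:
// match +1, mismatch -1, gap column -2.  N (or any non-ACGT letter)
// mismatches everything, including itself.  Traceback ties are broken
// deterministically: diagonal, then up (gap in b), then left (gap in a),
// so identical inputs always yield the same alignment.

static inline bool is_match(char x, char y) {
  if (x != y) return false;
  return x == 'A' || x == 'C' || x == 'G' || x == 'T';
}

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b) {
  const int na = a.size(), nb = b.size();
  const int GAP = -2, MATCH = 1, MISMATCH = -1;
  if (na == 0 || nb == 0) stop("sequences must be non-empty");
  for (auto &c : a) c = std::toupper(c);
  for (auto &c : b) c = std::toupper(c);

  // score matrix (na+1) x (nb+1), row-major
  std::vector<int> S((na + 1) * (nb + 1));
  const int W = nb + 1;
  for (int j = 0; j <= nb; ++j) S[j] = GAP * j;
  for (int i = 1; i <= na; ++i) {
    S[i * W] = GAP * i;
    for (int j = 1; j <= nb; ++j) {
      int diag = S[(i - 1) * W + (j - 1)] +
                 (is_match(a[i - 1], b[j - 1]) ? MATCH : MISMATCH);
      int up = S[(i - 1) * W + j] + GAP;
      int left = S[i * W + (j - 1)] + GAP;
      int best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      S[i * W + j] = best;
    }
  }

  // traceback: prefer diagonal, then up, then left
  int i = na, j = nb;
  int cols = 0, ident = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      int sc = S[i * W + j];
      int diag = S[(i - 1) * W + (j - 1)] +
                 (is_match(a[i - 1], b[j - 1]) ? MATCH : MISMATCH);
      if (sc == diag) {
        if (is_match(a[i - 1], b[j - 1])) ++ident;
        --i; --j; ++cols;
        continue;
      }
      if (sc == S[(i - 1) * W + j] + GAP) { --i; ++cols; continue; }
      --j; ++cols; continue;
    }
    if (i > 0) { --i; ++cols; } else { --j; ++cols; }
  }

  return List::create(_["score"] = S[na * W + nb],
                      _["identity"] = (double)ident / (double)cols,
                      _["columns"] = cols,
                      _["identical"] = ident);
}
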