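#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Banded Levenshtein distance capped at max_dist: returns the exact
// distance if it is <= max_dist, otherwise max_dist + 1. Classic
// Ukkonen band of half-width max_dist with early abort.
static int lev_capped(const std::string &a, const std::string &b,
                      int max_dist) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (std::abs(la - lb) > max_dist) return max_dist + 1;
  const int INF = max_dist + 1;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j <= max_dist ? j : INF;
  for (int i = 1; i <= la; ++i) {
    int lo = std::max(1, i - max_dist), hi = std::min(lb, i + max_dist);
    cur[lo - 1] = (i - max_dist <= 1) ? i : INF;
    int rowmin = cur[lo - 1] < INF ? cur[lo - 1] : INF;
    for (int j = lo; j <= hi; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int v = sub < del ? sub : del;
      if (ins < v) v = ins;
      if (v > INF) v = INF;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (hi < lb) cur[hi + 1] = INF;
    if (rowmin > max_dist) return INF;
    std::swap(prev, cur);
  }
  return prev[lb] <= max_dist ? prev[lb] : INF;
}

// All pairs with Levenshtein distance <= max_dist, as a 1-based edge
// list. Pairs are pruned by (a) length difference and (b) the
// character-count L1 lower bound (one edit changes the composition
// L1 by at most 2) before the exact banded DP runs.
// [[Rcpp::export]]
List lev_edges_cpp(CharacterVector seqs, int max_dist) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);

  // composition profiles over a 26-letter window
  std::vector<std::array<unsigned char, 26>> cnt(n);
  for (int i = 0; i < n; ++i) {
    cnt[i].fill(0);
    for (char c : s[i]) {
      int k = c - 'A';
      if (k >= 0 && k < 26 && cnt[i][k] < 255) ++cnt[i][k];
    }
  }
  // process in length order so the inner loop is a sliding window
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return s[a].size() < s[b].size();
  });

  const int l1max = 2 * max_dist;
  std::vector<int> ei, ej, ed;
  for (int a = 0; a < n - 1; ++a) {
    const int i = ord[a];
    const int li = (int)s[i].size();
    for (int b = a + 1; b < n; ++b) {
      const int j = ord[b];
      if ((int)s[j].size() - li > max_dist) break;
      int l1 = 0;
      for (int k = 0; k < 26; ++k) {
        l1 += std::abs((int)cnt[i][k] - (int)cnt[j][k]);
        if (l1 > l1max) break;
      }
      if (l1 > l1max) continue;
      int d = lev_capped(s[i], s[j], max_dist);
      if (d <= max_dist) {
        ei.push_back(std::min(i, j) + 1);
        ej.push_back(std::max(i, j) + 1);
        ed.push_back(d);
      }
    }
    if (a % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["i"] = wrap(ei), _["j"] = wrap(ej),
                      _["d"] = wrap(ed));
}
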