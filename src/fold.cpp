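#include <Rcpp.h>
using namespace Rcpp;

// Maximum base pairing over nested (pseudoknot-free) secondary structures,
// Watson-Crick plus G.U wobble pairs on the DNA alphabet (T stands for U),
// with a minimum hairpin loop of `min_loop` unpaired bases. Classic O(n^3)
// dynamic programme with deterministic traceback.

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// [[Rcpp::export]]
List nussinov_cpp(std::string seq, int min_loop) {
  int n = (int)seq.size();
  IntegerVector pairing(n, NA_INTEGER);
  if (n == 0)
    return List::create(_["pairing"] = pairing, _["n_pairs"] = 0);

  std::vector<std::vector<int>> dp(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[i + 1][j];
      if (dp[i][j - 1] > best) best = dp[i][j - 1];
      if (can_pair(seq[i], seq[j]) && dp[i + 1][j - 1] + 1 > best)
        best = dp[i + 1][j - 1] + 1;
      for (int k = i + 1; k < j; ++k) {
        int v = dp[i][k] + dp[k + 1][j];
        if (v > best) best = v;
      }
      dp[i][j] = best;
    }
  }

  // traceback. On ties, closing the pair (i,j) is preferred over leaving an
  // end unpaired so that equal-score structures resolve to stacked stems
  // rather than gratuitous multiloops.
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (dp[i][j] == 0) continue;
    if (can_pair(seq[i], seq[j]) && dp[i][j] == dp[i + 1][j - 1] + 1) {
      pairing[i] = j + 1;
      pairing[j] = i + 1;
      stack.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    if (dp[i][j] == dp[i + 1][j]) { stack.push_back(std::make_pair(i + 1, j)); continue; }
    if (dp[i][j] == dp[i][j - 1]) { stack.push_back(std::make_pair(i, j - 1)); continue; }
    for (int k = i + 1; k < j; ++k) {
      if (dp[i][j] == dp[i][k] + dp[k + 1][j]) {
        stack.push_back(std::make_pair(i, k));
        stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }

  int np = 0;
  for (int i = 0; i < n; ++i) if (pairing[i] != NA_INTEGER) ++np;
  return List::create(_["pairing"] = pairing, _["n_pairs"] = np / 2);
}
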