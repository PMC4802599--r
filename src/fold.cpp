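#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Nussinov-style base-pair maximization with a minimum hairpin loop of
// `min_loop` unpaired nt. Pairs: A-U(T), G-C and the G-U wobble. Traceback
// is deterministic: when several branch points reach the optimum, the
// outermost partner is chosen, which keeps contiguous stems intact.

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// [[Rcpp::export(rng = false)]]
IntegerVector fold_partner_cpp(std::string seq, int min_loop = 3) {
  int n = seq.size();
  IntegerVector partner(n, 0);
  if (n < min_loop + 2) return partner;

  std::vector<std::vector<short>> dp(n, std::vector<short>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      short best = dp[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        short val = 1;
        if (k - 1 >= i + 1) val += dp[i + 1][k - 1];
        if (k + 1 <= j) val += dp[k + 1][j];
        if (val > best) best = val;
      }
      dp[i][j] = best;
    }
  }

  // iterative traceback over subintervals
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (dp[i][j] == dp[i + 1][j]) {
      // prefer pairing i when a pairing alternative reaches the optimum
      int chosen = -1;
      for (int k = j; k >= i + min_loop + 1; --k) {
        if (!can_pair(seq[i], seq[k])) continue;
        short val = 1;
        if (k - 1 >= i + 1) val += dp[i + 1][k - 1];
        if (k + 1 <= j) val += dp[k + 1][j];
        if (val == dp[i][j]) { chosen = k; break; }
      }
      if (chosen < 0) {
        stack.push_back(std::make_pair(i + 1, j));
        continue;
      }
      partner[i] = chosen + 1;  // 1-based
      partner[chosen] = i + 1;
      if (chosen - 1 > i + 1) stack.push_back(std::make_pair(i + 1, chosen - 1));
      if (chosen + 1 < j) stack.push_back(std::make_pair(chosen + 1, j));
      continue;
    }
    int chosen = -1;
    for (int k = j; k >= i + min_loop + 1; --k) {
      if (!can_pair(seq[i], seq[k])) continue;
      short val = 1;
      if (k - 1 >= i + 1) val += dp[i + 1][k - 1];
      if (k + 1 <= j) val += dp[k + 1][j];
      if (val == dp[i][j]) { chosen = k; break; }
    }
    partner[i] = chosen + 1;
    partner[chosen] = i + 1;
    if (chosen - 1 > i + 1) stack.push_back(std::make_pair(i + 1, chosen - 1));
    if (chosen + 1 < j) stack.push_back(std::make_pair(chosen + 1, j));
  }
  return partner;
}
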