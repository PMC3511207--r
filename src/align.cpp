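#include <Rcpp.h>
using namespace Rcpp;

// Global alignment with unit costs (match 0, mismatch 1, gap 1).
// Among all minimum-cost alignments the one with the shortest alignment
// length is taken (equivalently: indel pairs are collapsed into
// substitutions wherever optimal), which is what a traceback preferring the
// diagonal produces. Returns c(differing_columns, alignment_length).
// [[Rcpp::export(name = ".align_stats")]]
IntegerVector align_stats(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<int> cost_prev(m + 1), cost_cur(m + 1);
  std::vector<int> len_prev(m + 1), len_cur(m + 1);
  for (int j = 0; j <= m; ++j) { cost_prev[j] = j; len_prev[j] = j; }
  for (int i = 1; i <= n; ++i) {
    cost_cur[0] = i; len_cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int cd = cost_prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int ld = len_prev[j - 1] + 1;
      int cu = cost_prev[j] + 1, lu = len_prev[j] + 1;
      int cl = cost_cur[j - 1] + 1, ll = len_cur[j - 1] + 1;
      int c = cd, l = ld;                    // diagonal preferred on ties
      if (cu < c || (cu == c && lu < l)) { c = cu; l = lu; }
      if (cl < c || (cl == c && ll < l)) { c = cl; l = ll; }
      cost_cur[j] = c; len_cur[j] = l;
    }
    std::swap(cost_prev, cost_cur);
    std::swap(len_prev, len_cur);
  }
  return IntegerVector::create(cost_prev[m], len_prev[m]);
}
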