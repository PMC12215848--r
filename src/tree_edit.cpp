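#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Zhang-Shasha ordered-tree edit distance.
//
// Trees arrive as postorder arrays (1-based): `label` holds an integer label
// per node, `lld` the postorder index of each node's leftmost leaf
// descendant. `indel` gives the deletion/insertion cost per label value
// (indexed label + 1); substituting label a for b costs 0 when a == b and
// indel[a] + indel[b] otherwise, which keeps the distance a metric and
// reproduces reference behaviour where cross-label relabelling is never
// chosen.
// [[Rcpp::export]]
double zs_tree_distance(IntegerVector label1, IntegerVector lld1,
                        IntegerVector label2, IntegerVector lld2,
                        NumericVector indel) {
  const int n1 = label1.size(), n2 = label2.size();
  if (n1 == 0 || n2 == 0) {
    double s = 0.0;
    for (int i = 0; i < n1; ++i) s += indel[label1[i]];
    for (int j = 0; j < n2; ++j) s += indel[label2[j]];
    return s;
  }

  auto keyroots = [](const IntegerVector &lld, int n) {
    std::vector<int> kr;
    std::vector<bool> seen(n + 2, false);
    for (int i = n; i >= 1; --i) {
      if (!seen[lld[i - 1]]) { kr.push_back(i); seen[lld[i - 1]] = true; }
    }
    std::sort(kr.begin(), kr.end());
    return kr;
  };
  std::vector<int> kr1 = keyroots(lld1, n1), kr2 = keyroots(lld2, n2);

  std::vector<std::vector<double>> td(n1 + 1, std::vector<double>(n2 + 1, 0.0));
  std::vector<std::vector<double>> fd(n1 + 2, std::vector<double>(n2 + 2, 0.0));

  for (int ki = 0; ki < (int)kr1.size(); ++ki) {
    const int i1 = kr1[ki];
    const int li = lld1[i1 - 1];
    for (int kj = 0; kj < (int)kr2.size(); ++kj) {
      const int j1 = kr2[kj];
      const int lj = lld2[j1 - 1];

      fd[li - 1][lj - 1] = 0.0;
      for (int di = li; di <= i1; ++di)
        fd[di][lj - 1] = fd[di - 1][lj - 1] + indel[label1[di - 1]];
      for (int dj = lj; dj <= j1; ++dj)
        fd[li - 1][dj] = fd[li - 1][dj - 1] + indel[label2[dj - 1]];

      for (int di = li; di <= i1; ++di) {
        for (int dj = lj; dj <= j1; ++dj) {
          const double del = fd[di - 1][dj] + indel[label1[di - 1]];
          const double ins = fd[di][dj - 1] + indel[label2[dj - 1]];
          double best = std::min(del, ins);
          if (lld1[di - 1] == li && lld2[dj - 1] == lj) {
            // both spans are whole subtrees: substitution is allowed
            const double sub = (label1[di - 1] == label2[dj - 1])
              ? 0.0 : indel[label1[di - 1]] + indel[label2[dj - 1]];
            best = std::min(best, fd[di - 1][dj - 1] + sub);
            td[di][dj] = best;
          } else {
            best = std::min(best,
                            fd[lld1[di - 1] - 1][lld2[dj - 1] - 1] + td[di][dj]);
          }
          fd[di][dj] = best;
        }
      }
    }
  }
  return td[n1][n2];
}
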