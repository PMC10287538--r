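// Partition-refinement walk for EHH/nSL: starting from one group holding
// all background haplotypes, refine by the allele at each successive site
// outward from the focal site and report the number of haplotype pairs
// still identical after each site.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector ehh_pair_walk_cpp(const IntegerMatrix &alleles,
                                const IntegerVector &rows,
                                const IntegerVector &cols) {
  const int nr = rows.size(), nc = cols.size();
  IntegerVector out(nc);
  std::vector<int> groups(nr, 0);
  std::vector<int> relab;
  int n_groups = 1;
  for (int k = 0; k < nc; ++k) {
    const int col = cols[k] - 1;
    relab.assign(2 * n_groups, -1);
    int next_id = 0;
    for (int i = 0; i < nr; ++i) {
      const int key = 2 * groups[i] + alleles(rows[i] - 1, col);
      if (relab[key] < 0) relab[key] = next_id++;
      groups[i] = relab[key];
    }
    n_groups = next_id;
    std::vector<int> tab(n_groups, 0);
    for (int i = 0; i < nr; ++i) ++tab[groups[i]];
    long pairs = 0;
    for (int g = 0; g < n_groups; ++g)
      pairs += (long)tab[g] * (tab[g] - 1) / 2;
    out[k] = (int)pairs;
    if (pairs == 0) break;  // remaining entries stay 0
  }
  return out;
}
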