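#include <Rcpp.h>
using namespace Rcpp;

// Pairwise partition-agreement scoring of alignment sites.
//
// codes: n_taxa x n_sites integer matrix; codes(t, s) is the 0-based block
// id of taxon t in the set partition induced by site s (taxa with the same
// character share a block id), or -1 where the character is missing.
// nblocks: number of blocks per site.
//
// pa(i, j) = fraction of blocks of site j that nest inside one block of
// site i, after restricting each block to taxa observed at site i; an
// empty partition (or empty restriction) nests by convention.
// score(i) = mean over j != i of pa(i, j).
// [[Rcpp::export(name = ".tiger_scores_cpp")]]
NumericVector tiger_scores_cpp(IntegerMatrix codes, IntegerVector nblocks) {
  const int ntax = codes.nrow();
  const int nsite = codes.ncol();
  NumericVector score(nsite);
  std::vector<int> refblock; // per block of j: block id seen in i, -2 unset
  std::vector<char> ok;

  for (int i = 0; i < nsite; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nsite; ++j) {
      if (j == i) continue;
      const int bj = nblocks[j];
      if (bj == 0) { acc += 1.0; continue; }
      refblock.assign(bj, -2);
      ok.assign(bj, 1);
      for (int t = 0; t < ntax; ++t) {
        const int cj = codes(t, j);
        if (cj < 0 || !ok[cj]) continue;
        const int ci = codes(t, i);
        if (ci < 0) continue; // taxon absent at site i: drop from the block
        if (refblock[cj] == -2) refblock[cj] = ci;
        else if (refblock[cj] != ci) ok[cj] = 0;
      }
      int good = 0;
      for (int b = 0; b < bj; ++b) good += ok[b];
      acc += static_cast<double>(good) / bj;
    }
    score[i] = acc / (nsite - 1);
  }
  return score;
}
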