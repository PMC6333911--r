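#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Batch meiosis. One gamete per entry of `parent` (1-based row into the
// haplotype matrices). Per chromosome: crossover count ~ Poisson(length in
// Morgan), breakpoints uniform on (0, length), starting strand uniform; the
// strand switches at each breakpoint. A locus sitting exactly on a breakpoint
// stays with the left segment. Neutral IBD loci ride the same breakpoints so
// identity-by-descent tracing is consistent with the selectable loci.
// Mutation (allele toggle) is applied per selectable locus of the transmitted
// gamete with probability mut_rate; IBD founder labels never mutate.
//
// loc_first/loc_last (and ibd_first/ibd_last) are 1-based inclusive column
// ranges per chromosome; a 0 in *_first marks a chromosome without loci of
// that kind. Uses R's RNG stream, so set.seed() gives bit-reproducible runs.
// [[Rcpp::export(name = ".meiosis_batch")]]
List meiosis_batch(IntegerMatrix hap1, IntegerMatrix hap2,
                   IntegerMatrix ibd1, IntegerMatrix ibd2,
                   IntegerVector parent,
                   NumericVector pos,
                   IntegerVector loc_first, IntegerVector loc_last,
                   NumericVector ibd_pos,
                   IntegerVector ibd_first, IntegerVector ibd_last,
                   NumericVector chrom_len,
                   double mut_rate) {
  const int m = parent.size();
  const int L = hap1.ncol();
  const int Li = ibd1.ncol();
  const int C = chrom_len.size();
  IntegerMatrix out(m, L);
  IntegerMatrix outi(m, Li);
  std::vector<double> bp;
  bp.reserve(16);

  for (int g = 0; g < m; ++g) {
    const int p = parent[g] - 1;
    if (p < 0 || p >= hap1.nrow()) stop("parent index out of range");
    for (int c = 0; c < C; ++c) {
      const int k = (int) R::rpois(chrom_len[c]);
      bp.clear();
      for (int j = 0; j < k; ++j) bp.push_back(unif_rand() * chrom_len[c]);
      std::sort(bp.begin(), bp.end());
      const int strand0 = (unif_rand() < 0.5) ? 0 : 1;

      if (loc_first[c] > 0) {
        int idx = 0, strand = strand0;
        const int a = loc_first[c] - 1, b = loc_last[c] - 1;
        for (int j = a; j <= b; ++j) {
          while (idx < k && bp[idx] < pos[j]) { strand ^= 1; ++idx; }
          out(g, j) = strand ? hap2(p, j) : hap1(p, j);
        }
      }
      if (ibd_first[c] > 0) {
        int idx = 0, strand = strand0;
        const int a = ibd_first[c] - 1, b = ibd_last[c] - 1;
        for (int j = a; j <= b; ++j) {
          while (idx < k && bp[idx] < ibd_pos[j]) { strand ^= 1; ++idx; }
          outi(g, j) = strand ? ibd2(p, j) : ibd1(p, j);
        }
      }
    }
    if (mut_rate > 0.0) {
      for (int j = 0; j < L; ++j)
        if (unif_rand() < mut_rate) out(g, j) = 1 - out(g, j);
    }
  }
  return List::create(_["hap"] = out, _["ibd"] = outi);
}
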