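#include <Rcpp.h>
using namespace Rcpp;

// Gamete formation under the Haldane model: crossovers are a Poisson process
// along each chromosome (rate 1 per Morgan, no interference), chromosomes
// assort independently via a random entry strand.
//
// H1, H2: nParents x L phased haplotype matrices (0/1 alleles).
// parent: 0-based parent row index, one entry per gamete to produce.
// pos: locus genetic positions in cM, non-decreasing within a chromosome.
// chrom_begin / chrom_end: 0-based half-open locus ranges per chromosome.
// chrom_len: chromosome genetic lengths in cM.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix& H1, const IntegerMatrix& H2,
                          const IntegerVector& parent, const NumericVector& pos,
                          const IntegerVector& chrom_begin,
                          const IntegerVector& chrom_end,
                          const NumericVector& chrom_len) {
  const int L = H1.ncol();
  const int n = parent.size();
  const int C = chrom_begin.size();
  IntegerMatrix G(n, L);
  std::vector<double> cx;
  for (int g = 0; g < n; ++g) {
    const int p = parent[g];
    for (int c = 0; c < C; ++c) {
      const double len = chrom_len[c];
      const int k = (int) R::rpois(len / 100.0);
      cx.resize(k);
      for (int j = 0; j < k; ++j) cx[j] = unif_rand() * len;
      std::sort(cx.begin(), cx.end());
      int strand = (unif_rand() < 0.5) ? 0 : 1;
      size_t ci = 0;
      for (int l = chrom_begin[c]; l < chrom_end[c]; ++l) {
        while (ci < cx.size() && cx[ci] < pos[l]) { strand ^= 1; ++ci; }
        G(g, l) = (strand == 0) ? H1(p, l) : H2(p, l);
      }
    }
  }
  return G;
}
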