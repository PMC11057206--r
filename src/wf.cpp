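#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gamete formation under Poisson crossovers (no interference; Haldane map
// function). A and B hold the two haplotypes of each individual
// (n_ind x n_loci, 0/1). `parent` gives the 1-based parent of each gamete.
// `chrom_start` holds 0-based start offsets of each chromosome block plus a
// final sentinel equal to n_loci; `pos` is the genetic position (Morgans),
// non-decreasing within a chromosome. Chromosomes assort independently.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix make_gametes_cpp(const IntegerMatrix& A, const IntegerMatrix& B,
                               const IntegerVector& parent,
                               const IntegerVector& chrom_start,
                               const NumericVector& pos) {
  const int L = A.ncol();
  const int G = parent.size();
  const int nseg = chrom_start.size() - 1;
  IntegerMatrix out(G, L);
  std::vector<double> cx;

  for (int g = 0; g < G; ++g) {
    const int p = parent[g] - 1;
    for (int s = 0; s < nseg; ++s) {
      const int lo = chrom_start[s], hi = chrom_start[s + 1];  // [lo, hi)
      int state = (unif_rand() < 0.5) ? 0 : 1;
      const double a = pos[lo], b = pos[hi - 1], len = b - a;
      const int ncx = (len > 0.0) ? static_cast<int>(R::rpois(len)) : 0;
      if (ncx == 0) {
        if (state == 0)
          for (int j = lo; j < hi; ++j) out(g, j) = A(p, j);
        else
          for (int j = lo; j < hi; ++j) out(g, j) = B(p, j);
      } else {
        cx.resize(ncx);
        for (int k = 0; k < ncx; ++k) cx[k] = a + unif_rand() * len;
        std::sort(cx.begin(), cx.end());
        int k = 0;
        for (int j = lo; j < hi; ++j) {
          while (k < ncx && cx[k] < pos[j]) { state ^= 1; ++k; }
          out(g, j) = (state == 0) ? A(p, j) : B(p, j);
        }
      }
    }
  }
  return out;
}
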