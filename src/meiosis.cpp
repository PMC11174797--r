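#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Batch meiosis. One gamete per entry of `parent` (0-based individual index).
// haplo holds two rows per individual (rows 2i and 2i+1). Per chromosome the
// crossover count is Poisson(length in Morgans), crossover positions are
// uniform, there is no interference, and the starting haplotype is a fair
// coin flip. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix meiosis_batch_cpp(const IntegerMatrix& haplo,
                                const IntegerVector& parent,
                                const IntegerVector& chr_start,
                                const IntegerVector& chr_end,
                                const NumericVector& pos,
                                const NumericVector& chr_len) {
  const int m = haplo.ncol();
  const int ng = parent.size();
  const int nchr = chr_len.size();
  IntegerMatrix out(ng, m);
  std::vector<double> xo;
  for (int g = 0; g < ng; ++g) {
    const int r1 = 2 * parent[g];
    const int r2 = r1 + 1;
    for (int c = 0; c < nchr; ++c) {
      const double L = chr_len[c];
      const int nxo = (L > 0.0) ? (int) R::rpois(L) : 0;
      xo.resize(nxo);
      for (int k = 0; k < nxo; ++k) xo[k] = unif_rand() * L;
      std::sort(xo.begin(), xo.end());
      int phase = (unif_rand() < 0.5) ? 0 : 1;
      int k = 0;
      for (int j = chr_start[c]; j <= chr_end[c]; ++j) {
        while (k < nxo && xo[k] <= pos[j]) { phase ^= 1; ++k; }
        out(g, j) = (phase == 0) ? haplo(r1, j) : haplo(r2, j);
      }
    }
  }
  return out;
}
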