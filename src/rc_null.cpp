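#include <Rcpp.h>
#include <vector>
#include <numeric>
#include <algorithm>
using namespace Rcpp;

// Raup-Crick null engine. For each replicate, a null community is built
// for every sample: the sample's observed richness S_x is drawn without
// replacement with probability proportional to occupancy (via exponential
// keys, distributionally identical to sequential weighted sampling), and
// its observed read total N_x is distributed multinomially over the drawn
// taxa proportional to pool-wide relative abundances, with one read per
// drawn taxon guaranteed. Returns, per pair, the counts of null
// Bray-Curtis values below / tied with the observed value. Uses R's RNG,
// so results are reproducible under set.seed().

// [[Rcpp::export]]
NumericMatrix rc_null_counts_cpp(IntegerVector S_x, IntegerVector N_x,
                                 NumericVector occupancy,
                                 NumericVector pool_rel,
                                 NumericVector bc_obs, int n_reps) {
  const int n = S_x.size();
  const int T = occupancy.size();
  const int npairs = n * (n - 1) / 2;
  const double tol = 1e-10;
  NumericVector lt(npairs), eq(npairs);
  std::vector< std::vector<int> > comm(n, std::vector<int>(T));
  std::vector<int> idx(T), fill(T);
  std::vector<double> keys(T), prob(T);
  RNGScope scope;
  for (int r = 0; r < n_reps; ++r) {
    for (int j = 0; j < n; ++j) {
      std::fill(comm[j].begin(), comm[j].end(), 0);
      const int S = S_x[j];
      for (int i = 0; i < T; ++i) keys[i] = ::exp_rand() / occupancy[i];
      std::iota(idx.begin(), idx.end(), 0);
      std::nth_element(idx.begin(), idx.begin() + S - 1, idx.end(),
                       [&](int a, int b) { return keys[a] < keys[b]; });
      double psum = 0.0;
      for (int k = 0; k < S; ++k) psum += pool_rel[idx[k]];
      const int extra = N_x[j] - S;
      if (extra > 0 && psum > 0) {
        for (int k = 0; k < S; ++k) prob[k] = pool_rel[idx[k]] / psum;
        ::rmultinom(extra, prob.data(), S, fill.data());
        for (int k = 0; k < S; ++k) comm[j][idx[k]] = 1 + fill[k];
      } else if (extra > 0) {
        for (int k = 0; k < S; ++k) prob[k] = 1.0 / S;
        ::rmultinom(extra, prob.data(), S, fill.data());
        for (int k = 0; k < S; ++k) comm[j][idx[k]] = 1 + fill[k];
      } else {
        for (int k = 0; k < S; ++k) comm[j][idx[k]] = 1;
      }
    }
    int q = 0;
    for (int a = 0; a < n; ++a) {
      for (int b = a + 1; b < n; ++b, ++q) {
        long num = 0, den = 0;
        const std::vector<int>& xa = comm[a];
        const std::vector<int>& xb = comm[b];
        for (int i = 0; i < T; ++i) {
          const int d = xa[i] - xb[i];
          num += d > 0 ? d : -d;
          den += xa[i] + xb[i];
        }
        const double bc = den > 0 ? (double) num / den : 0.0;
        if (bc < bc_obs[q] - tol) lt[q] += 1.0;
        else if (bc <= bc_obs[q] + tol) eq[q] += 1.0;
      }
    }
    if ((r & 31) == 0) Rcpp::checkUserInterrupt();
  }
  return cbind(lt, eq);
}
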