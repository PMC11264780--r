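#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// betaMNTD engine. relab: taxa x samples relative abundances; D: patristic
// distance matrix over the same taxa (rows of relab); perms: one tip
// permutation per null replicate (1-based, from R's RNG so runs are
// seed-reproducible). A permutation p relocates taxon i to tip p[i], i.e.
// the null shuffles taxon identities uniformly across the tips of the
// pooled tree.
//
// Per replicate, the distance from every pool taxon to its nearest taxon
// in each sample is computed once (O(samples x taxa x richness)); each
// pair's betaMNTD is then an O(richness) weighted sum, which keeps the
// whole null loop linear in the number of samples rather than pairs.

struct Pools {
  std::vector< std::vector<int> > idx;
  std::vector< std::vector<double> > w;
};

static void pair_sums(const Pools& P, const std::vector<double>& dmin,
                      int T, int n, double* out) {
  // dmin laid out [sample][taxon]; out gets n*(n-1)/2 pair values
  int q = 0;
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b, ++q) {
      double s = 0.0;
      const double* db = &dmin[(size_t) b * T];
      for (size_t u = 0; u < P.idx[a].size(); ++u)
        s += P.w[a][u] * db[P.idx[a][u]];
      const double* da = &dmin[(size_t) a * T];
      for (size_t u = 0; u < P.idx[b].size(); ++u)
        s += P.w[b][u] * da[P.idx[b][u]];
      out[q] = 0.5 * s;
    }
  }
}

static void fill_dmin(const Pools& P, const double* Dp, int T, int n,
                      const int* p, std::vector<double>& dmin) {
  // dmin[sample j][taxon i] = min over members m of sample j of D(pi, pm)
  for (int j = 0; j < n; ++j) {
    double* dj = &dmin[(size_t) j * T];
    for (int i = 0; i < T; ++i) {
      const int pi = p ? p[i] : i;
      const double* col = Dp + (size_t) pi * T;  // D symmetric
      double best = R_PosInf;
      for (size_t u = 0; u < P.idx[j].size(); ++u) {
        const int pm = p ? p[P.idx[j][u]] : P.idx[j][u];
        const double d = col[pm];
        if (d < best) best = d;
      }
      dj[i] = best;
    }
  }
}

// [[Rcpp::export]]
List bmntd_engine_cpp(NumericMatrix relab, NumericMatrix D, bool weighted,
                      IntegerMatrix perms) {
  const int T = relab.nrow(), n = relab.ncol();
  Pools P;
  P.idx.resize(n); P.w.resize(n);
  for (int j = 0; j < n; ++j) {
    double tot = 0.0;
    for (int i = 0; i < T; ++i)
      if (relab(i, j) > 0) { P.idx[j].push_back(i); tot += relab(i, j); }
    const int Sj = (int) P.idx[j].size();
    if (Sj == 0) stop("empty sample in betaMNTD input");
    for (int k = 0; k < Sj; ++k)
      P.w[j].push_back(weighted ? relab(P.idx[j][k], j) / tot : 1.0 / Sj);
  }
  const double* Dp = D.begin();
  const int npairs = n * (n - 1) / 2;
  std::vector<double> dmin((size_t) n * T);
  NumericVector obs(npairs);
  fill_dmin(P, Dp, T, n, nullptr, dmin);
  pair_sums(P, dmin, T, n, REAL(obs));
  const int nrep = perms.nrow();
  NumericMatrix nulls(nrep, npairs);
  std::vector<int> p(T);
  std::vector<double> row(npairs);
  for (int r = 0; r < nrep; ++r) {
    for (int i = 0; i < T; ++i) p[i] = perms(r, i) - 1;
    fill_dmin(P, Dp, T, n, p.data(), dmin);
    pair_sums(P, dmin, T, n, row.data());
    for (int q = 0; q < npairs; ++q) nulls(r, q) = row[q];
    if ((r & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["obs"] = obs, _["nulls"] = nulls);
}
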