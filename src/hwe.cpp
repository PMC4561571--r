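// Monte-Carlo version of the Hardy-Weinberg exact (probability) test.
// Conditional on the observed allele counts, genotype configurations are
// sampled by shuffling the 2n allele copies and pairing them; the p-value
// is the (1 + count)/(1 + reps) proportion of configurations with Levene
// conditional probability no larger than the observed one.  Only the
// configuration-dependent part of the log-probability is compared:
//   S = H log 2 - sum_{ij} log(g_ij!)
// (the multinomial terms fixed by the allele counts cancel).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {
double config_score(const std::vector<int> &a, int K,
                    std::vector<int> &gcount) {
  std::fill(gcount.begin(), gcount.end(), 0);
  int n = (int) a.size() / 2, H = 0;
  for (int i = 0; i < n; i++) {
    int x = a[2 * i], y = a[2 * i + 1];
    if (x > y) std::swap(x, y);
    gcount[(x - 1) * K + (y - 1)]++;
    if (x != y) H++;
  }
  double s = H * M_LN2;
  for (size_t j = 0; j < gcount.size(); j++)
    if (gcount[j] > 1) s -= lgamma((double) gcount[j] + 1.0);
  return s;
}
} // namespace

// [[Rcpp::export]]
double cpp_hwe_mc(IntegerVector alleles, int K, int reps) {
  std::vector<int> a(alleles.begin(), alleles.end());
  std::vector<int> gcount(K * K, 0);
  double s_obs = config_score(a, K, gcount);
  int cnt = 0;
  int m = (int) a.size();
  for (int r = 0; r < reps; r++) {
    for (int i = m - 1; i > 0; i--) { // Fisher-Yates with R's RNG
      int j = (int) (unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(a[i], a[j]);
    }
    if (config_score(a, K, gcount) <= s_obs + 1e-9) cnt++;
  }
  return (1.0 + cnt) / (1.0 + reps);
}
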