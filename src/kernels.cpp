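#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Genotype-array switch chain for the Hardy-Weinberg exact test. The
// state is the full ordered assignment of allele labels to the 2n slots
// of n individuals; a step swaps one allele between two random
// individuals. That proposal is symmetric and every swap is accepted: the
// number of ordered states mapping to a genotype count array {n_c} is
// n!/prod(n_c!) * 2^h, so the uniform walk over ordered states visits
// arrays exactly with the conditional probability
//   P(array | allele counts) = n! 2^h prod(m_a!) / ((2n)! prod(n_c!)).
// The p-value is the fraction of visited arrays whose conditional
// probability (tracked up to constants as T = h*log 2 - sum log n_c!) is
// <= the observed one (probability-ordering criterion); the Monte Carlo
// SE comes from batch means. Uses R's RNG: seed with set.seed() first.

// [[Rcpp::export]]
NumericVector hwe_mc_cpp(IntegerVector a1, IntegerVector a2, int k,
                         int dememorisation, int batches, int iter_per_batch) {
  int n = a1.size();
  std::vector<int> g1(n), g2(n);
  std::vector<double> lgam(2 * n + 2);
  for (int i = 0; i <= 2 * n + 1; ++i) lgam[i] = std::lgamma((double)i + 1.0);
  std::vector<int> cnt(k * k, 0);
  const double LOG2 = std::log(2.0);

  double T = 0.0;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    g1[i] = a1[i] - 1;
    g2[i] = a2[i] - 1;
    int lo = std::min(g1[i], g2[i]), hi = std::max(g1[i], g2[i]);
    cnt[lo * k + hi]++;
    if (lo != hi) h++;
  }
  for (int c = 0; c < k * k; ++c) T -= lgam[cnt[c]];
  T += h * LOG2;
  const double T_obs = T;

  long long below_total = 0, done = 0;
  long long below_batch = 0, in_batch = 0;
  std::vector<double> per_batch;
  per_batch.reserve(batches);
  long long total_iter = (long long)dememorisation +
                         (long long)batches * iter_per_batch;

  for (long long it = 0; it < total_iter; ++it) {
    int i = (int)(unif_rand() * n);
    int j = (int)(unif_rand() * (n - 1));
    if (j >= i) j++;
    int pi = unif_rand() < 0.5 ? 0 : 1;
    int pj = unif_rand() < 0.5 ? 0 : 1;
    int ai = pi == 0 ? g1[i] : g2[i];
    int aj = pj == 0 ? g1[j] : g2[j];
    if (ai != aj) {
      int lo1 = std::min(g1[i], g2[i]), hi1 = std::max(g1[i], g2[i]);
      int lo2 = std::min(g1[j], g2[j]), hi2 = std::max(g1[j], g2[j]);
      int ng1i = pi == 0 ? aj : g1[i];
      int ng2i = pi == 1 ? aj : g2[i];
      int ng1j = pj == 0 ? ai : g1[j];
      int ng2j = pj == 1 ? ai : g2[j];
      int nlo1 = std::min(ng1i, ng2i), nhi1 = std::max(ng1i, ng2i);
      int nlo2 = std::min(ng1j, ng2j), nhi2 = std::max(ng1j, ng2j);

      double Tnew = T;
      int hnew = h;
      // remove old genotypes
      Tnew += lgam[cnt[lo1 * k + hi1]] - lgam[cnt[lo1 * k + hi1] - 1];
      cnt[lo1 * k + hi1]--;
      if (lo1 != hi1) hnew--;
      Tnew += lgam[cnt[lo2 * k + hi2]] - lgam[cnt[lo2 * k + hi2] - 1];
      cnt[lo2 * k + hi2]--;
      if (lo2 != hi2) hnew--;
      // add new genotypes
      Tnew -= lgam[cnt[nlo1 * k + nhi1] + 1] - lgam[cnt[nlo1 * k + nhi1]];
      cnt[nlo1 * k + nhi1]++;
      if (nlo1 != nhi1) hnew++;
      Tnew -= lgam[cnt[nlo2 * k + nhi2] + 1] - lgam[cnt[nlo2 * k + nhi2]];
      cnt[nlo2 * k + nhi2]++;
      if (nlo2 != nhi2) hnew++;
      Tnew += (hnew - h) * LOG2;

      g1[i] = ng1i; g2[i] = ng2i; g1[j] = ng1j; g2[j] = ng2j;
      h = hnew;
      T = Tnew;
    }
    if (it >= dememorisation) {
      if (T <= T_obs + 1e-7) { below_total++; below_batch++; }
      done++; in_batch++;
      if (in_batch == iter_per_batch) {
        per_batch.push_back((double)below_batch / iter_per_batch);
        below_batch = 0;
        in_batch = 0;
        // resync T: incremental updates accumulate rounding error, and the
        // probability-ordering comparison needs exact ties at the observed
        // level
        T = h * LOG2;
        for (int c = 0; c < k * k; ++c) T -= lgam[cnt[c]];
      }
    }
  }

  double p = (double)below_total / done;
  int B = per_batch.size();
  double mean = 0.0;
  for (int b = 0; b < B; ++b) mean += per_batch[b];
  mean /= B;
  double v = 0.0;
  for (int b = 0; b < B; ++b) v += (per_batch[b] - mean) * (per_batch[b] - mean);
  double se = B > 1 ? std::sqrt(v / (B - 1) / B) : NA_REAL;
  return NumericVector::create(p, se);
}

// Mantel permutation distribution: Pearson r between the lower triangle of
// A and the jointly row/column-permuted B, for n_perm random permutations.
// Uses R's RNG.

// [[Rcpp::export]]
NumericVector mantel_perm_cpp(NumericMatrix A, NumericMatrix B, int n_perm) {
  int n = A.nrow();
  int m = n * (n - 1) / 2;
  std::vector<double> a(m);
  int l = 0;
  double amean = 0.0;
  for (int j = 1; j < n; ++j)
    for (int i = 0; i < j; ++i) { a[l] = A(i, j); amean += a[l]; ++l; }
  amean /= m;
  double ass = 0.0;
  for (int t = 0; t < m; ++t) { a[t] -= amean; ass += a[t] * a[t]; }
  double asd = std::sqrt(ass);

  std::vector<int> p(n);
  std::vector<double> b(m);
  NumericVector out(n_perm);
  for (int s = 0; s < n_perm; ++s) {
    for (int i = 0; i < n; ++i) p[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      int tmp = p[i]; p[i] = p[j]; p[j] = tmp;
    }
    double bmean = 0.0;
    l = 0;
    for (int j = 1; j < n; ++j)
      for (int i = 0; i < j; ++i) { b[l] = B(p[i], p[j]); bmean += b[l]; ++l; }
    bmean /= m;
    double bss = 0.0, dot = 0.0;
    for (int t = 0; t < m; ++t) {
      double bb = b[t] - bmean;
      bss += bb * bb;
      dot += a[t] * bb;
    }
    out[s] = dot / (asd * std::sqrt(bss));
  }
  return out;
}
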