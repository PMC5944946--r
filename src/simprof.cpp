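#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Internally samples are stored as contiguous columns of an OTUs x samples
// array so the pairwise Bray-Curtis pass vectorises; within-OTU permutation
// shuffles each row across samples.

// Sorted Bray-Curtis similarity profile (ascending, similarity = 1 - d)
// over all sample pairs. T is OTUs x samples, column-contiguous.
static void bc_profile(const std::vector<double> &T, int m, int n,
                       std::vector<double> &tot, std::vector<double> &prof) {
  for (int j = 0; j < n; ++j) {
    const double *col = &T[static_cast<size_t>(j) * m];
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += col[k];
    tot[j] = s;
  }
  int idx = 0;
  for (int i = 0; i < n; ++i) {
    const double *a = &T[static_cast<size_t>(i) * m];
    for (int j = i + 1; j < n; ++j) {
      const double *b = &T[static_cast<size_t>(j) * m];
      double num = 0.0;
      for (int k = 0; k < m; ++k) num += std::fabs(a[k] - b[k]);
      const double den = tot[i] + tot[j];
      prof[idx++] = (den > 0.0) ? 1.0 - num / den : 0.0;
    }
  }
  std::sort(prof.begin(), prof.end());
}

// Fisher-Yates shuffle of every OTU row across samples (R RNG).
static void permute_rows(std::vector<double> &T, int m, int n) {
  for (int k = 0; k < m; ++k) {
    double *row = &T[k];
    for (int i = n - 1; i > 0; --i) {
      const int j = static_cast<int>(unif_rand() * (i + 1));
      std::swap(row[static_cast<size_t>(i) * m],
                row[static_cast<size_t>(j) * m]);
    }
  }
}

// SIMPROF permutation machinery: mean expected profile from n_expected
// within-OTU permutations, pi statistics for the observed profile and for
// n_test further permutations. Uses R's RNG (seed set from the R side).
// [[Rcpp::export]]
List cpp_simprof_core(NumericMatrix X, int n_expected, int n_test) {
  const int n = X.nrow();   // samples
  const int m = X.ncol();   // OTUs
  const int npairs = n * (n - 1) / 2;
  std::vector<double> T(static_cast<size_t>(m) * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < m; ++k)
      T[static_cast<size_t>(i) * m + k] = X(i, k);

  std::vector<double> tot(n), obs(npairs), work(npairs);
  bc_profile(T, m, n, tot, obs);

  std::vector<double> acc(npairs, 0.0);
  for (int p = 0; p < n_expected; ++p) {
    permute_rows(T, m, n);
    bc_profile(T, m, n, tot, work);
    for (int k = 0; k < npairs; ++k) acc[k] += work[k];
  }
  NumericVector mean_prof(npairs);
  for (int k = 0; k < npairs; ++k) mean_prof[k] = acc[k] / n_expected;

  double pi_obs = 0.0;
  for (int k = 0; k < npairs; ++k) pi_obs += std::fabs(obs[k] - mean_prof[k]);
  pi_obs /= npairs;

  NumericVector pi_perm(n_test);
  for (int p = 0; p < n_test; ++p) {
    permute_rows(T, m, n);
    bc_profile(T, m, n, tot, work);
    double s = 0.0;
    for (int k = 0; k < npairs; ++k) s += std::fabs(work[k] - mean_prof[k]);
    pi_perm[p] = s / npairs;
  }

  NumericVector obs_prof(obs.begin(), obs.end());
  return List::create(_["pi_obs"] = pi_obs, _["pi_perm"] = pi_perm,
                      _["mean_profile"] = mean_prof,
                      _["obs_profile"] = obs_prof);
}
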