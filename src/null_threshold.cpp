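#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Island-score threshold for a requested E-value under a random (Poisson)
// background, by seeded Monte Carlo.
//
// Each draw simulates one genome: every window receives an independent
// Poisson(lambda) tag count (the large-n limit of placing n tags uniformly on
// the effective genome), windows with count >= min_count are eligible, runs
// of eligible windows separated by at most gap_windows ineligible windows
// form islands, and an island's score is the sum of -log Poisson pmf over its
// eligible windows.  The returned threshold is the smallest observed island
// score s such that the expected number of islands with score >= s per
// genome is at most e_value; island scores are discrete, so ties at the
// cutoff rank push the threshold up to the next achieved score.  Uses R's
// RNG: seed with set.seed() on the R side.
// [[Rcpp::export(name = ".null_score_threshold_cpp")]]
double null_score_threshold_cpp(int n_draws, IntegerVector windows_per_chrom,
                                double lambda, int min_count, int gap_windows,
                                double e_value) {
  if (n_draws < 1) stop("n_draws must be >= 1");
  if (!(lambda > 0)) stop("lambda must be positive");
  if (min_count < 1) stop("min_count must be >= 1");
  if (ISNAN(e_value) || !(e_value > 0)) stop("e_value must be positive");
  if (e_value == R_PosInf) return 0.0;  // every candidate island passes

  // count-indexed lookup tables: Poisson CDF for inversion sampling and the
  // window score -log pmf; the tail beyond cumulative 1 - 1e-13 collapses
  // onto the last entry (a slight score underestimate for rarer counts,
  // conservative and negligible at that mass)
  int kmax = (int)R::qpois(1e-13, lambda, 0, 0) + 2;
  if (kmax < min_count + 2) kmax = min_count + 2;
  std::vector<double> cdf(kmax + 1), score(kmax + 1);
  double acc = 0.0;
  for (int k = 0; k <= kmax; ++k) {
    acc += R::dpois((double)k, lambda, 0);
    cdf[k] = acc;
    score[k] = (k >= min_count) ? -R::dpois((double)k, lambda, 1) : 0.0;
  }
  cdf[kmax] = 1.0;

  double kd = std::floor((double)n_draws * e_value);
  // e_value below 1/n_draws: nothing observed may pass (K == 0)
  size_t K = (size_t)std::min(kd, 1e18);

  std::vector<double> scores;
  GetRNGstate();
  int n_chrom = windows_per_chrom.size();
  for (int d = 0; d < n_draws; ++d) {
    for (int c = 0; c < n_chrom; ++c) {
      int W = windows_per_chrom[c];
      double cur = 0.0;
      bool open = false;
      int gap_run = 0;
      for (int w = 0; w < W; ++w) {
        double u = unif_rand();
        int k = (int)(std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
        if (k > kmax) k = kmax;
        if (k >= min_count) {
          cur = open ? cur + score[k] : score[k];
          open = true;
          gap_run = 0;
        } else if (open && ++gap_run > gap_windows) {
          scores.push_back(cur);
          open = false; cur = 0.0; gap_run = 0;
        }
      }
      if (open) scores.push_back(cur);
    }
  }
  PutRNGstate();

  if (scores.empty()) return 0.0;          // the null never forms an island
  if (scores.size() <= K) return 0.0;      // everything observed is within E
  double vmax = *std::max_element(scores.begin(), scores.end());
  if (K == 0) return std::nextafter(vmax, R_PosInf);

  // v[K] is the (K+1)-th largest score; any s <= v[K] exceeds the E-value,
  // so take the smallest achieved score strictly above it
  std::nth_element(scores.begin(), scores.begin() + K, scores.end(),
                   std::greater<double>());
  double vK = scores[K];
  double thr = R_PosInf;
  for (size_t i = 0; i < K; ++i) {
    if (scores[i] > vK && scores[i] < thr) thr = scores[i];
  }
  if (thr == R_PosInf) thr = std::nextafter(vK, R_PosInf);
  return thr;
}
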