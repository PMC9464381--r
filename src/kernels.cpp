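#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Expected curable detections for one patient under the sensitivity cascade.
// Occurrence mass of interval i sits at t_occ = i - 0.5 (0-based: i + 0.5);
// the q-th scheduled exam at or after the occurrence interval detects with
// probability sens * (1 - sens)^q, discounted by curability dp^(t_exam - t_occ).
static inline double patient_actual(const NumericMatrix &R, const IntegerMatrix &S,
                                    const int k, const int K,
                                    const std::vector<double> &dpw,
                                    const std::vector<double> &sw) {
  double tot = 0.0;
  for (int i = 0; i < K; ++i) {
    const double mass = R(k, i);
    if (mass <= 0.0) continue;
    int q = 0;
    for (int j = i; j < K; ++j) {
      if (S(k, j)) {
        tot += mass * sw[q] * dpw[j - i];
        ++q;
      }
    }
  }
  return tot;
}

static void make_tables(const int K, const double dp, const double sens,
                        std::vector<double> &dpw, std::vector<double> &sw) {
  dpw.resize(K);
  sw.resize(K);
  for (int d = 0; d < K; ++d) dpw[d] = std::pow(dp, d + 0.5);
  double rem = 1.0;
  for (int q = 0; q < K; ++q) {
    sw[q] = sens * rem;
    rem *= (1.0 - sens);
  }
}

// [[Rcpp::export]]
double n_actual_cpp(NumericMatrix R, IntegerMatrix S, double dp, double sens) {
  const int N = R.nrow(), K = R.ncol();
  std::vector<double> dpw, sw;
  make_tables(K, dp, sens, dpw, sw);
  double tot = 0.0;
  for (int k = 0; k < N; ++k) tot += patient_actual(R, S, k, K, dpw, sw);
  return tot;
}

// Random allocation: slots are drawn one at a time from `draws` (1-based,
// column-major over the N x K grid); a duplicate slot consumes a draw without
// adding an exam. Stops at the first draw after which the accumulated expected
// curable detections reach `target_actual`. Returns draws = -1 if the sequence
// is exhausted before the target is met.
// [[Rcpp::export]]
List ra_allocate_cpp(NumericMatrix R, double dp, double sens,
                     double target_actual, IntegerVector draws) {
  const int N = R.nrow(), K = R.ncol();
  std::vector<double> dpw, sw;
  make_tables(K, dp, sens, dpw, sw);
  IntegerMatrix S(N, K);
  double tot = 0.0;
  int used = -1, exams = 0;
  if (tot >= target_actual) used = 0;
  if (used < 0) {
    const int L = draws.size();
    for (int d = 0; d < L; ++d) {
      const int slot = draws[d] - 1;
      const int k = slot % N, j = slot / N;
      if (!S(k, j)) {
        const double before = patient_actual(R, S, k, K, dpw, sw);
        S(k, j) = 1;
        tot += patient_actual(R, S, k, K, dpw, sw) - before;
        ++exams;
      }
      if (tot >= target_actual) {
        used = d + 1;
        break;
      }
    }
  }
  return List::create(_["schedule"] = S, _["draws"] = used,
                      _["exams"] = exams, _["n_actual"] = tot);
}
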