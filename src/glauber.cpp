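#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Heat-bath (Glauber) dynamics for the pairwise maximum-entropy model
//   P(sigma) ~ exp( beta * ( h . sigma + sum_{i<j} J_ij sigma_i sigma_j ) )
// with sigma_i = +/-1 and symmetric J, zero diagonal. A sweep updates all N
// sites once in a fresh random order; each update sets sigma_i = +1 with its
// conditional probability 1 / (1 + exp(-2 beta f_i)), f_i = h_i + sum_j J_ij
// sigma_j. Local fields are cached and updated incrementally on flips.
// Randomness comes from R's RNG, so set.seed() fully determines the output.

static inline void random_perm(std::vector<int> &perm) {
  const int n = static_cast<int>(perm.size());
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(perm[i], perm[j]);
  }
}

static void init_fields(const NumericVector &h, const NumericMatrix &J,
                        const std::vector<int> &sigma,
                        std::vector<double> &field) {
  const int N = h.size();
  for (int i = 0; i < N; ++i) {
    double f = h[i];
    for (int j = 0; j < N; ++j) f += J(i, j) * sigma[j];
    field[i] = f;
  }
}

static inline void sweep(const NumericMatrix &J, double beta,
                         std::vector<int> &sigma, std::vector<double> &field,
                         std::vector<int> &perm, std::vector<int> *flipped) {
  const int N = static_cast<int>(sigma.size());
  random_perm(perm);
  for (int k = 0; k < N; ++k) {
    const int i = perm[k];
    const double p = 1.0 / (1.0 + std::exp(-2.0 * beta * field[i]));
    const int s_new = (unif_rand() < p) ? 1 : -1;
    if (s_new != sigma[i]) {
      const double d = 2.0 * s_new;   // s_new - s_old
      for (int j = 0; j < N; ++j) field[j] += J(j, i) * d;
      field[i] -= J(i, i) * d;        // diagonal is zero, but keep exact
      sigma[i] = s_new;
      if (flipped && s_new == 1) flipped->push_back(i);
    }
  }
}

// [[Rcpp::export(name = ".glauber_sample_cpp")]]
IntegerMatrix glauber_sample_cpp(NumericVector h, NumericMatrix J, double beta,
                                 int n_samples, int burn_in_sweeps,
                                 int thin_sweeps, IntegerVector init) {
  const int N = h.size();
  std::vector<int> sigma(init.begin(), init.end());
  std::vector<double> field(N);
  std::vector<int> perm(N);
  init_fields(h, J, sigma, field);
  for (int s = 0; s < burn_in_sweeps; ++s)
    sweep(J, beta, sigma, field, perm, nullptr);
  IntegerMatrix out(n_samples, N);
  for (int s = 0; s < n_samples; ++s) {
    for (int t = 0; t < thin_sweeps; ++t)
      sweep(J, beta, sigma, field, perm, nullptr);
    for (int j = 0; j < N; ++j) out(s, j) = (sigma[j] + 1) / 2;
  }
  return out;
}

// First-passage food-detection time: start from the all-empty state
// (sigma = -1 everywhere), run Glauber sweeps, and return the first sweep
// (1-based) by which the food nodes have all (or, with first_only, any)
// ever been occupied. Returns NA if not detected within max_sweeps.
// [[Rcpp::export(name = ".detection_time_cpp")]]
int detection_time_cpp(NumericVector h, NumericMatrix J, double beta,
                       IntegerVector food_idx0, int max_sweeps,
                       bool first_only, IntegerVector init) {
  const int N = h.size();
  std::vector<int> sigma(init.begin(), init.end());
  std::vector<double> field(N);
  std::vector<int> perm(N);
  std::vector<int> food_pos(N, -1);
  const int K = food_idx0.size();
  for (int k = 0; k < K; ++k) food_pos[food_idx0[k]] = k;
  std::vector<bool> seen(K, false);
  int remaining = K;
  init_fields(h, J, sigma, field);
  std::vector<int> flipped;
  for (int s = 1; s <= max_sweeps; ++s) {
    flipped.clear();
    sweep(J, beta, sigma, field, perm, &flipped);
    for (size_t m = 0; m < flipped.size(); ++m) {
      const int k = food_pos[flipped[m]];
      if (k >= 0 && !seen[k]) { seen[k] = true; --remaining; }
    }
    if (first_only ? (remaining < K) : (remaining == 0)) return s;
  }
  return NA_INTEGER;
}
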