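#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Deterministic, platform-independent RNG (splitmix64). The surrogate test
// must give bit-identical verdicts for a (seed, window, pair) triple on any
// build, and must not disturb R's global RNG stream.
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t mix_seed(double seed, double window_index, double pair_index) {
  uint64_t s = 0x8f1bbcdcbfa53e0bULL;
  s ^= (uint64_t)(int64_t)seed;          splitmix64(s);
  s ^= (uint64_t)(int64_t)window_index;  splitmix64(s);
  s ^= (uint64_t)(int64_t)pair_index;    splitmix64(s);
  return s;
}

// bounded draw in [0, n); modulo bias is negligible for n << 2^64
static inline int draw_below(uint64_t &state, int n) {
  return (int)(splitmix64(state) % (uint64_t)n);
}

static double joint_entropy_bits(const std::vector<int> &cnt, int n) {
  double h = 0.0;
  const double invn = 1.0 / (double)n;
  for (size_t k = 0; k < cnt.size(); ++k) {
    if (cnt[k] > 0) {
      double p = cnt[k] * invn;
      h -= p * std::log2(p);
    }
  }
  return h;
}

//' @noRd
// [[Rcpp::export(name = ".surrogate_mi")]]
NumericVector surrogate_mi(IntegerVector bx, IntegerVector by, int b,
                           int n_surrogates, double hx, double hy,
                           double seed, double window_index, double pair_index) {
  const int n = bx.size();
  if (by.size() != n) stop("bin vectors must have equal length");
  uint64_t state = mix_seed(seed, window_index, pair_index);

  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = by[i] - 1;  // 0-based bin of y

  std::vector<int> bx0(n);
  for (int i = 0; i < n; ++i) bx0[i] = (bx[i] - 1) * b;

  std::vector<int> cnt((size_t)b * b);
  NumericVector out(n_surrogates);

  for (int s = 0; s < n_surrogates; ++s) {
    // Fisher-Yates shuffle of the y bins
    for (int i = n - 1; i > 0; --i) {
      int j = draw_below(state, i + 1);
      std::swap(perm[i], perm[j]);
    }
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) cnt[(size_t)(bx0[i] + perm[i])]++;
    out[s] = hx + hy - joint_entropy_bits(cnt, n);
  }
  return out;
}
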