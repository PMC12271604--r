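#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap cost and a fixed
// traceback preference (diagonal, then up = gap in b, then left = gap in a)
// so that co-optimal alignments resolve deterministically.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap) {
  const size_t n = a.size(), m = b.size();
  const size_t W = m + 1;
  std::vector<int> prev(W), cur(W);
  std::vector<signed char> tb((n + 1) * W);  // 0 diag, 1 up, 2 left

  for (size_t j = 0; j <= m; ++j) { prev[j] = (int)j * gap; tb[j] = 2; }
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i * gap;
    tb[i * W] = 1;
    const char ai = a[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      const int sdiag = prev[j - 1] + (ai == b[j - 1] ? match : mismatch);
      const int sup   = prev[j] + gap;
      const int sleft = cur[j - 1] + gap;
      int best = sdiag; signed char dir = 0;
      if (sup > best)   { best = sup;   dir = 1; }
      if (sleft > best) { best = sleft; dir = 2; }
      cur[j] = best;
      tb[i * W + j] = dir;
    }
    std::swap(prev, cur);
  }
  const int score = prev[m];

  std::string r1, r2;
  r1.reserve(n + m); r2.reserve(n + m);
  size_t i = n, j = m;
  while (i > 0 || j > 0) {
    const signed char dir = tb[i * W + j];
    if (i > 0 && j > 0 && dir == 0) {
      r1.push_back(a[i - 1]); r2.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      r1.push_back(a[i - 1]); r2.push_back('-'); --i;
    } else {
      r1.push_back('-'); r2.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(r1.begin(), r1.end());
  std::reverse(r2.begin(), r2.end());
  return List::create(_["aln1"] = r1, _["aln2"] = r2, _["score"] = score);
}

// Alignment statistics for the relief-factor similarity score: M = matching
// columns; G = gap characters lying in maximal gap runs of length >=
// gap_run_min, runs counted per sequence.
// [[Rcpp::export]]
List aln_stats_cpp(std::string aln1, std::string aln2, int gap_run_min) {
  const size_t L = aln1.size();
  long M = 0, G = 0;
  long run1 = 0, run2 = 0;
  for (size_t i = 0; i <= L; ++i) {
    const char c1 = (i < L) ? aln1[i] : 'x';
    const char c2 = (i < L) ? aln2[i] : 'x';
    if (i < L && c1 == c2 && c1 != '-') ++M;
    if (c1 == '-') ++run1; else { if (run1 >= gap_run_min) G += run1; run1 = 0; }
    if (c2 == '-') ++run2; else { if (run2 >= gap_run_min) G += run2; run2 = 0; }
  }
  return List::create(_["M"] = (double)M, _["G"] = (double)G,
                      _["aln_len"] = (double)L);
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Minimizer sketch: in every window of w consecutive k-mers keep the k-mer
// with the minimal hash (leftmost on ties). Hash = splitmix64 of the 2-bit
// encoded k-mer (seed 0), truncated to 53 bits so it is exact in a double.
// Returns 1-based start offsets.
// [[Rcpp::export]]
DataFrame minimizer_sketch_cpp(std::string seq, int k, int w) {
  const long n = (long)seq.size();
  const long nk = n - k + 1;
  std::vector<double> hashes; std::vector<int> offs;
  if (nk < 1 || k < 1 || w < 1)
    return DataFrame::create(_["hash"] = NumericVector(0),
                             _["offset"] = IntegerVector(0));
  std::vector<uint64_t> hv((size_t)nk);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t v = 0;
  for (long i = 0; i < n; ++i) {
    uint64_t code;
    switch (seq[i]) {
      case 'A': case 'a': code = 0; break;
      case 'C': case 'c': code = 1; break;
      case 'G': case 'g': code = 2; break;
      case 'T': case 't': code = 3; break;
      default: code = 0;
    }
    v = ((v << 2) | code) & mask;
    if (i >= k - 1) hv[(size_t)(i - k + 1)] = splitmix64(v) >> 11;
  }
  const long nwin = (nk >= w) ? (nk - w + 1) : 1;
  const long wl = (nk >= w) ? w : nk;
  long last_off = -1;
  for (long s = 0; s < nwin; ++s) {
    long best = s;
    for (long j = s + 1; j < s + wl; ++j)
      if (hv[(size_t)j] < hv[(size_t)best]) best = j;
    if (best != last_off) {
      hashes.push_back((double)hv[(size_t)best]);
      offs.push_back((int)best + 1);
      last_off = best;
    }
  }
  return DataFrame::create(_["hash"] = hashes, _["offset"] = offs);
}
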