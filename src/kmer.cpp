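#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default:  return -1;
  }
}

// Sliding-window word counter. Windows containing any non-ACGT character are
// skipped (the run-length counter resets); counting is case-insensitive.
// [[Rcpp::export]]
IntegerVector count_words_cpp(const std::string& seq, int k) {
  const long long B = 1LL << (2 * k);
  IntegerVector counts((R_xlen_t)B);
  const long long mask = B - 1;
  long long idx = 0, n_windows = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; idx = 0; continue; }
    idx = ((idx << 2) | c) & mask;
    if (++run >= k) { counts[(R_xlen_t)idx]++; n_windows++; }
  }
  counts.attr("n_windows") = (double)n_windows;
  return counts;
}

// Order-m Markov chain sampler. `probs` has 4^m rows (contexts in
// lexicographic order, A<C<G<T) and 4 columns of next-base probabilities.
// The first m bases are uniform. Uses R's RNG (seedable from R).
// [[Rcpp::export]]
std::string sample_markov_cpp(const NumericMatrix& probs, int m, int length) {
  const int n_ctx = probs.nrow();
  std::vector<double> cum((size_t)n_ctx * 4);
  for (int r = 0; r < n_ctx; ++r) {
    double s = 0.0;
    for (int j = 0; j < 4; ++j) { s += probs(r, j); cum[(size_t)r * 4 + j] = s; }
  }
  static const char bases[] = "ACGT";
  std::string out((size_t)length, 'A');
  long long ctx = 0;
  const long long mask = n_ctx - 1;
  for (int i = 0; i < length; ++i) {
    int b;
    if (i < m) {
      b = (int)(unif_rand() * 4.0); if (b > 3) b = 3;
    } else {
      double u = unif_rand() * cum[(size_t)ctx * 4 + 3];
      b = 0;
      while (b < 3 && u > cum[(size_t)ctx * 4 + b]) ++b;
    }
    out[(size_t)i] = bases[b];
    if (m > 0) ctx = ((ctx << 2) | b) & mask;
  }
  return out;
}

static inline long long word_at(const std::vector<int>& codes, long long s, int k) {
  long long idx = 0;
  for (int t = 0; t < k; ++t) idx = (idx << 2) | codes[(size_t)(s + t)];
  return idx;
}

// Iterative point-mutation experiment with incremental signature updates.
// Maintains, for each word length, the current counts and the running sum of
// squared count differences S from the original sequence, so each snapshot
// distance is O(1): d = 100 * sqrt(S) / n_windows (percent-scale Euclidean).
// The sequence must be pure ACGT (validated in R). Uses R's RNG.
// [[Rcpp::export]]
List mutation_trajectory_cpp(const std::string& seq, double n_iter_d,
                             int snapshot_every, const IntegerVector& ks,
                             bool record_counts) {
  const long long L = (long long)seq.size();
  const long long n_iter = (long long)n_iter_d;
  const int nk = ks.size();

  std::vector<int> codes((size_t)L);
  for (long long i = 0; i < L; ++i) codes[(size_t)i] = base_code(seq[(size_t)i]);

  std::vector<std::vector<long long>> counts0(nk), counts(nk);
  std::vector<double> S(nk, 0.0);
  std::vector<long long> W(nk);
  for (int t = 0; t < nk; ++t) {
    const int k = ks[t];
    const long long B = 1LL << (2 * k), mask = B - 1;
    counts0[t].assign((size_t)B, 0);
    long long idx = 0;
    for (long long i = 0; i < L; ++i) {
      idx = ((idx << 2) | codes[(size_t)i]) & mask;
      if (i >= k - 1) counts0[t][(size_t)idx]++;
    }
    counts[t] = counts0[t];
    W[t] = L - k + 1;
  }

  const long long n_snap = n_iter / snapshot_every + 1;
  NumericVector iterations((R_xlen_t)n_snap);
  NumericMatrix dist((R_xlen_t)n_snap, nk);
  List counts_snapshots(record_counts ? (R_xlen_t)n_snap : 0);

  long long snap_i = 0;
  auto take_snapshot = [&](long long it) {
    iterations[(R_xlen_t)snap_i] = (double)it;
    for (int t = 0; t < nk; ++t)
      dist((R_xlen_t)snap_i, t) = 100.0 * std::sqrt(S[t]) / (double)W[t];
    if (record_counts) {
      List per_k(nk);
      for (int t = 0; t < nk; ++t) {
        IntegerVector cv((R_xlen_t)counts[t].size());
        for (size_t b = 0; b < counts[t].size(); ++b) cv[(R_xlen_t)b] = (int)counts[t][b];
        per_k[t] = cv;
      }
      counts_snapshots[(R_xlen_t)snap_i] = per_k;
    }
    snap_i++;
  };
  take_snapshot(0);

  for (long long it = 1; it <= n_iter; ++it) {
    long long pos = (long long)(unif_rand() * (double)L);
    if (pos >= L) pos = L - 1;
    int nb = (int)(unif_rand() * 4.0);
    if (nb > 3) nb = 3;

    for (int t = 0; t < nk; ++t) {
      const int k = ks[t];
      const long long s0 = pos - k + 1 > 0 ? pos - k + 1 : 0;
      const long long s1 = pos < L - k ? pos : L - k;
      for (long long s = s0; s <= s1; ++s) {
        const long long b = word_at(codes, s, k);
        const double d = (double)(counts[t][(size_t)b] - counts0[t][(size_t)b]);
        S[t] += -2.0 * d + 1.0;
        counts[t][(size_t)b]--;
      }
    }
    codes[(size_t)pos] = nb;
    for (int t = 0; t < nk; ++t) {
      const int k = ks[t];
      const long long s0 = pos - k + 1 > 0 ? pos - k + 1 : 0;
      const long long s1 = pos < L - k ? pos : L - k;
      for (long long s = s0; s <= s1; ++s) {
        const long long b = word_at(codes, s, k);
        const double d = (double)(counts[t][(size_t)b] - counts0[t][(size_t)b]);
        S[t] += 2.0 * d + 1.0;
        counts[t][(size_t)b]++;
      }
    }
    if (it % snapshot_every == 0) take_snapshot(it);
  }

  static const char bases[] = "ACGT";
  std::string final_seq((size_t)L, 'A');
  for (long long i = 0; i < L; ++i) final_seq[(size_t)i] = bases[codes[(size_t)i]];

  List final_counts(nk);
  for (int t = 0; t < nk; ++t) {
    IntegerVector cv((R_xlen_t)counts[t].size());
    for (size_t b = 0; b < counts[t].size(); ++b) cv[(R_xlen_t)b] = (int)counts[t][b];
    cv.attr("n_windows") = (double)W[t];
    final_counts[t] = cv;
  }

  return List::create(_["iterations"] = iterations,
                      _["distance"] = dist,
                      _["final_sequence"] = final_seq,
                      _["final_counts"] = final_counts,
                      _["counts_snapshots"] = counts_snapshots);
}
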