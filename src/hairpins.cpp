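// Inverted-repeat (hairpin) scan.
//
// A hit is a pair of equal-length arms (arm1 before arm2) such that arm2 is
// the reverse complement of arm1 up to a mismatch budget of
// floor(max_mismatch_frac * stem_len), with a loop of at least min_loop
// unpaired bases between the arms.  Hits are *maximal*: neither the outward
// extension (one base added before arm1 and after arm2) nor the inward
// extension (one base added after arm1 and before arm2) is itself valid
// (budget for the extended length, loop and sequence bounds, stem cap).
//
// Pairs (u, v) with u + v = s lie on one anti-diagonal; a stem is a
// contiguous window of pair indices t (u = t, v = s - t).  Every valid
// window of length L with k = floor(frac * L) mismatches contains a pure
// complementary run of length >= ceil((L - k) / (k + 1)); scanning is
// seeded at such runs, so the full O(n^2) pair space is touched only by a
// cheap match pass.

#include <Rcpp.h>
#include <set>
#include <tuple>
#include <cmath>
using namespace Rcpp;

static inline bool comp_match(char a, char b) {
  switch (a) {
    case 'A': return b == 'T';
    case 'T': return b == 'A';
    case 'C': return b == 'G';
    case 'G': return b == 'C';
  }
  return false;
}

static inline int budget(int L, double frac) {
  return (int)std::floor(frac * L + 1e-9);
}

// [[Rcpp::export]]
IntegerMatrix hairpin_scan_cpp(std::string seq, int min_stem, double frac,
                               int min_loop, int max_stem) {
  const int n = (int)seq.size();
  std::set<std::tuple<int, int, int>> hits;  // (a1s, a1e, a2s) 1-based

  std::vector<int> budget_tab(max_stem + 2, 0);
  for (int L = 0; L <= max_stem + 1; ++L) budget_tab[L] = budget(L, frac);
  const int budget_max = budget_tab[max_stem];

  // smallest pure run any valid window must contain
  int minrun = max_stem;
  for (int L = min_stem; L <= max_stem; ++L) {
    int r = L / (budget_tab[L] + 1);  // == ceil((L-k)/(k+1))
    if (r < minrun) minrun = r;
  }
  if (minrun < 1) minrun = 1;

  // 2-bit base codes; complementary pairs sum to 3 (A+T, C+G)
  std::vector<unsigned char> code(n, 255);
  for (int i = 0; i < n; ++i) {
    switch (seq[i]) {
      case 'A': code[i] = 0; break;
      case 'C': code[i] = 1; break;
      case 'G': code[i] = 2; break;
      case 'T': code[i] = 3; break;
    }
  }
  const unsigned char* cc = code.data();

  std::vector<int> C(n / 2 + 2);  // mismatch prefix sums over [tmin, tmax]
  std::vector<std::pair<int, int>> runs;

  for (int s = 1; s <= 2 * n - 2; ++s) {
    int tmin = std::max(0, s - n + 1);
    int tmax = (s - min_loop - 1) / 2;  // loop constraint on t2
    if (s - min_loop - 1 < 0) continue;
    if (tmax - tmin + 1 < min_stem) continue;
    int len = tmax - tmin + 1;
    int* Cp = C.data();
    Cp[0] = 0;
    runs.clear();  // (rs, re) of maximal pure match runs >= minrun
    {
      const unsigned char* fwd = cc + tmin;
      const unsigned char* rev = cc + s - tmin;
      int acc = 0;
      int run_start = 0;
      for (int i = 0; i < len; ++i) {
        int mm = (int)(fwd[i] + *(rev - i) != 3);
        if (mm) {
          if (i - run_start >= minrun) runs.push_back({run_start, i - 1});
          run_start = i + 1;
        }
        acc += mm;
        Cp[i + 1] = acc;
      }
      if (len - run_start >= minrun) runs.push_back({run_start, len - 1});
    }
    if (runs.empty()) continue;
    // validity of window [a, b] in local coordinates
    auto valid = [&](int a, int b) -> bool {
      if (a < 0 || b >= len) return false;
      int L = b - a + 1;
      if (L < min_stem || L > max_stem) return false;
      return (C[b + 1] - C[a]) <= budget_tab[L];
    };
    // enumerate candidate windows around each seed run
    for (const auto& run : runs) {
      int rs = run.first, re = run.second;
      // a valid window overlaps this run by >= minrun positions, so
      // a <= re - minrun + 1 and b >= rs + minrun - 1; and since b >= rs,
      // mismatches accumulated before the run already count against the
      // largest budget: drop a with C[rs] - C[a] > budget_max
      int a_lo = std::max(0, rs - max_stem + 1);
      while (a_lo < rs && C[rs] - C[a_lo] > budget_max) ++a_lo;
      int a_hi = re - minrun + 1;
      for (int a = a_lo; a <= a_hi; ++a) {
        int b_hi = std::min(a + max_stem - 1, len - 1);
        int b_lo = std::max(a + min_stem - 1, rs + minrun - 1);
        for (int b = b_lo; b <= b_hi; ++b) {
          if (C[b + 1] - C[a] > budget_max) break;  // mm only grows with b
          if (!valid(a, b)) continue;
          if (valid(a - 1, b) || valid(a, b + 1)) continue;
          int t1 = a + tmin, t2 = b + tmin;
          hits.insert(std::make_tuple(t1 + 1, t2 + 1, s - t2 + 1));
        }
      }
    }
  }

  IntegerMatrix out((int)hits.size(), 7);
  colnames(out) = CharacterVector::create("a1_start", "a1_end", "a2_start",
                                          "a2_end", "stem", "mismatches",
                                          "loop");
  int i = 0;
  for (const auto& h : hits) {
    int a1s = std::get<0>(h), a1e = std::get<1>(h), a2s = std::get<2>(h);
    int L = a1e - a1s + 1;
    int a2e = a2s + L - 1;
    int mm = 0;
    for (int k = 0; k < L; ++k) {
      if (!comp_match(seq[a1s - 1 + k], seq[a2e - 1 - k])) ++mm;
    }
    out(i, 0) = a1s; out(i, 1) = a1e; out(i, 2) = a2s; out(i, 3) = a2e;
    out(i, 4) = L;   out(i, 5) = mm;  out(i, 6) = a2s - a1e - 1;
    ++i;
  }
  return out;
}
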