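// Scanning and null-model kernels.
//
// Sequences and patterns arrive as base bitmasks (A=1, C=2, G=4, T=8; a
// subject position with mask 0 -- e.g. an N -- matches nothing).  The
// occurrence-count DP and the Monte Carlo sampler both run a Shift-And
// automaton whose state is the bitmask of pattern prefixes matching at the
// current position; the state space is enumerated by BFS so only reachable
// states are carried.

#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_scan_bits(IntegerVector seq, IntegerVector pat) {
  const int L = seq.size(), m = pat.size();
  if (m < 1) stop("empty pattern");
  std::vector<int> out;
  for (int i = 0; i + m <= L; ++i) {
    bool ok = true;
    for (int j = 0; j < m; ++j) {
      if (!(seq[i + j] & pat[j])) { ok = false; break; }
    }
    if (ok) out.push_back(i);  // 0-based
  }
  return wrap(out);
}

struct Automaton {
  int m;
  int match_mask[4];            // bit j set iff base b matches pattern pos j
  int smask;                    // proper-prefix state bits
  std::vector<int> states;
  std::vector<std::array<int, 4> > trans;
  std::vector<std::array<int, 4> > emit;
};

static Automaton build_automaton(const IntegerVector &pat) {
  Automaton a;
  a.m = pat.size();
  if (a.m < 1) stop("empty pattern");
  if (a.m > 16) stop("pattern longer than 16 nt: automaton state space too large");
  for (int b = 0; b < 4; ++b) {
    a.match_mask[b] = 0;
    for (int j = 0; j < a.m; ++j)
      if (pat[j] & (1 << b)) a.match_mask[b] |= (1 << j);
  }
  a.smask = (a.m > 1) ? ((1 << (a.m - 1)) - 1) : 0;
  std::vector<int> id(a.smask + 1, -1);
  a.states.push_back(0);
  id[0] = 0;
  for (size_t qi = 0; qi < a.states.size(); ++qi) {
    int s = a.states[qi];
    std::array<int, 4> tr, em;
    for (int b = 0; b < 4; ++b) {
      int full = ((s << 1) | 1) & a.match_mask[b];
      em[b] = (full >> (a.m - 1)) & 1;
      int ns = full & a.smask;
      if (id[ns] < 0) {
        id[ns] = (int)a.states.size();
        a.states.push_back(ns);
      }
      tr[b] = id[ns];
    }
    a.trans.push_back(tr);
    a.emit.push_back(em);
  }
  return a;
}

// Exact distribution of the number of (overlapping) match positions in an
// i.i.d. sequence of length L; counts >= cap are lumped into the last entry.
// [[Rcpp::export]]
NumericVector cpp_occurrence_dp(IntegerVector pat, int L, NumericVector freq, int cap) {
  if (L < 0) stop("L must be >= 0");
  if (cap < 1) stop("cap must be >= 1");
  if (freq.size() != 4) stop("freq must have 4 entries (A, C, G, T)");
  Automaton a = build_automaton(pat);
  const int n = (int)a.states.size(), C = cap + 1;
  std::vector<double> P((size_t)n * C, 0.0), Q((size_t)n * C, 0.0);
  P[0] = 1.0;
  for (int step = 0; step < L; ++step) {
    std::fill(Q.begin(), Q.end(), 0.0);
    for (int s = 0; s < n; ++s) {
      const double *ps = &P[(size_t)s * C];
      for (int b = 0; b < 4; ++b) {
        const double f = freq[b];
        if (f == 0.0) continue;
        double *qt = &Q[(size_t)a.trans[s][b] * C];
        if (a.emit[s][b]) {
          for (int c = 0; c < C; ++c) {
            int nc = c + 1; if (nc > cap) nc = cap;
            qt[nc] += ps[c] * f;
          }
        } else {
          for (int c = 0; c < C; ++c) qt[c] += ps[c] * f;
        }
      }
    }
    P.swap(Q);
  }
  NumericVector out(C);
  for (int c = 0; c < C; ++c) {
    double acc = 0.0;
    for (int s = 0; s < n; ++s) acc += P[(size_t)s * C + c];
    out[c] = acc;
  }
  return out;
}

// Number of simulated i.i.d. sequences (out of reps) holding >= k matches.
// Uses R's RNG, so set.seed() in R makes runs reproducible.
// [[Rcpp::export]]
int cpp_mc_tail(IntegerVector pat, int L, int k, NumericVector freq, int reps) {
  if (reps < 1) stop("reps must be >= 1");
  if (L < 0) stop("L must be >= 0");
  if (k < 0) stop("k must be >= 0");
  if (freq.size() != 4) stop("freq must have 4 entries (A, C, G, T)");
  Automaton a = build_automaton(pat);
  const double c0 = freq[0], c1 = c0 + freq[1], c2 = c1 + freq[2];
  int succ = 0;
  for (int r = 0; r < reps; ++r) {
    int state = 0, cnt = 0;
    for (int i = 0; i < L && cnt < k; ++i) {
      double u = unif_rand();
      int b = (u < c0) ? 0 : (u < c1) ? 1 : (u < c2) ? 2 : 3;
      cnt += a.emit[state][b];
      state = a.trans[state][b];
    }
    if (cnt >= k) ++succ;
  }
  return succ;
}
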