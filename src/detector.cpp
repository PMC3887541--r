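// Tandem-repeat detection primitives.
//
// Three pieces live in compiled code because they run over megabase-scale
// sequence: maximal perfect-run enumeration, wraparound dynamic programming
// against indefinite unit repetitions, and the seed-and-extend scan that
// combines them. Coordinates are 0-based half-open throughout.

#include <Rcpp.h>
#include <climits>
#include <cstdint>
using namespace Rcpp;

static const int NEG = INT_MIN / 4; // safe -infinity under addition

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline int base_idx(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

// Smallest period via the KMP failure function; a unit is primitive iff
// smallest_period(u) == |u|.
static int smallest_period(const std::string &u) {
  const int n = (int)u.size();
  std::vector<int> f(n + 1, 0);
  int k = 0;
  for (int i = 1; i < n; ++i) {
    while (k > 0 && u[i] != u[k]) k = f[k];
    if (u[i] == u[k]) ++k;
    f[i + 1] = k;
  }
  const int p = n - f[n];
  return (n % p == 0) ? p : n;
}

// ---------------------------------------------------------------------------
// Maximal perfect runs
//
// For each unit size u, positions i with s[i] == s[i+u] (both valid bases)
// form runs; a maximal run of r such positions is a tandem span [i, i+r+u)
// with period u. The span is kept when the leading unit is primitive, the
// span has >= 2 full copies (r >= u) and length >= min_length.
// ---------------------------------------------------------------------------

struct PerfectRun {
  int start, end, ulen;
};

static void scan_perfect(const std::string &s, const std::vector<char> &valid,
                         int max_unit, int min_length, int min_copies_len_r,
                         std::vector<PerfectRun> &out) {
  const int n = (int)s.size();
  for (int u = 1; u <= max_unit; ++u) {
    if (2 * u > n) break;
    int i = 0;
    while (i + u < n) {
      if (valid[i] && valid[i + u] && s[i] == s[i + u]) {
        int j = i;
        while (j + u < n && valid[j] && valid[j + u] && s[j] == s[j + u]) ++j;
        const int r = j - i;           // matched positions
        const int L = r + u;           // span length
        if (r >= u && L >= min_length && (min_copies_len_r <= 0 || r >= min_copies_len_r)) {
          if (smallest_period(s.substr(i, u)) == u)
            out.push_back({i, i + L, u});
        }
        i = j + 1;
      } else {
        ++i;
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_detect_perfect(std::string seq, int max_unit, int min_length) {
  const int n = (int)seq.size();
  std::vector<char> valid(n);
  for (int i = 0; i < n; ++i) valid[i] = is_acgt(seq[i]);
  std::vector<PerfectRun> runs;
  scan_perfect(seq, valid, max_unit, min_length, 0, runs);
  const int m = (int)runs.size();
  IntegerVector st(m), en(m);
  CharacterVector un(m);
  for (int k = 0; k < m; ++k) {
    st[k] = runs[k].start;
    en[k] = runs[k].end;
    un[k] = seq.substr(runs[k].start, runs[k].ulen);
  }
  return DataFrame::create(_["start"] = st, _["end"] = en, _["unit"] = un,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Wraparound DP: global-in-window alignment against u^inf with free start and
// end phase. State (i, j): i window chars consumed, next reference char is
// unit[j]. Moves: diagonal (consume both), up (gap in reference), left-with-
// wrap (gap in window). Within-row deletion relaxation runs two ascending
// passes so paths may cross the column wrap.
// ---------------------------------------------------------------------------

struct Aln {
  int score, nm, nx, ni, start_phase;
  std::string consensus;
};

static Aln wrap_align(const char *w, int m, const std::string &unit,
                      int match, int mismatch, int indel) {
  const int u = (int)unit.size();
  std::vector<int> prev(u, 0), cur(u, 0);
  std::vector<uint8_t> ptr((size_t)(m + 1) * u, 0); // 1=diag 2=up 3=left

  for (int i = 1; i <= m; ++i) {
    const char c = w[i - 1];
    for (int j = 0; j < u; ++j) {
      const int jm = (j + u - 1) % u;
      const int sd = prev[jm] + (c == unit[jm] ? match : mismatch);
      const int su = prev[j] + indel;
      if (sd >= su) { cur[j] = sd; ptr[(size_t)i * u + j] = 1; }
      else          { cur[j] = su; ptr[(size_t)i * u + j] = 2; }
    }
    for (int pass = 0; pass < 2; ++pass) {
      for (int j = 0; j < u; ++j) {
        const int jm = (j + u - 1) % u;
        const int sl = cur[jm] + indel;
        if (sl > cur[j]) { cur[j] = sl; ptr[(size_t)i * u + j] = 3; }
      }
    }
    std::swap(prev, cur);
  }

  int jbest = 0;
  for (int j = 1; j < u; ++j)
    if (prev[j] > prev[jbest]) jbest = j;

  Aln a;
  a.score = prev[jbest];
  a.nm = a.nx = a.ni = 0;

  // traceback for counts and per-column consensus votes
  std::vector<std::array<int, 4> > votes(u, {0, 0, 0, 0});
  int i = m, j = jbest;
  while (i > 0) {
    const uint8_t p = ptr[(size_t)i * u + j];
    if (p == 1) {
      const int jm = (j + u - 1) % u;
      const char c = w[i - 1];
      votes[jm][base_idx(c)] += 1;
      if (c == unit[jm]) ++a.nm; else ++a.nx;
      --i;
      j = jm;
    } else if (p == 2) {
      ++a.ni;
      --i;
    } else { // p == 3
      ++a.ni;
      j = (j + u - 1) % u;
    }
  }
  a.start_phase = j;

  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  a.consensus = unit;
  for (int k = 0; k < u; ++k) {
    int tot = votes[k][0] + votes[k][1] + votes[k][2] + votes[k][3];
    if (tot == 0) continue; // uncovered column keeps the reference base
    int best = 0;
    for (int b = 1; b < 4; ++b)
      if (votes[k][b] > votes[k][best]) best = b;
    // tie goes to the reference base when it is among the maxima
    const int ref = base_idx(unit[k]);
    if (ref >= 0 && votes[k][ref] == votes[k][best]) best = ref;
    a.consensus[k] = BASES[best];
  }
  return a;
}

// [[Rcpp::export]]
List cpp_align_repeat(std::string window, std::string unit,
                      int match, int mismatch, int indel) {
  Aln a = wrap_align(window.c_str(), (int)window.size(), unit,
                     match, mismatch, indel);
  return List::create(_["score"] = a.score, _["n_match"] = a.nm,
                      _["n_mismatch"] = a.nx, _["n_indel"] = a.ni,
                      _["consensus"] = a.consensus,
                      _["start_phase"] = a.start_phase);
}

// Extension DP with start phase fixed at 0 of `unit` (caller pre-rotates /
// reverses). Walks away from the seed in direction `step`, stops at invalid
// bases, sequence ends, or when the best row score has dropped more than
// `dropoff` below the running maximum. Returns the arg-max prefix length and
// its score gain.
static void extend_dp(const std::string &s, int start_idx, int step,
                      const std::string &unit, int match, int mismatch,
                      int indel, int dropoff, int &best_len, int &best_gain) {
  const int n = (int)s.size();
  const int u = (int)unit.size();
  std::vector<int> prev(u, NEG), cur(u, NEG);
  prev[0] = 0;
  best_len = 0;
  best_gain = 0;
  int i = 0, idx = start_idx;
  while (idx >= 0 && idx < n) {
    const char c = s[idx];
    if (!is_acgt(c)) break;
    ++i;
    for (int j = 0; j < u; ++j) {
      const int jm = (j + u - 1) % u;
      const int sd = (prev[jm] <= NEG) ? NEG
                     : prev[jm] + (c == unit[jm] ? match : mismatch);
      const int su = (prev[j] <= NEG) ? NEG : prev[j] + indel;
      cur[j] = sd >= su ? sd : su;
    }
    for (int pass = 0; pass < 2; ++pass)
      for (int j = 0; j < u; ++j) {
        const int jm = (j + u - 1) % u;
        if (cur[jm] > NEG && cur[jm] + indel > cur[j]) cur[j] = cur[jm] + indel;
      }
    int rowmax = cur[0];
    for (int j = 1; j < u; ++j)
      if (cur[j] > rowmax) rowmax = cur[j];
    if (rowmax > best_gain) { best_gain = rowmax; best_len = i; }
    if (best_gain - rowmax > dropoff) break;
    std::swap(prev, cur);
    idx += step;
  }
}

// ---------------------------------------------------------------------------
// Seed-and-extend detector. Seeds are maximal perfect runs with >= 2 exact
// copies and length >= max(2u, seed_floor); each seed is extended in both
// directions under the drop-off rule and the chosen window is re-scored with
// a free-phase wraparound alignment. Thresholds are applied on the re-scored
// window; further filtering (copy number, primitivity of the consensus,
// overlap resolution) happens in R.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_detect(std::string seq, int max_unit, int min_length,
                     int min_score, int match, int mismatch, int indel,
                     int dropoff, int seed_floor) {
  const int n = (int)seq.size();
  std::vector<char> valid(n);
  for (int i = 0; i < n; ++i) valid[i] = is_acgt(seq[i]);

  std::vector<int> st, en, sc, nm, nx, ni;
  std::vector<std::string> un;

  for (int u = 1; u <= max_unit; ++u) {
    if (2 * u > n) break;
    const int seed_min = std::max(2 * u, seed_floor);
    int i = 0;
    while (i + u < n) {
      if (valid[i] && valid[i + u] && seq[i] == seq[i + u]) {
        int j = i;
        while (j + u < n && valid[j] && valid[j + u] && seq[j] == seq[j + u]) ++j;
        const int r = j - i;
        const int L = r + u;
        if (r >= u && L >= seed_min) {
          const std::string unit = seq.substr(i, u);
          if (smallest_period(unit) == u) {
            // right: next expected base is unit[L % u]
            const int ph = L % u;
            std::string runit = unit.substr(ph) + unit.substr(0, ph);
            int rlen, rgain;
            extend_dp(seq, i + L, +1, runit, match, mismatch, indel, dropoff,
                      rlen, rgain);
            // left: reversed flank against reversed unit (seed starts in
            // phase 0, so leftward the first expected base is unit[u-1])
            std::string lunit(unit.rbegin(), unit.rend());
            int llen, lgain;
            extend_dp(seq, i - 1, -1, lunit, match, mismatch, indel, dropoff,
                      llen, lgain);
            const int total = L * match + lgain + rgain;
            // re-score windows with any headroom near the threshold; the
            // free-phase score can only exceed the seed-constrained one
            if (total >= min_score - 4) {
              const int ws = i - llen, we = i + L + rlen;
              Aln a = wrap_align(seq.c_str() + ws, we - ws, unit,
                                 match, mismatch, indel);
              if (a.score >= min_score && we - ws >= min_length) {
                std::string obs = a.consensus.substr(a.start_phase) +
                                  a.consensus.substr(0, a.start_phase);
                st.push_back(ws);
                en.push_back(we);
                un.push_back(obs);
                sc.push_back(a.score);
                nm.push_back(a.nm);
                nx.push_back(a.nx);
                ni.push_back(a.ni);
              }
            }
          }
        }
        i = j + 1;
      } else {
        ++i;
      }
    }
  }

  return DataFrame::create(
      _["start"] = wrap(st), _["end"] = wrap(en), _["unit"] = wrap(un),
      _["score"] = wrap(sc), _["n_match"] = wrap(nm),
      _["n_mismatch"] = wrap(nx), _["n_indel"] = wrap(ni),
      _["stringsAsFactors"] = false);
}

// Per-interval A/C/G/T counts over 0-based half-open intervals.
// [[Rcpp::export]]
IntegerMatrix cpp_base_counts(std::string seq, IntegerVector starts,
                              IntegerVector ends) {
  const int n = (int)seq.size();
  const int m = starts.size();
  IntegerMatrix out(m, 4);
  colnames(out) = CharacterVector::create("A", "C", "G", "T");
  for (int k = 0; k < m; ++k) {
    const int a = std::max(0, (int)starts[k]);
    const int b = std::min(n, (int)ends[k]);
    int cnt[4] = {0, 0, 0, 0};
    for (int i = a; i < b; ++i) {
      const int bi = base_idx(seq[i]);
      if (bi >= 0) ++cnt[bi];
    }
    for (int c = 0; c < 4; ++c) out(k, c) = cnt[c];
  }
  return out;
}
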