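// Sliding-window edit-distance scan of degenerate repeat motifs.
// Motifs may contain IUPAC ambiguity codes; a window base matches a motif
// position when it belongs to the position's allowed set (so one degenerate
// consensus stands for the whole family of resolved motifs).  The per-position
// score is (L - min edit distance over the db) / L, computed with a banded DP
// clamped at max_edit + 1: scores below (L - max_edit - 1) / L are reported at
// that floor, which is irrelevant for peak calling at thresholds near 0.85.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline uint8_t iupac_mask(char c) {
  switch (c) {
  case 'A': case 'a': return 1;
  case 'C': case 'c': return 2;
  case 'G': case 'g': return 4;
  case 'T': case 't': case 'U': case 'u': return 8;
  case 'R': case 'r': return 1 | 4;
  case 'Y': case 'y': return 2 | 8;
  case 'S': case 's': return 2 | 4;
  case 'W': case 'w': return 1 | 8;
  case 'K': case 'k': return 4 | 8;
  case 'M': case 'm': return 1 | 2;
  case 'B': case 'b': return 2 | 4 | 8;
  case 'D': case 'd': return 1 | 4 | 8;
  case 'H': case 'h': return 1 | 2 | 8;
  case 'V': case 'v': return 1 | 2 | 4;
  case 'N': case 'n': return 15;
  default: return 0; // never matches
  }
}

// banded global edit distance (unit costs) between window w (length L) and
// motif m (length L); band half-width = maxd; early abandon above `cap`.
// Match = set intersection non-empty.  Returns min(dist, cap + 1).
static int banded_edit(const uint8_t *w, const uint8_t *m, int L, int cap) {
  const int band = cap + 1;
  std::vector<int> prev(2 * band + 1), cur(2 * band + 1);
  const int BIG = 1000;
  // row i (motif), offsets j - i in [-band, band]
  for (int o = -band; o <= band; ++o) prev[o + band] = (o >= 0) ? o : BIG;
  for (int i = 1; i <= L; ++i) {
    int rowmin = BIG;
    for (int o = -band; o <= band; ++o) {
      int j = i + o;
      if (j < 0 || j > L) { cur[o + band] = BIG; continue; }
      int best = BIG;
      if (j > 0) { // diagonal: prev row, col j-1 => same offset o
        int d = prev[o + band];
        if (d < BIG) {
          bool match = (w[j - 1] & m[i - 1]) != 0;
          best = d + (match ? 0 : 1);
        }
      }
      if (o + 1 <= band) { // deletion in window dim? up: prev row j => offset j-(i-1)=o+1
        int d = prev[o + 1 + band];
        if (d < BIG && d + 1 < best) best = d + 1;
      }
      if (j > 0 && o - 1 >= -band) { // left: same row j-1 => offset o-1
        int d = cur[o - 1 + band];
        if (d < BIG && d + 1 < best) best = d + 1;
      }
      cur[o + band] = best;
      if (best < rowmin) rowmin = best;
    }
    if (rowmin > cap) return cap + 1;
    std::swap(prev, cur);
  }
  int res = prev[0 + band]; // offset L - L = 0
  return std::min(res, cap + 1);
}

// [[Rcpp::export]]
NumericVector cpp_motif_track(std::string seq, std::vector<std::string> motifs,
                              int max_edit = 8) {
  if (motifs.empty()) stop("empty motif database");
  const int L = (int)motifs[0].size();
  for (auto &m : motifs)
    if ((int)m.size() != L) stop("all motifs must have the same length");
  const int n = (int)seq.size();
  if (n < L) return NumericVector(0);
  std::vector<std::vector<uint8_t>> mm(motifs.size());
  for (size_t i = 0; i < motifs.size(); ++i) {
    mm[i].resize(L);
    for (int j = 0; j < L; ++j) mm[i][j] = iupac_mask(motifs[i][j]);
  }
  std::vector<uint8_t> sm(n);
  for (int i = 0; i < n; ++i) sm[i] = iupac_mask(seq[i]);
  NumericVector out(n - L + 1);
  for (int p = 0; p + L <= n; ++p) {
    int best = max_edit + 1;
    for (size_t mi = 0; mi < mm.size() && best > 0; ++mi) {
      // cheap Hamming upper bound first
      int ham = 0;
      const uint8_t *mo = mm[mi].data();
      for (int j = 0; j < L && ham <= max_edit; ++j)
        if (!(sm[p + j] & mo[j])) ++ham;
      int d;
      if (ham == 0) d = 0;
      else if (ham <= best) d = std::min(ham, banded_edit(sm.data() + p, mo, L, std::min(best - 1, max_edit)));
      else d = banded_edit(sm.data() + p, mo, L, std::min(best - 1, max_edit));
      if (d < best) best = d;
    }
    out[p] = (double)(L - best) / (double)L;
  }
  return out;
}

// Semi-global alignment of a motif (global) against a region of sequence
// (free ends): returns c(start, end, dist) where [start, end) is the spanned
// region interval (0-based, relative to `region`) of the best alignment.
// Used to decide whether a detected repeat unit spans exactly L bases.
// [[Rcpp::export]]
IntegerVector cpp_motif_span(std::string region, std::string motif) {
  const int L = (int)motif.size(), n = (int)region.size();
  std::vector<uint8_t> r(n), m(L);
  for (int i = 0; i < n; ++i) r[i] = iupac_mask(region[i]);
  for (int i = 0; i < L; ++i) m[i] = iupac_mask(motif[i]);
  // dp[i][j]: edit distance of motif[0..i) vs region[..j) with free start
  std::vector<std::vector<int>> dp(L + 1, std::vector<int>(n + 1));
  std::vector<std::vector<int>> st(L + 1, std::vector<int>(n + 1)); // start col
  for (int j = 0; j <= n; ++j) { dp[0][j] = 0; st[0][j] = j; }
  for (int i = 1; i <= L; ++i) {
    dp[i][0] = i; st[i][0] = 0;
    for (int j = 1; j <= n; ++j) {
      int diag = dp[i - 1][j - 1] + (((r[j - 1] & m[i - 1]) != 0) ? 0 : 1);
      int up = dp[i - 1][j] + 1;
      int left = dp[i][j - 1] + 1;
      if (diag <= up && diag <= left) { dp[i][j] = diag; st[i][j] = st[i - 1][j - 1]; }
      else if (up <= left) { dp[i][j] = up; st[i][j] = st[i - 1][j]; }
      else { dp[i][j] = left; st[i][j] = st[i][j - 1]; }
    }
  }
  // among minimum-distance end columns, prefer the span closest to the motif
  // length (ties at equal cost arise from free shifts around degenerate
  // positions and must not masquerade as indels)
  int bj = 0, bd = dp[L][0];
  for (int j = 0; j <= n; ++j) {
    int span = j - st[L][j];
    int bspan = bj - st[L][bj];
    if (dp[L][j] < bd ||
        (dp[L][j] == bd && std::abs(span - L) < std::abs(bspan - L))) {
      bd = dp[L][j]; bj = j;
    }
  }
  return IntegerVector::create(st[L][bj], bj, bd);
}
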