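// Pairwise alignment engine: affine-gap DP (global / extension / local) and a
// seeded local aligner (exact k-mer anchors, collinear chaining, DP gap fill,
// X-drop end extension).  Scoring defaults match +1 / mismatch -2 /
// gap open -4 / gap extend -1: a gap of length L costs open + L * extend.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

static const int NEG = -100000000;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // N / masked: never matches anything, incl. itself
  }
}

static std::vector<int8_t> encode(const std::string &s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int8_t)base_code(s[i]);
  return v;
}

struct AlnResult {
  int qstart, qend, tstart, tend; // 0-based half-open on the input subsequences
  int score, matches, columns;
  std::string ops; // 'M' consume both, 'I' consume query only, 'D' target only
  bool ok;
};

// Affine-gap DP over query a (rows) and target b (cols).
// mode 0 = global (both ends pinned), 1 = extension (start pinned at (0,0),
// end free, X-drop pruning), 2 = local (Smith-Waterman).
static AlnResult align_rect(const std::vector<int8_t> &a, const std::vector<int8_t> &b,
                            int mode, int match, int mismatch, int gap_open, int gap_ext,
                            int xdrop, bool prefer_far = false) {
  const int n = (int)a.size(), m = (int)b.size();
  AlnResult res; res.ok = false;
  res.qstart = res.qend = res.tstart = res.tend = 0;
  res.score = 0; res.matches = 0; res.columns = 0;
  if ((double)(n + 1) * (double)(m + 1) > 2.0e7)
    stop("alignment rectangle too large (%d x %d)", n, m);
  const int W = m + 1;
  std::vector<int> M((size_t)(n + 1) * W), X((size_t)(n + 1) * W), Y((size_t)(n + 1) * W);
  // traceback: 2 bits per state; tbM: 0 diag-from-M,1 from-X,2 from-Y,3 local-start
  std::vector<uint8_t> tbM((size_t)(n + 1) * W), tbX((size_t)(n + 1) * W), tbY((size_t)(n + 1) * W);
  const int go = gap_open, ge = gap_ext;
  auto idx = [W](int i, int j) { return (size_t)i * W + j; };

  M[0] = 0; X[0] = NEG; Y[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    M[idx(0, j)] = NEG; Y[idx(0, j)] = NEG;
    if (mode == 0 || mode == 1) {
      X[idx(0, j)] = -(go + ge * j);
    } else {
      X[idx(0, j)] = NEG;
    }
    tbX[idx(0, j)] = 1;
  }
  int best = (mode == 0) ? NEG : 0;
  int bi = 0, bj = 0; // best end cell (extension/local)
  for (int i = 1; i <= n; ++i) {
    M[idx(i, 0)] = NEG; X[idx(i, 0)] = NEG;
    Y[idx(i, 0)] = (mode == 0 || mode == 1) ? -(go + ge * i) : NEG;
    tbY[idx(i, 0)] = 2;
    int rowmax = NEG;
    for (int j = 1; j <= m; ++j) {
      const size_t c = idx(i, j), d = idx(i - 1, j - 1), u = idx(i - 1, j), l = idx(i, j - 1);
      const int s = (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ? match : mismatch;
      // M
      int vm = M[d], src = 0;
      if (X[d] > vm) { vm = X[d]; src = 1; }
      if (Y[d] > vm) { vm = Y[d]; src = 2; }
      int mv = (vm <= NEG / 2) ? NEG : vm + s;
      if (mode == 2 && mv < s) { /* allow fresh local start */ }
      if (mode == 2 && 0 + s > mv) { mv = s; src = 3; }
      M[c] = mv; tbM[c] = (uint8_t)src;
      // X: gap in query, consume target (move left -> right)
      int xo = (M[l] <= NEG / 2) ? NEG : M[l] - go - ge;
      int xy = (Y[l] <= NEG / 2) ? NEG : Y[l] - go - ge;
      int xe = (X[l] <= NEG / 2) ? NEG : X[l] - ge;
      if (xy > xo) { X[c] = (xe > xy) ? xe : xy; tbX[c] = (xe > xy) ? 1 : 2; }
      else         { X[c] = (xe > xo) ? xe : xo; tbX[c] = (xe > xo) ? 1 : 0; }
      // Y: gap in target, consume query
      int yo = (M[u] <= NEG / 2) ? NEG : M[u] - go - ge;
      int yx = (X[u] <= NEG / 2) ? NEG : X[u] - go - ge;
      int ye = (Y[u] <= NEG / 2) ? NEG : Y[u] - ge;
      if (yx > yo) { Y[c] = (ye > yx) ? ye : yx; tbY[c] = (ye > yx) ? 2 : 1; }
      else         { Y[c] = (ye > yo) ? ye : yo; tbY[c] = (ye > yo) ? 2 : 0; }
      int h = M[c]; if (X[c] > h) h = X[c]; if (Y[c] > h) h = Y[c];
      if (h > rowmax) rowmax = h;
      // full-SW tracebacks end at the first co-optimal maximum but start at
      // the furthest one; prefer_far selects the latter convention (used for
      // leftward extensions, which operate on reversed prefixes)
      if (mode != 0 && (M[c] > best || (prefer_far && M[c] == best)))
        { best = M[c]; bi = i; bj = j; }
    }
    if (mode == 1 && xdrop > 0 && rowmax < best - xdrop) { // prune remaining rows
      // zero-fill below not needed; stop here
      break;
    }
  }
  int ei, ej; // end cell
  int state; // 0 M, 1 X, 2 Y
  if (mode == 0) {
    ei = n; ej = m;
    int v = M[idx(ei, ej)]; state = 0;
    if (X[idx(ei, ej)] > v) { v = X[idx(ei, ej)]; state = 1; }
    if (Y[idx(ei, ej)] > v) { v = Y[idx(ei, ej)]; state = 2; }
    best = v;
  } else {
    ei = bi; ej = bj; state = 0;
    if (best <= 0 && mode == 2) { res.ok = true; res.ops = ""; return res; } // empty local hit
  }
  // traceback
  std::string ops;
  int i = ei, j = ej, st = state;
  while (i > 0 || j > 0) {
    if (mode != 0 && st == 0 && tbM[idx(i, j)] == 3) { ops.push_back('M'); --i; --j; break; }
    if (st == 0) {
      if (i == 0 || j == 0) break;
      uint8_t s = tbM[idx(i, j)];
      ops.push_back('M'); --i; --j; st = (s == 3) ? 0 : (int)s;
      if (mode != 0 && s == 3) break;
    } else if (st == 1) {
      if (j == 0) break;
      uint8_t s = tbX[idx(i, j)];
      ops.push_back('D'); --j; st = (s == 1) ? 1 : ((s == 2) ? 2 : 0);
    } else {
      if (i == 0) break;
      uint8_t s = tbY[idx(i, j)];
      ops.push_back('I'); --i; st = (s == 2) ? 2 : ((s == 1) ? 1 : 0);
    }
    if (mode != 0 && i == 0 && j == 0) break;
    if (mode == 1 && i == 0 && j == 0) break;
  }
  std::reverse(ops.begin(), ops.end());
  res.qstart = i; res.tstart = j; res.qend = ei; res.tend = ej;
  res.score = best; res.ops = ops;
  int mm = 0; { int qi = i, tj = j;
    for (char o : ops) {
      if (o == 'M') { if (a[qi] >= 0 && a[qi] == b[tj]) ++mm; ++qi; ++tj; }
      else if (o == 'I') ++qi; else ++tj;
    } }
  res.matches = mm; res.columns = (int)ops.size();
  res.ok = true;
  return res;
}

// [[Rcpp::export]]
List cpp_align_pair(std::string a, std::string b, int mode,
                    int match = 1, int mismatch = -2, int gap_open = 4,
                    int gap_ext = 1, int xdrop = 50) {
  std::vector<int8_t> ea = encode(a), eb = encode(b);
  AlnResult r = align_rect(ea, eb, mode, match, mismatch, gap_open, gap_ext, xdrop);
  return List::create(_["qstart"] = r.qstart, _["qend"] = r.qend,
                      _["tstart"] = r.tstart, _["tend"] = r.tend,
                      _["score"] = r.score, _["matches"] = r.matches,
                      _["columns"] = r.columns, _["ops"] = r.ops);
}

// ------------------------- seeded aligner ----------------------------------

struct Anchor { int q, t, len; };

typedef std::unordered_map<uint64_t, std::vector<int>> KmerIndex;

static void build_index(const std::vector<int8_t> &t, int k, KmerIndex &index) {
  const int m = (int)t.size();
  if (m < k) return;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  index.reserve((size_t)m * 2);
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < m; ++i) {
    int c = t[i];
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask; ++run;
    if (run >= k) index[h].push_back(i - k + 1);
  }
}

static void collect_anchors(const std::vector<int8_t> &q, const KmerIndex &index,
                            int k, bool self, std::vector<Anchor> &anchors) {
  const int n = (int)q.size();
  if (n < k) return;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  // k-mers occurring many times sit inside internal tandem repeats; anchors
  // there explode quadratically and contribute nothing the gap fill cannot
  // recover, so high-multiplicity k-mers are skipped
  const size_t max_occ = 8;
  std::vector<std::pair<int,int>> qt;
  { uint64_t h = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = q[i];
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask; ++run;
      if (run < k) continue;
      auto it = index.find(h);
      if (it == index.end() || it->second.size() > max_occ) continue;
      int qs = i - k + 1;
      for (int ts : it->second) {
        if (self && ts <= qs) continue; // upper triangle only; excludes main diagonal
        qt.push_back(std::make_pair(qs, ts));
      }
      if (qt.size() > 4000000) stop("anchor explosion; input too repetitive");
    } }
  // merge overlapping k-mer matches on the same diagonal into maximal segments
  std::sort(qt.begin(), qt.end(), [](const std::pair<int,int> &a, const std::pair<int,int> &b) {
    int da = a.second - a.first, db = b.second - b.first;
    if (da != db) return da < db;
    return a.first < b.first;
  });
  for (size_t i = 0; i < qt.size();) {
    int d = qt[i].second - qt[i].first;
    int qs = qt[i].first, qe = qs + k;
    size_t j = i + 1;
    while (j < qt.size() && (qt[j].second - qt[j].first) == d && qt[j].first <= qe) {
      qe = std::max(qe, qt[j].first + k); ++j;
    }
    Anchor a; a.q = qs; a.t = qs + d; a.len = qe - qs;
    anchors.push_back(a);
    i = j;
  }
}

static List seed_align_core(const std::vector<int8_t> &q, const std::vector<int8_t> &t,
                            const KmerIndex &index, int k, bool self,
                            int max_gap_q, int max_gap_t, int min_seed_bases,
                            int match, int mismatch, int gap_open, int gap_ext,
                            int xdrop, int max_chains) {
  std::vector<Anchor> anchors;
  collect_anchors(q, index, k, self, anchors);
  List out;
  if (anchors.empty()) return out;
  if (anchors.size() > 12000) { // keep longest
    std::sort(anchors.begin(), anchors.end(), [](const Anchor &a, const Anchor &b) { return a.len > b.len; });
    anchors.resize(12000);
  }
  std::sort(anchors.begin(), anchors.end(), [](const Anchor &a, const Anchor &b) {
    if (a.q != b.q) return a.q < b.q;
    return a.t < b.t;
  });
  const int A = (int)anchors.size();
  std::vector<double> dp(A);
  std::vector<int> prev(A, -1);
  for (int i = 0; i < A; ++i) dp[i] = anchors[i].len;
  int maxlen = 0;
  for (int i = 0; i < A; ++i) maxlen = std::max(maxlen, anchors[i].len);
  for (int i = 0; i < A; ++i) {
    const Anchor &ai = anchors[i];
    for (int j = i - 1; j >= 0; --j) {
      const Anchor &aj = anchors[j];
      if (aj.q + maxlen < ai.q - max_gap_q) break; // sorted by q; no closer predecessors
      if (aj.q >= ai.q || aj.t >= ai.t) continue;
      int gq = ai.q - (aj.q + aj.len);
      int gt = ai.t - (aj.t + aj.len);
      int ov = std::max(-gq, -gt); // overlap to trim later
      if (ov >= std::min(ai.len, aj.len)) continue;
      if (gq > max_gap_q || gt > max_gap_t) continue;
      double pen = 0.05 * (std::max(0, gq) + std::max(0, gt)) + 0.01 * std::abs(gq - gt);
      double cand = dp[j] + ai.len - (ov > 0 ? ov : 0) - pen;
      if (cand > dp[i]) { dp[i] = cand; prev[i] = j; }
    }
  }
  std::vector<char> used(A, 0);
  int found = 0;
  while (found < max_chains) {
    int bi = -1; double bs = -1;
    for (int i = 0; i < A; ++i) if (!used[i] && dp[i] > bs) { bs = dp[i]; bi = i; }
    if (bi < 0 || bs < min_seed_bases) break;
    // backtrack
    std::vector<int> chain;
    for (int i = bi; i >= 0 && !used[i]; i = prev[i]) { chain.push_back(i); if (prev[i] < 0) break; }
    std::reverse(chain.begin(), chain.end());
    for (int i : chain) used[i] = 1;
    // collect + trim overlaps
    std::vector<Anchor> segs;
    for (int ci : chain) segs.push_back(anchors[ci]);
    std::vector<Anchor> clean;
    for (auto s : segs) {
      if (!clean.empty()) {
        Anchor &p = clean.back();
        int d1 = (p.q + p.len) - s.q;
        int d2 = (p.t + p.len) - s.t;
        int d = std::max(d1, d2);
        if (d > 0) { s.q += d; s.t += d; s.len -= d; }
        if (s.len <= 0) continue;
        if (s.q < p.q + p.len || s.t < p.t + p.len) continue;
      }
      clean.push_back(s);
    }
    if (clean.empty()) continue;
    int seedbases = 0; for (auto &s : clean) seedbases += s.len;
    if (seedbases < min_seed_bases) continue;
    // assemble ops
    std::string ops;
    bool bad = false;
    for (size_t i = 0; i < clean.size(); ++i) {
      if (i > 0) {
        int gq = clean[i].q - (clean[i - 1].q + clean[i - 1].len);
        int gt = clean[i].t - (clean[i - 1].t + clean[i - 1].len);
        if (gq > 0 && gt > 0) {
          if ((double)gq * gt > 1.5e7) { // too big to fill: treat as paired gaps
            ops.append((size_t)gq, 'I'); ops.append((size_t)gt, 'D');
          } else {
            std::vector<int8_t> sa(q.begin() + clean[i - 1].q + clean[i - 1].len, q.begin() + clean[i].q);
            std::vector<int8_t> sb(t.begin() + clean[i - 1].t + clean[i - 1].len, t.begin() + clean[i].t);
            AlnResult g = align_rect(sa, sb, 0, match, mismatch, gap_open, gap_ext, 0);
            if (!g.ok) { bad = true; break; }
            ops += g.ops;
          }
        } else if (gq > 0) ops.append((size_t)gq, 'I');
        else if (gt > 0) ops.append((size_t)gt, 'D');
      }
      ops.append((size_t)clean[i].len, 'M');
    }
    if (bad) continue;
    int q0 = clean.front().q, t0 = clean.front().t;
    int q1 = clean.back().q + clean.back().len, t1 = clean.back().t + clean.back().len;
    // X-drop end extensions; grow the DP rectangle only while the optimum
    // keeps hitting its boundary (most extensions stop within a few bases)
    auto extend = [&](const std::vector<int8_t> &sa, const std::vector<int8_t> &sb,
                      int avail_a, int avail_b, bool prefer_far) {
      AlnResult best_e; best_e.ok = false; best_e.score = 0;
      for (int lim = 256; ; lim *= 8) {
        int la = std::min(avail_a, lim), lb = std::min(avail_b, lim);
        if (la <= 0 || lb <= 0) break;
        std::vector<int8_t> pa(sa.begin(), sa.begin() + la);
        std::vector<int8_t> pb(sb.begin(), sb.begin() + lb);
        AlnResult e = align_rect(pa, pb, 1, match, mismatch, gap_open, gap_ext,
                                 xdrop, prefer_far);
        best_e = e;
        bool at_edge = (e.qend >= la && la < avail_a) || (e.tend >= lb && lb < avail_b);
        if (!at_edge || lim >= 4000) break;
      }
      return best_e;
    };
    { // left: reversed prefixes
      if (q0 > 0 && t0 > 0) {
        int ql = std::min(q0, 4000), tl = std::min(t0, 4000);
        std::vector<int8_t> ra(ql), rb(tl);
        for (int i2 = 0; i2 < ql; ++i2) ra[i2] = q[q0 - 1 - i2];
        for (int i2 = 0; i2 < tl; ++i2) rb[i2] = t[t0 - 1 - i2];
        AlnResult e = extend(ra, rb, ql, tl, true);
        if (e.ok && e.score >= 0 && !e.ops.empty()) {
          std::string rops(e.ops.rbegin(), e.ops.rend());
          ops = rops + ops; q0 -= e.qend; t0 -= e.tend;
        }
      }
    }
    { // right
      int qa = (int)q.size() - q1, ta = (int)t.size() - t1;
      if (qa > 0 && ta > 0) {
        int ql = std::min(qa, 4000), tl = std::min(ta, 4000);
        std::vector<int8_t> sa(q.begin() + q1, q.begin() + q1 + ql);
        std::vector<int8_t> sb(t.begin() + t1, t.begin() + t1 + tl);
        AlnResult e = extend(sa, sb, ql, tl, false);
        if (e.ok && e.score >= 0 && !e.ops.empty()) { ops += e.ops; q1 += e.qend; t1 += e.tend; }
      }
    }
    // stats + blocks
    int mm = 0, sc = 0; int qi = q0, tj = t0;
    std::vector<int> bq0, bq1, bt0, bt1, bmm;
    int curq = -1, curt = -1, curm = 0;
    char prevop = 0;
    for (char o : ops) {
      if (o == 'M') {
        if (prevop != 'M') { curq = qi; curt = tj; curm = 0; }
        bool is = (q[qi] >= 0 && q[qi] == t[tj]);
        if (is) { ++mm; ++curm; sc += match; } else sc += mismatch;
        ++qi; ++tj;
      } else {
        if (prevop == 'M') {
          bq0.push_back(curq); bq1.push_back(qi); bt0.push_back(curt);
          bt1.push_back(tj); bmm.push_back(curm);
        }
        if (o != prevop) { sc -= gap_open; }
        sc -= gap_ext;
        if (o == 'I') ++qi; else ++tj;
      }
      prevop = o;
    }
    if (prevop == 'M') {
      bq0.push_back(curq); bq1.push_back(qi); bt0.push_back(curt);
      bt1.push_back(tj); bmm.push_back(curm);
    }
    IntegerMatrix blocks((int)bq0.size(), 5);
    for (int i2 = 0; i2 < (int)bq0.size(); ++i2) {
      blocks(i2, 0) = bq0[i2]; blocks(i2, 1) = bq1[i2];
      blocks(i2, 2) = bt0[i2]; blocks(i2, 3) = bt1[i2];
      blocks(i2, 4) = bmm[i2];
    }
    out.push_back(List::create(_["qstart"] = q0, _["qend"] = q1,
                               _["tstart"] = t0, _["tend"] = t1,
                               _["score"] = sc, _["matches"] = mm,
                               _["columns"] = (int)ops.size(),
                               _["blocks"] = blocks));
    ++found;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_seed_align(std::string qs, std::string ts, int k = 15, bool self = false,
                    int max_gap_q = 1000, int max_gap_t = 1000,
                    int min_seed_bases = 30, int match = 1, int mismatch = -2,
                    int gap_open = 4, int gap_ext = 1, int xdrop = 40,
                    int max_chains = 64) {
  std::vector<int8_t> q = encode(qs), t = encode(ts);
  KmerIndex index;
  build_index(t, k, index);
  return seed_align_core(q, t, index, k, self, max_gap_q, max_gap_t,
                         min_seed_bases, match, mismatch, gap_open, gap_ext,
                         xdrop, max_chains);
}

// multiple queries against one target: the target index is built once
// [[Rcpp::export]]
List cpp_seed_align_multi(std::vector<std::string> queries, std::string ts,
                          int k = 15, int max_gap_q = 1000, int max_gap_t = 1000,
                          int min_seed_bases = 30, int match = 1, int mismatch = -2,
                          int gap_open = 4, int gap_ext = 1, int xdrop = 40,
                          int max_chains = 64) {
  std::vector<int8_t> t = encode(ts);
  KmerIndex index;
  build_index(t, k, index);
  List out((int)queries.size());
  for (size_t i = 0; i < queries.size(); ++i) {
    std::vector<int8_t> q = encode(queries[i]);
    out[i] = seed_align_core(q, t, index, k, false, max_gap_q, max_gap_t,
                             min_seed_bases, match, mismatch, gap_open, gap_ext,
                             xdrop, max_chains);
  }
  return out;
}
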