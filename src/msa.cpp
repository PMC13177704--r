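// Deterministic progressive multiple sequence alignment: UPGMA guide tree
// built from pairwise global-alignment identities (ties broken by input
// order), then profile-profile Needleman-Wunsch merges.  This is the
// built-in MSA backend; an external aligner can be swapped in at the R level.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
#include <algorithm>

using namespace Rcpp;

static inline int code5(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case '-': return 4;
  default: return 5; // N etc: scores 0 against everything
  }
}

struct PairAln { double identity; };

// linear-space-free simple global affine alignment returning ops
static std::string nw_ops(const std::string &a, const std::string &b,
                          int match, int mismatch, int go, int ge,
                          double *identity) {
  const int n = (int)a.size(), m = (int)b.size();
  const int NEG = -100000000;
  std::vector<int> M((n + 1) * (m + 1)), X((n + 1) * (m + 1)), Y((n + 1) * (m + 1));
  std::vector<uint8_t> tM((n + 1) * (m + 1)), tX((n + 1) * (m + 1)), tY((n + 1) * (m + 1));
  auto id = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  M[0] = 0; X[0] = NEG; Y[0] = NEG;
  for (int j = 1; j <= m; ++j) { M[id(0, j)] = NEG; Y[id(0, j)] = NEG; X[id(0, j)] = -(go + ge * j); tX[id(0, j)] = 1; }
  for (int i = 1; i <= n; ++i) {
    M[id(i, 0)] = NEG; X[id(i, 0)] = NEG; Y[id(i, 0)] = -(go + ge * i); tY[id(i, 0)] = 2;
    for (int j = 1; j <= m; ++j) {
      int ca = code5(a[i - 1]), cb = code5(b[j - 1]);
      int s = (ca < 4 && ca == cb) ? match : mismatch;
      int vm = M[id(i - 1, j - 1)], src = 0;
      if (X[id(i - 1, j - 1)] > vm) { vm = X[id(i - 1, j - 1)]; src = 1; }
      if (Y[id(i - 1, j - 1)] > vm) { vm = Y[id(i - 1, j - 1)]; src = 2; }
      M[id(i, j)] = (vm <= NEG / 2) ? NEG : vm + s; tM[id(i, j)] = src;
      int xo = (M[id(i, j - 1)] <= NEG / 2) ? NEG : M[id(i, j - 1)] - go - ge;
      int xy = (Y[id(i, j - 1)] <= NEG / 2) ? NEG : Y[id(i, j - 1)] - go - ge;
      int xe = (X[id(i, j - 1)] <= NEG / 2) ? NEG : X[id(i, j - 1)] - ge;
      if (xy > xo) { X[id(i, j)] = std::max(xe, xy); tX[id(i, j)] = (xe > xy) ? 1 : 2; }
      else { X[id(i, j)] = std::max(xe, xo); tX[id(i, j)] = (xe > xo) ? 1 : 0; }
      int yo = (M[id(i - 1, j)] <= NEG / 2) ? NEG : M[id(i - 1, j)] - go - ge;
      int yx = (X[id(i - 1, j)] <= NEG / 2) ? NEG : X[id(i - 1, j)] - go - ge;
      int ye = (Y[id(i - 1, j)] <= NEG / 2) ? NEG : Y[id(i - 1, j)] - ge;
      if (yx > yo) { Y[id(i, j)] = std::max(ye, yx); tY[id(i, j)] = (ye > yx) ? 2 : 1; }
      else { Y[id(i, j)] = std::max(ye, yo); tY[id(i, j)] = (ye > yo) ? 2 : 0; }
    }
  }
  int i = n, j = m, st = 0;
  { int v = M[id(n, m)]; st = 0;
    if (X[id(n, m)] > v) { v = X[id(n, m)]; st = 1; }
    if (Y[id(n, m)] > v) { v = Y[id(n, m)]; st = 2; } }
  std::string ops;
  while (i > 0 || j > 0) {
    if (st == 0) { uint8_t s = tM[id(i, j)]; ops.push_back('M'); --i; --j; st = s; }
    else if (st == 1) { uint8_t s = tX[id(i, j)]; ops.push_back('D'); --j; st = s; }
    else { uint8_t s = tY[id(i, j)]; ops.push_back('I'); --i; st = s; }
  }
  std::reverse(ops.begin(), ops.end());
  if (identity) {
    int mm = 0, cols = (int)ops.size(); int qi = 0, tj = 0;
    for (char o : ops) {
      if (o == 'M') { int ca = code5(a[qi]), cb = code5(b[tj]); if (ca < 4 && ca == cb) ++mm; ++qi; ++tj; }
      else if (o == 'I') ++qi; else ++tj;
    }
    *identity = cols > 0 ? (double)mm / cols : 1.0;
  }
  return ops;
}

// profile-profile global alignment; profiles as column frequency over A,C,G,T,-
static std::string profile_ops(const std::vector<std::string> &ra,
                               const std::vector<std::string> &rb,
                               double match, double mismatch, double go, double ge) {
  const int n = (int)ra[0].size(), m = (int)rb[0].size();
  if ((double)(n + 1) * (m + 1) > 4.0e7) stop("internal MSA profile too large; use the mafft backend");
  auto freqs = [](const std::vector<std::string> &rows, int len) {
    std::vector<std::array<double, 5>> f(len);
    for (auto &col : f) col.fill(0.0);
    for (const auto &r : rows)
      for (int j = 0; j < len; ++j) { int c = code5(r[j]); if (c < 5) f[j][c] += 1.0; }
    double nr = (double)rows.size();
    for (auto &col : f) for (auto &v : col) v /= nr;
    return f;
  };
  auto fa = freqs(ra, n), fb = freqs(rb, m);
  auto colscore = [&](int i, int j) {
    double s = 0;
    for (int x = 0; x < 4; ++x)
      for (int y = 0; y < 4; ++y)
        s += fa[i][x] * fb[j][y] * ((x == y) ? match : mismatch);
    return s;
  };
  const double NEGD = -1e15;
  std::vector<double> M((size_t)(n + 1) * (m + 1)), X((size_t)(n + 1) * (m + 1)), Y((size_t)(n + 1) * (m + 1));
  std::vector<uint8_t> tM((size_t)(n + 1) * (m + 1)), tX((size_t)(n + 1) * (m + 1)), tY((size_t)(n + 1) * (m + 1));
  auto id = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  M[0] = 0; X[0] = NEGD; Y[0] = NEGD;
  for (int j = 1; j <= m; ++j) { M[id(0, j)] = NEGD; Y[id(0, j)] = NEGD; X[id(0, j)] = -(go + ge * j); tX[id(0, j)] = 1; }
  for (int i = 1; i <= n; ++i) {
    M[id(i, 0)] = NEGD; X[id(i, 0)] = NEGD; Y[id(i, 0)] = -(go + ge * i); tY[id(i, 0)] = 2;
    for (int j = 1; j <= m; ++j) {
      double s = colscore(i - 1, j - 1);
      double vm = M[id(i - 1, j - 1)]; int src = 0;
      if (X[id(i - 1, j - 1)] > vm) { vm = X[id(i - 1, j - 1)]; src = 1; }
      if (Y[id(i - 1, j - 1)] > vm) { vm = Y[id(i - 1, j - 1)]; src = 2; }
      M[id(i, j)] = vm + s; tM[id(i, j)] = src;
      double xo = M[id(i, j - 1)] - go - ge, xy = Y[id(i, j - 1)] - go - ge, xe = X[id(i, j - 1)] - ge;
      if (xy > xo) { X[id(i, j)] = std::max(xe, xy); tX[id(i, j)] = (xe > xy) ? 1 : 2; }
      else { X[id(i, j)] = std::max(xe, xo); tX[id(i, j)] = (xe > xo) ? 1 : 0; }
      double yo = M[id(i - 1, j)] - go - ge, yx = X[id(i - 1, j)] - go - ge, ye = Y[id(i - 1, j)] - ge;
      if (yx > yo) { Y[id(i, j)] = std::max(ye, yx); tY[id(i, j)] = (ye > yx) ? 2 : 1; }
      else { Y[id(i, j)] = std::max(ye, yo); tY[id(i, j)] = (ye > yo) ? 2 : 0; }
    }
  }
  int i = n, j = m, st = 0;
  { double v = M[id(n, m)]; st = 0;
    if (X[id(n, m)] > v) { v = X[id(n, m)]; st = 1; }
    if (Y[id(n, m)] > v) { v = Y[id(n, m)]; st = 2; } }
  std::string ops;
  while (i > 0 || j > 0) {
    if (st == 0) { uint8_t s = tM[id(i, j)]; ops.push_back('M'); --i; --j; st = s; }
    else if (st == 1) { uint8_t s = tX[id(i, j)]; ops.push_back('D'); --j; st = s; }
    else { uint8_t s = tY[id(i, j)]; ops.push_back('I'); --i; st = s; }
  }
  std::reverse(ops.begin(), ops.end());
  return ops;
}

// [[Rcpp::export]]
CharacterVector cpp_progressive_msa(std::vector<std::string> seqs,
                                    int match = 1, int mismatch = -2,
                                    int gap_open = 4, int gap_ext = 1) {
  const int n = (int)seqs.size();
  if (n < 2) stop("need at least two sequences");
  // pairwise identities for the guide tree
  std::vector<std::vector<double>> D(n, std::vector<double>(n, 0.0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double idy;
      nw_ops(seqs[i], seqs[j], match, mismatch, gap_open, gap_ext, &idy);
      D[i][j] = D[j][i] = 1.0 - idy;
    }
  // UPGMA with deterministic ties (smallest pair of current cluster indices)
  struct Node { std::vector<int> members; std::vector<std::string> rows; int size; };
  std::vector<Node> act;
  for (int i = 0; i < n; ++i) {
    Node nd; nd.members = { i }; nd.rows = { seqs[i] }; nd.size = 1;
    act.push_back(nd);
  }
  std::vector<std::vector<double>> CD = D;
  std::vector<int> alive(n, 1);
  int remaining = n;
  while (remaining > 1) {
    int bi = -1, bj = -1; double bd = 1e18;
    for (int i = 0; i < (int)act.size(); ++i) {
      if (!alive[i]) continue;
      for (int j = i + 1; j < (int)act.size(); ++j) {
        if (!alive[j]) continue;
        if (CD[i][j] < bd - 1e-12) { bd = CD[i][j]; bi = i; bj = j; }
      }
    }
    // merge bj into a new node
    std::vector<std::string> ra = act[bi].rows, rb = act[bj].rows;
    std::string ops = (ra.size() == 1 && rb.size() == 1)
      ? nw_ops(ra[0], rb[0], match, mismatch, gap_open, gap_ext, nullptr)
      : profile_ops(ra, rb, match, mismatch, gap_open, gap_ext);
    std::vector<std::string> merged;
    for (const auto &r : ra) {
      std::string out; out.reserve(ops.size()); size_t p = 0;
      for (char o : ops) { if (o == 'M' || o == 'I') out.push_back(r[p++]); else out.push_back('-'); }
      merged.push_back(out);
    }
    for (const auto &r : rb) {
      std::string out; out.reserve(ops.size()); size_t p = 0;
      for (char o : ops) { if (o == 'M' || o == 'D') out.push_back(r[p++]); else out.push_back('-'); }
      merged.push_back(out);
    }
    Node nd;
    nd.members = act[bi].members;
    nd.members.insert(nd.members.end(), act[bj].members.begin(), act[bj].members.end());
    nd.rows = merged; nd.size = act[bi].size + act[bj].size;
    // UPGMA distance update
    std::vector<double> nd_d(act.size() + 1, 0.0);
    for (int kk = 0; kk < (int)act.size(); ++kk) {
      if (!alive[kk] || kk == bi || kk == bj) continue;
      nd_d[kk] = (CD[bi][kk] * act[bi].size + CD[bj][kk] * act[bj].size) / (double)nd.size;
    }
    alive[bi] = 0; alive[bj] = 0;
    act.push_back(nd);
    alive.push_back(1);
    for (auto &row : CD) row.push_back(0.0);
    CD.push_back(std::vector<double>(act.size(), 0.0));
    int ni = (int)act.size() - 1;
    for (int kk = 0; kk < ni; ++kk) { CD[ni][kk] = CD[kk][ni] = nd_d[kk]; }
    --remaining;
  }
  // final node: reorder rows to input order
  const Node &root = act.back();
  CharacterVector out(n);
  for (size_t r = 0; r < root.members.size(); ++r) out[root.members[r]] = root.rows[r];
  return out;
}
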