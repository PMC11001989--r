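#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// xorshift hashing
// ---------------------------------------------------------------------------

// 32-bit xorshift, shift triple (13, 17, 5), one full step per hash.
// Zero is a fixed point of xorshift, so a zero seed is remapped to a fixed
// nonzero constant before stepping.
static inline uint32_t xorshift32(uint32_t y) {
  if (y == 0u) y = 0x9E3779B9u;
  y ^= y << 13;
  y ^= y >> 17;
  y ^= y << 5;
  return y;
}

// [[Rcpp::export]]
IntegerVector hash_kmer_cpp(IntegerVector codes, double s) {
  if (s < 1) stop("hash-space size 's' must be >= 1");
  uint64_t us = (uint64_t) s;
  R_xlen_t n = codes.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (codes[i] == NA_INTEGER) { out[i] = NA_INTEGER; continue; }
    out[i] = (int) (xorshift32((uint32_t) codes[i]) % us);
  }
  return out;
}

// ---------------------------------------------------------------------------
// k-mer encoding
// ---------------------------------------------------------------------------

// map: sequence as 0-based letter indices; NA or negative = unmapped symbol.
// Emits base-x codes of every window of k consecutive mapped letters, then
// sorts codes (stably) carrying original 0-based start positions along.
// [[Rcpp::export]]
List encode_kmers_cpp(IntegerVector map, int k, int x) {
  if (k < 1) stop("'k' must be >= 1");
  if (x < 2) stop("alphabet size must be >= 2");
  R_xlen_t n = map.size();
  std::vector<int> codes;
  std::vector<int> pos;
  if (n >= k) {
    long long xk = 1;
    for (int i = 0; i < k; ++i) {
      xk *= x;
      if (xk > 2147483647LL) stop("x^k exceeds the 32-bit encoding cap");
    }
    long long lead = xk / x;
    long long code = 0;
    int run = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      int c = (map[i] == NA_INTEGER) ? -1 : map[i];
      if (c < 0 || c >= x) { run = 0; code = 0; continue; }
      if (run < k) {
        code = code * x + c;
        ++run;
      } else {
        code = (code - (long long) map[i - k] * lead) * x + c;
      }
      if (run == k) {
        codes.push_back((int) code);
        pos.push_back((int) (i - k + 1));
      }
    }
  }
  size_t m = codes.size();
  std::vector<int> idx(m);
  for (size_t i = 0; i < m; ++i) idx[i] = (int) i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return codes[a] < codes[b]; });
  IntegerVector sk(m), sp(m);
  for (size_t i = 0; i < m; ++i) {
    sk[i] = codes[idx[i]];
    sp[i] = pos[idx[i]];
  }
  return List::create(_["kmers"] = sk, _["positions"] = sp);
}

// ---------------------------------------------------------------------------
// rare-k-mer candidate gathering (phase 1 / phase 3 hot path)
// ---------------------------------------------------------------------------

// Visits the focal sequence's rare-k-mer groups in ascending size,
// recording group members until the running total reaches A, and
// tabulates per-candidate shared counts. 'starts'/'ends' are the focal's
// 1-based group pointers into 'member'; 'focal' is excluded.
// [[Rcpp::export]]
List gather_counts_cpp(IntegerVector member, IntegerVector starts,
                       IntegerVector ends, int focal, double A) {
  int ns = (int) starts.size();
  std::vector<std::pair<int, int> > slots(ns);  // (size, slot index)
  for (int t = 0; t < ns; ++t)
    slots[t] = std::make_pair(ends[t] - starts[t] + 1, t);
  std::stable_sort(slots.begin(), slots.end());
  std::vector<int> vals;
  long total = 0;
  const int* mem = INTEGER(member);
  for (int t = 0; t < ns; ++t) {
    if (total >= (long) A) break;
    int sl = slots[t].second;
    for (int q = starts[sl] - 1; q <= ends[sl] - 1; ++q) {
      if (mem[q] != focal) vals.push_back(mem[q]);
    }
    total += slots[t].first;
  }
  std::sort(vals.begin(), vals.end());
  std::vector<int> ids, counts;
  size_t i = 0;
  int maxc = 0;
  while (i < vals.size()) {
    size_t j = i;
    while (j < vals.size() && vals[j] == vals[i]) ++j;
    ids.push_back(vals[i]);
    counts.push_back((int) (j - i));
    if ((int) (j - i) > maxc) maxc = (int) (j - i);
    i = j;
  }
  IntegerVector hist(maxc);
  for (size_t t = 0; t < counts.size(); ++t) hist[counts[t] - 1] += 1;
  return List::create(_["ids"] = IntegerVector(ids.begin(), ids.end()),
                      _["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["hist"] = hist);
}

// ---------------------------------------------------------------------------
// k-mer matching and collinear chaining
// ---------------------------------------------------------------------------

struct Block { int s1, s2, len; };

// Merged walk over two sorted k-mer code vectors; shared codes emit position
// pairs, runs on the same diagonal coalesce into contiguous blocks.
// Codes repeated c1 x c2 > 64 times across the pair are skipped
// (low-complexity guard against combinatorial blowup).
static void collect_blocks(const int* k1, const int* p1, int n1,
                           const int* k2, const int* p2, int n2,
                           int k, std::vector<Block>& blocks) {
  std::vector<std::pair<int, int> > pairs;  // (pos1, pos2) of k-mer starts
  const long long per_code_cap = 64;
  const size_t total_cap = 200000;
  int i = 0, j = 0;
  while (i < n1 && j < n2) {
    if (k1[i] < k2[j]) { ++i; continue; }
    if (k1[i] > k2[j]) { ++j; continue; }
    int c = k1[i];
    int i2 = i; while (i2 < n1 && k1[i2] == c) ++i2;
    int j2 = j; while (j2 < n2 && k2[j2] == c) ++j2;
    if ((long long) (i2 - i) * (j2 - j) <= per_code_cap) {
      for (int a = i; a < i2; ++a)
        for (int b = j; b < j2; ++b)
          pairs.push_back(std::make_pair(p1[a], p2[b]));
    }
    if (pairs.size() > total_cap) break;
    i = i2; j = j2;
  }
  std::sort(pairs.begin(), pairs.end(),
            [](const std::pair<int, int>& a, const std::pair<int, int>& b) {
              int da = a.first - a.second, db = b.first - b.second;
              if (da != db) return da < db;
              return a.first < b.first;
            });
  size_t q = 0;
  while (q < pairs.size()) {
    int d = pairs[q].first - pairs[q].second;
    int start = pairs[q].first;
    int end = start + k;
    size_t r = q + 1;
    while (r < pairs.size()) {
      int dr = pairs[r].first - pairs[r].second;
      if (dr != d || pairs[r].first > end) break;
      end = std::max(end, pairs[r].first + k);
      ++r;
    }
    Block b;
    b.s1 = start;
    b.s2 = start - d;
    b.len = end - start;
    blocks.push_back(b);
    q = r;
  }
}

// Weighted chain DP over candidate blocks: maximize total anchored positions
// subject to strict collinearity (end1_i <= start1_j and end2_i <= start2_j).
// Ties broken toward the chain whose first block starts earlier in sequence
// 1, then toward fewer blocks. Returns kept block indices in chain order.
static long chain_dp(const std::vector<Block>& blk, std::vector<int>& keep) {
  keep.clear();
  int m = (int) blk.size();
  if (m == 0) return 0;
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (blk[a].s1 != blk[b].s1) return blk[a].s1 < blk[b].s1;
    return blk[a].s2 < blk[b].s2;
  });
  std::vector<long> best(m);
  std::vector<int> prev(m, -1), cnt(m), first(m);
  for (int oi = 0; oi < m; ++oi) {
    const Block& bi = blk[ord[oi]];
    best[oi] = bi.len;
    cnt[oi] = 1;
    first[oi] = bi.s1;
    for (int oj = 0; oj < oi; ++oj) {
      const Block& bj = blk[ord[oj]];
      if (bj.s1 + bj.len <= bi.s1 && bj.s2 + bj.len <= bi.s2) {
        long cand = best[oj] + bi.len;
        int cfirst = first[oj];
        int ccnt = cnt[oj] + 1;
        bool better = cand > best[oi] ||
          (cand == best[oi] && (cfirst < first[oi] ||
                                (cfirst == first[oi] && ccnt < cnt[oi])));
        if (better) {
          best[oi] = cand;
          prev[oi] = oj;
          cnt[oi] = ccnt;
          first[oi] = cfirst;
        }
      }
    }
  }
  int end = 0;
  for (int oi = 1; oi < m; ++oi) {
    bool better = best[oi] > best[end] ||
      (best[oi] == best[end] && (first[oi] < first[end] ||
                                 (first[oi] == first[end] && cnt[oi] < cnt[end])));
    if (better) end = oi;
  }
  long total = best[end];
  std::vector<int> rev;
  for (int at = end; at >= 0; at = prev[at]) {
    rev.push_back(ord[at]);
    if (prev[at] < 0) break;
  }
  keep.assign(rev.rbegin(), rev.rend());
  return total;
}

static IntegerMatrix blocks_to_matrix(const std::vector<Block>& blocks) {
  IntegerMatrix out((int) blocks.size(), 3);
  for (size_t i = 0; i < blocks.size(); ++i) {
    out(i, 0) = blocks[i].s1;
    out(i, 1) = blocks[i].s2;
    out(i, 2) = blocks[i].len;
  }
  colnames(out) = CharacterVector::create("start1", "start2", "length");
  return out;
}

// [[Rcpp::export]]
IntegerMatrix match_blocks_cpp(IntegerVector k1, IntegerVector p1,
                               IntegerVector k2, IntegerVector p2, int k) {
  std::vector<Block> blocks;
  collect_blocks(INTEGER(k1), INTEGER(p1), (int) k1.size(),
                 INTEGER(k2), INTEGER(p2), (int) k2.size(), k, blocks);
  return blocks_to_matrix(blocks);
}

// [[Rcpp::export]]
List chain_blocks_cpp(IntegerMatrix candidates) {
  std::vector<Block> blocks(candidates.nrow());
  for (int i = 0; i < candidates.nrow(); ++i) {
    blocks[i].s1 = candidates(i, 0);
    blocks[i].s2 = candidates(i, 1);
    blocks[i].len = candidates(i, 2);
  }
  std::vector<int> keep;
  long total = chain_dp(blocks, keep);
  std::vector<Block> kept;
  for (size_t i = 0; i < keep.size(); ++i) kept.push_back(blocks[keep[i]]);
  return List::create(_["blocks"] = blocks_to_matrix(kept),
                      _["anchored"] = (double) total,
                      _["keep"] = IntegerVector(keep.begin(), keep.end()));
}

// ---------------------------------------------------------------------------
// k-mer similarity from an anchor chain
// ---------------------------------------------------------------------------

// Numerator: anchored positions. Denominator: estimated overlap implied by
// the first/last anchor diagonals (clamped to [longest anchor, min length])
// plus the number of inter-anchor intervals whose flanking lengths differ
// between the two sequences (minimum implied gap runs).
static double ksim_core(const std::vector<Block>& ch, int len1, int len2,
                        double* cov_out) {
  if (cov_out) *cov_out = 0.0;
  if (ch.empty() || len1 < 1 || len2 < 1) return 0.0;
  long anchored = 0;
  int maxlen = 0;
  for (size_t i = 0; i < ch.size(); ++i) {
    anchored += ch[i].len;
    if (ch[i].len > maxlen) maxlen = ch[i].len;
  }
  const Block& f = ch.front();
  const Block& l = ch.back();
  int df = f.s1 - f.s2;
  int dl = l.s1 - l.s2;
  double start = df > 0 ? df : 0;
  double end = std::min((double) len1, (double) len2 + dl);
  double est = end - start;
  double lo = maxlen;
  double hi = std::min(len1, len2);
  if (est < lo) est = lo;
  if (est > hi) est = hi;
  if (est < (double) anchored) est = (double) anchored;
  int gaps = 0;
  for (size_t i = 1; i < ch.size(); ++i) {
    int g1 = ch[i].s1 - (ch[i - 1].s1 + ch[i - 1].len);
    int g2 = ch[i].s2 - (ch[i - 1].s2 + ch[i - 1].len);
    if (g1 != g2) ++gaps;
  }
  double sim = (double) anchored / (est + gaps);
  if (sim > 1) sim = 1;
  if (sim < 0) sim = 0;
  if (cov_out) {
    double cov = hi > 0 ? est / hi : 0.0;
    *cov_out = cov > 1 ? 1.0 : cov;
  }
  return sim;
}

// [[Rcpp::export]]
NumericVector ksim_from_blocks_cpp(IntegerMatrix chain, int len1, int len2) {
  std::vector<Block> ch(chain.nrow());
  for (int i = 0; i < chain.nrow(); ++i) {
    ch[i].s1 = chain(i, 0);
    ch[i].s2 = chain(i, 1);
    ch[i].len = chain(i, 2);
  }
  double cov = 0;
  double sim = ksim_core(ch, len1, len2, &cov);
  return NumericVector::create(_["similarity"] = sim, _["coverage"] = cov);
}

static double ksim_pair(const int* k1, const int* p1, int n1, int len1,
                        const int* k2, const int* p2, int n2, int len2,
                        int k, double* cov_out) {
  std::vector<Block> blocks;
  collect_blocks(k1, p1, n1, k2, p2, n2, k, blocks);
  std::vector<int> keep;
  chain_dp(blocks, keep);
  std::vector<Block> kept;
  for (size_t i = 0; i < keep.size(); ++i) kept.push_back(blocks[keep[i]]);
  return ksim_core(kept, len1, len2, cov_out);
}

// Batch k-mer similarity of one focal sequence against many others.
// 'kmers'/'positions' are per-sequence sorted index vectors; 'focal' and
// 'idx' are 1-based. Returns an n x 2 matrix (similarity, coverage).
// [[Rcpp::export]]
NumericMatrix kmer_sim_many_cpp(List kmers, List positions, IntegerVector lens,
                                int focal, IntegerVector idx, int k) {
  IntegerVector fk = kmers[focal - 1];
  IntegerVector fp = positions[focal - 1];
  int flen = lens[focal - 1];
  int n = (int) idx.size();
  NumericMatrix out(n, 2);
  colnames(out) = CharacterVector::create("similarity", "coverage");
  for (int t = 0; t < n; ++t) {
    int j = idx[t] - 1;
    IntegerVector jk = kmers[j];
    IntegerVector jp = positions[j];
    double cov = 0;
    out(t, 0) = ksim_pair(INTEGER(fk), INTEGER(fp), (int) fk.size(), flen,
                          INTEGER(jk), INTEGER(jp), (int) jk.size(), lens[j],
                          k, &cov);
    out(t, 1) = cov;
  }
  return out;
}

// ---------------------------------------------------------------------------
// anchored affine-gap alignment
// ---------------------------------------------------------------------------

static inline double subscore(const NumericMatrix& sub, double sub_min,
                              int a, int b) {
  if (a < 0 || b < 0 || a >= sub.nrow() || b >= sub.ncol()) return sub_min;
  return sub(a, b);
}

// ops: 0 = aligned column, 1 = gap in sequence 1, 2 = gap in sequence 2.
// Affine-gap global alignment of one region; a gap of length g costs
// gap_open + g * gap_extend. freeBegin/freeEnd make leading/trailing gaps
// free (used for terminal regions only).
static double align_region(const int* a, int na, const int* b, int nb,
                           const NumericMatrix& sub, double sub_min,
                           double gapO, double gapE,
                           bool freeBegin, bool freeEnd,
                           std::vector<signed char>& ops) {
  const double NEG = -std::numeric_limits<double>::infinity();
  if (na == 0 && nb == 0) return 0.0;
  if (na == 0) {
    for (int j = 0; j < nb; ++j) ops.push_back(1);
    return (freeBegin || freeEnd) ? 0.0 : gapO + nb * gapE;
  }
  if (nb == 0) {
    for (int i = 0; i < na; ++i) ops.push_back(2);
    return (freeBegin || freeEnd) ? 0.0 : gapO + na * gapE;
  }
  int W = nb + 1;
  // rolling score rows; full backpointer tables (char per state per cell)
  std::vector<double> Mprev(W), Xprev(W), Yprev(W), Mcur(W), Xcur(W), Ycur(W);
  std::vector<signed char> bM((size_t)(na + 1) * W), bX((size_t)(na + 1) * W),
      bY((size_t)(na + 1) * W);
  // backpointer codes: 0 = M, 1 = X (gap in s2), 2 = Y (gap in s1), 3 = start
  Mprev[0] = 0.0; Xprev[0] = NEG; Yprev[0] = NEG;
  bM[0] = 3;
  for (int j = 1; j <= nb; ++j) {
    Mprev[j] = NEG;
    Xprev[j] = NEG;
    Yprev[j] = freeBegin ? 0.0 : gapO + j * gapE;
    bY[j] = (j == 1) ? 3 : 2;
  }
  double bestEnd = NEG;
  int bestI = na, bestJ = nb, bestS = 0;
  for (int i = 1; i <= na; ++i) {
    Mcur[0] = NEG;
    Ycur[0] = NEG;
    Xcur[0] = freeBegin ? 0.0 : gapO + i * gapE;
    bX[(size_t) i * W] = (i == 1) ? 3 : 1;
    for (int j = 1; j <= nb; ++j) {
      // M
      double m0 = Mprev[j - 1], m1 = Xprev[j - 1], m2 = Yprev[j - 1];
      signed char pb = 0;
      double mb = m0;
      if (m1 > mb) { mb = m1; pb = 1; }
      if (m2 > mb) { mb = m2; pb = 2; }
      Mcur[j] = mb + subscore(sub, sub_min, a[i - 1], b[j - 1]);
      bM[(size_t) i * W + j] = pb;
      // X: consume a[i-1], gap in s2
      double xo = Mprev[j] + gapO + gapE;
      double xe = Xprev[j] + gapE;
      if (xo >= xe) { Xcur[j] = xo; bX[(size_t) i * W + j] = 0; }
      else          { Xcur[j] = xe; bX[(size_t) i * W + j] = 1; }
      // Y: consume b[j-1], gap in s1
      double yo = Mcur[j - 1] + gapO + gapE;
      double ye = Ycur[j - 1] + gapE;
      if (yo >= ye) { Ycur[j] = yo; bY[(size_t) i * W + j] = 0; }
      else          { Ycur[j] = ye; bY[(size_t) i * W + j] = 2; }
    }
    if (freeEnd) {
      // candidate end at (i, nb): remaining rows i+1..na become free gaps
      double cands[3] = { Mcur[nb], Xcur[nb], Ycur[nb] };
      for (int s = 0; s < 3; ++s)
        if (cands[s] > bestEnd) { bestEnd = cands[s]; bestI = i; bestJ = nb; bestS = s; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  // after loop, "prev" rows hold row na
  if (freeEnd) {
    for (int j = 0; j <= nb; ++j) {
      double cands[3] = { Mprev[j], Xprev[j], Yprev[j] };
      if (j == 0) { cands[0] = (na == 0) ? 0 : NEG; cands[2] = NEG; cands[1] = Xprev[0]; }
      for (int s = 0; s < 3; ++s)
        if (cands[s] > bestEnd) { bestEnd = cands[s]; bestI = na; bestJ = j; bestS = s; }
    }
  } else {
    double cands[3] = { Mprev[nb], Xprev[nb], Yprev[nb] };
    bestEnd = cands[0]; bestS = 0;
    if (cands[1] > bestEnd) { bestEnd = cands[1]; bestS = 1; }
    if (cands[2] > bestEnd) { bestEnd = cands[2]; bestS = 2; }
    bestI = na; bestJ = nb;
  }
  // traceback
  std::vector<signed char> rev;
  // trailing free gaps first (they are appended after the traced path)
  std::vector<signed char> tail;
  for (int i = na; i > bestI; --i) tail.push_back(2);
  for (int j = nb; j > bestJ; --j) tail.push_back(1);
  int i = bestI, j = bestJ, s = bestS;
  while (i > 0 || j > 0) {
    signed char p;
    if (s == 0) {
      if (i == 0 || j == 0) break;
      p = bM[(size_t) i * W + j];
      rev.push_back(0);
      --i; --j;
    } else if (s == 1) {
      p = bX[(size_t) i * W + j];
      rev.push_back(2);
      --i;
    } else {
      p = bY[(size_t) i * W + j];
      rev.push_back(1);
      --j;
    }
    if (p == 3) break;
    s = p;
  }
  // any remaining leading letters become (free or already-costed) gaps
  while (i > 0) { rev.push_back(2); --i; }
  while (j > 0) { rev.push_back(1); --j; }
  for (size_t t = rev.size(); t > 0; --t) ops.push_back(rev[t - 1]);
  for (size_t t = 0; t < tail.size(); ++t) ops.push_back(tail[t]);
  return bestEnd;
}

// Anchored alignment of a full pair given a collinear chain. Anchors are
// fixed aligned columns; inter-anchor regions use global affine DP; terminal
// regions have free terminal gaps. Returns per-position accounting over the
// overlap region (columns between the first and last aligned column).
// [[Rcpp::export]]
List anchored_align_cpp(IntegerVector s1, IntegerVector s2, IntegerMatrix chain,
                        NumericMatrix sub, double gap_open, double gap_extend) {
  int n1 = (int) s1.size(), n2 = (int) s2.size();
  double sub_min = R_PosInf;
  for (int i = 0; i < sub.nrow(); ++i)
    for (int j = 0; j < sub.ncol(); ++j)
      if (sub(i, j) < sub_min) sub_min = sub(i, j);
  int nb = chain.nrow();
  std::vector<signed char> ops;
  double score = 0.0;
  int c1 = 0, c2 = 0;
  const int* ps1 = INTEGER(s1);
  const int* ps2 = INTEGER(s2);
  for (int t = 0; t <= nb; ++t) {
    int e1 = (t < nb) ? chain(t, 0) : n1;
    int e2 = (t < nb) ? chain(t, 1) : n2;
    if (e1 < c1 || e2 < c2) stop("invalid anchor chain (not collinear)");
    bool freeB = (t == 0), freeE = (t == nb);
    score += align_region(ps1 + c1, e1 - c1, ps2 + c2, e2 - c2,
                          sub, sub_min, gap_open, gap_extend, freeB, freeE, ops);
    if (t < nb) {
      int len = chain(t, 2);
      for (int q = 0; q < len; ++q) {
        ops.push_back(0);
        score += subscore(sub, sub_min, ps1[e1 + q], ps2[e2 + q]);
      }
      c1 = e1 + len;
      c2 = e2 + len;
    }
  }
  // accounting over the overlap region
  int first0 = -1, last0 = -1;
  for (size_t t = 0; t < ops.size(); ++t)
    if (ops[t] == 0) { if (first0 < 0) first0 = (int) t; last0 = (int) t; }
  int matches = 0, mismatches = 0, gap_pos = 0, gap_runs = 0, overlap = 0;
  if (first0 >= 0) {
    overlap = last0 - first0 + 1;
    int i = 0, j = 0;
    signed char run_op = 0;
    for (int t = 0; t < (int) ops.size(); ++t) {
      signed char op = ops[t];
      bool in_ov = (t >= first0 && t <= last0);
      if (op == 0) {
        if (in_ov) {
          int a = ps1[i], b = ps2[j];
          if (a >= 0 && a == b) ++matches; else ++mismatches;
        }
        ++i; ++j;
        run_op = 0;
      } else {
        if (in_ov) {
          ++gap_pos;
          if (op != run_op) ++gap_runs;
        }
        if (op == 1) ++j; else ++i;
        run_op = op;
      }
    }
  }
  return List::create(
      _["matches"] = matches, _["mismatches"] = mismatches,
      _["gap_runs"] = gap_runs, _["gap_positions"] = gap_pos,
      _["overlap_length"] = overlap, _["score"] = score,
      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
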