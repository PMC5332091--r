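#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment over integer-encoded sequences (indices into
// the substitution matrix). Gap of length L costs gap_open + L * gap_extend.
// Returns best-scoring block with 0-based half-open coordinates, aligned
// column count and match count from the traceback.
// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  // DP matrices: M (match/mismatch), X (gap in b / insertion in a), Y (gap in a)
  std::vector<double> M((n + 1) * (m + 1), 0.0), X((n + 1) * (m + 1), R_NegInf),
      Y((n + 1) * (m + 1), R_NegInf);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0), tbX((n + 1) * (m + 1), 0),
      tbY((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double go = gap_open + gap_extend;
      double x1 = M[idx(i - 1, j)] - go, x2 = X[idx(i - 1, j)] - gap_extend;
      X[idx(i, j)] = std::max(x1, x2);
      tbX[idx(i, j)] = x1 >= x2 ? 1 : 2;
      double y1 = M[idx(i, j - 1)] - go, y2 = Y[idx(i, j - 1)] - gap_extend;
      Y[idx(i, j)] = std::max(y1, y2);
      tbY[idx(i, j)] = y1 >= y2 ? 1 : 2;
      double s = sub(a[i - 1], b[j - 1]);
      double dM = M[idx(i - 1, j - 1)] + s;
      double dX = X[idx(i - 1, j - 1)] + s;
      double dY = Y[idx(i - 1, j - 1)] + s;
      double v = dM;
      unsigned char t = 1;
      if (dX > v) { v = dX; t = 2; }
      if (dY > v) { v = dY; t = 3; }
      if (v < 0) { v = 0; t = 0; }
      M[idx(i, j)] = v;
      tbM[idx(i, j)] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["qstart"] = 0, _["qend"] = 0,
                        _["sstart"] = 0, _["send"] = 0, _["length"] = 0,
                        _["matches"] = 0);
  }
  // traceback
  int i = bi, j = bj, state = 0; // 0 = M
  int len = 0, matches = 0;
  int qend = bi, send = bj;
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char t = tbM[idx(i, j)];
      if (t == 0) break;
      ++len;
      if (a[i - 1] == b[j - 1]) ++matches;
      state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
      --i; --j;
      if (state == 0 && M[idx(i, j)] <= 0 && tbM[idx(i, j)] == 0) break;
    } else if (state == 1) { // X: gap in b, consume a
      unsigned char t = tbX[idx(i, j)];
      ++len;
      state = (t == 1) ? 0 : 1;
      --i;
    } else { // Y: gap in a, consume b
      unsigned char t = tbY[idx(i, j)];
      ++len;
      state = (t == 1) ? 0 : 2;
      --j;
    }
  }
  return List::create(_["score"] = best, _["qstart"] = i, _["qend"] = qend,
                      _["sstart"] = j, _["send"] = send, _["length"] = len,
                      _["matches"] = matches);
}

// Score-only local alignment in linear memory (no traceback).
// [[Rcpp::export]]
double cpp_sw_score(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  std::vector<double> Mp(m + 1, 0.0), Xp(m + 1, R_NegInf), Yp(m + 1, R_NegInf);
  std::vector<double> M(m + 1, 0.0), X(m + 1, R_NegInf), Y(m + 1, R_NegInf);
  double best = 0.0, go = gap_open + gap_extend;
  for (int i = 1; i <= n; ++i) {
    M[0] = 0.0; X[0] = R_NegInf; Y[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      X[j] = std::max(Mp[j] - go, Xp[j] - gap_extend);
      Y[j] = std::max(M[j - 1] - go, Y[j - 1] - gap_extend);
      double s = sub(a[i - 1], b[j - 1]);
      double v = std::max(std::max(Mp[j - 1], Xp[j - 1]), Yp[j - 1]) + s;
      if (v < 0) v = 0;
      M[j] = v;
      if (v > best) best = v;
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  return best;
}

// Seed-and-extend ungapped local alignment for nucleotide sequences encoded
// as integers A=0, C=1, G=2, T=3, N=-1 (N never seeds or matches).
// Exact k-mer seeds; X-drop ungapped extension; same-diagonal blocks merged
// (match counts recomputed over the merged span). Returns a numeric matrix
// with columns qstart, qend, sstart, send, length, matches, score
// (0-based half-open).
// [[Rcpp::export]]
NumericMatrix cpp_seed_extend(IntegerVector q, IntegerVector s, int k,
                              double match, double mismatch, double xdrop,
                              int bridge) {
  int nq = q.size(), ns = s.size();
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(ns);
  uint64_t key = 0, mask = (k < 32) ? ((uint64_t(1) << (2 * k)) - 1) : ~uint64_t(0);
  int run = 0;
  for (int i = 0; i < ns; ++i) {
    if (s[i] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | uint64_t(s[i])) & mask;
    if (++run >= k) index[key].push_back(i - k + 1);
  }
  // per-diagonal coverage: furthest query end already explained
  std::unordered_map<long long, int> covered;
  struct Block { int qs, qe, ss; int matches; };
  std::vector<Block> blocks;
  key = 0; run = 0;
  for (int i = 0; i < nq; ++i) {
    if (q[i] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | uint64_t(q[i])) & mask;
    if (++run < k) continue;
    int qpos = i - k + 1;
    auto it = index.find(key);
    if (it == index.end()) continue;
    for (int spos : it->second) {
      long long diag = (long long)qpos - (long long)spos;
      auto cv = covered.find(diag);
      if (cv != covered.end() && qpos < cv->second) continue;
      // extend right from seed end
      double sc = match * k, bestsc = sc;
      int qe = qpos + k, se = spos + k, bq = qe;
      while (qe < nq && se < ns && q[qe] >= 0 && s[se] >= 0) {
        sc += (q[qe] == s[se]) ? match : mismatch;
        ++qe; ++se;
        if (sc > bestsc) { bestsc = sc; bq = qe; }
        else if (bestsc - sc > xdrop) break;
      }
      int right_end = bq;
      // extend left from seed start
      sc = bestsc;
      double bestsc2 = sc;
      int qs = qpos, ss = spos, bqs = qs;
      while (qs > 0 && ss > 0 && q[qs - 1] >= 0 && s[ss - 1] >= 0) {
        sc += (q[qs - 1] == s[ss - 1]) ? match : mismatch;
        --qs; --ss;
        if (sc > bestsc2) { bestsc2 = sc; bqs = qs; }
        else if (bestsc2 - sc > xdrop) break;
      }
      int left_start = bqs;
      // count matches over [left_start, right_end)
      int mt = 0;
      for (int p = left_start; p < right_end; ++p)
        if (q[p] == s[p - (int)diag]) ++mt;
      Block b;
      b.qs = left_start; b.qe = right_end;
      b.ss = left_start - (int)diag; b.matches = mt;
      blocks.push_back(b);
      covered[diag] = right_end;
    }
  }
  // merge same-diagonal blocks that overlap or sit within `bridge` bases
  std::sort(blocks.begin(), blocks.end(), [](const Block &a, const Block &b) {
    long long da = (long long)a.qs - a.ss, db = (long long)b.qs - b.ss;
    if (da != db) return da < db;
    return a.qs < b.qs;
  });
  std::vector<Block> merged;
  for (auto &b : blocks) {
    if (!merged.empty()) {
      Block &p = merged.back();
      long long dp = (long long)p.qs - p.ss, db = (long long)b.qs - b.ss;
      if (dp == db && b.qs <= p.qe + bridge) {
        if (b.qe > p.qe) {
          int mt = 0;
          int ns_off = (int)dp;
          int qe = std::max(p.qe, b.qe);
          for (int pp = p.qs; pp < qe; ++pp)
            if (q[pp] >= 0 && q[pp] == s[pp - ns_off]) ++mt;
          p.qe = qe; p.matches = mt;
        }
        continue;
      }
    }
    merged.push_back(b);
  }
  NumericMatrix out(merged.size(), 7);
  for (size_t r = 0; r < merged.size(); ++r) {
    const Block &b = merged[r];
    int len = b.qe - b.qs;
    out(r, 0) = b.qs; out(r, 1) = b.qe;
    out(r, 2) = b.ss; out(r, 3) = b.ss + len;
    out(r, 4) = len; out(r, 5) = b.matches;
    out(r, 6) = b.matches * match + (len - b.matches) * mismatch;
  }
  colnames(out) = CharacterVector::create("qstart", "qend", "sstart", "send",
                                          "length", "matches", "score");
  return out;
}

// All window sums of a position matrix over an integer-encoded sequence
// (used by the EM motif E-step). Returns numeric(0) when the sequence is
// shorter than the matrix width.
// [[Rcpp::export]]
NumericVector cpp_window_scores(IntegerVector seq, NumericMatrix mat) {
  int n = seq.size(), w = mat.ncol();
  if (n < w) return NumericVector(0);
  NumericVector out(n - w + 1);
  for (int i = 0; i + w <= n; ++i) {
    double sc = 0.0;
    for (int j = 0; j < w; ++j) sc += mat(seq[i + j], j);
    out[i] = sc;
  }
  return out;
}

// Best ungapped window score of a PSSM over an integer-encoded sequence.
// pssm: alphabet_size x width. Returns c(score, start0) or c(-Inf, -1)
// when the sequence is shorter than the profile.
// [[Rcpp::export]]
NumericVector cpp_pssm_scan(IntegerVector seq, NumericMatrix pssm) {
  int n = seq.size(), w = pssm.ncol();
  if (n < w) return NumericVector::create(R_NegInf, -1);
  double best = R_NegInf;
  int at = -1;
  for (int i = 0; i + w <= n; ++i) {
    double sc = 0.0;
    for (int j = 0; j < w; ++j) sc += pssm(seq[i + j], j);
    if (sc > best) { best = sc; at = i; }
  }
  return NumericVector::create(best, at);
}
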