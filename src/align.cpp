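#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine gap model: a gap of length L costs gap_open + L * gap_extend
// (BLAST "existence/extension" convention; linear gaps = gap_open 0).

static const double NEG_INF = -1e30;

// score-only alignment, two rolling rows, O(min) memory
static double score_only(const int* q, int n, const int* s, int m,
                         const double* sm, int A,
                         double go, double ge, bool local) {
  std::vector<double> H(m + 1), F(m + 1), Hd(m + 1);
  double best = local ? 0.0 : NEG_INF;
  H[0] = 0.0;
  F[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    H[j] = local ? 0.0 : -(go + j * ge);
    F[j] = NEG_INF;
  }
  for (int i = 1; i <= n; ++i) {
    std::swap(H, Hd);
    H[0] = local ? 0.0 : -(go + i * ge);
    double E = NEG_INF;                                 // gap in query, row-local
    const double* srow = sm + (size_t)(q[i - 1]) * A;
    for (int j = 1; j <= m; ++j) {
      E = std::max(H[j - 1] - go - ge, E - ge);         // horizontal: from current row
      F[j] = std::max(Hd[j] - go - ge, F[j] - ge);      // vertical: from previous row
      double diag = Hd[j - 1] + srow[s[j - 1]];
      double h = std::max(diag, std::max(E, F[j]));
      if (local && h < 0) h = 0;
      H[j] = h;
      if (local && h > best) best = h;
    }
  }
  if (!local) best = H[m];
  return best;
}

// [[Rcpp::export]]
double cpp_align_score(IntegerVector q, IntegerVector s, NumericMatrix sm,
                       double gap_open, double gap_extend, bool local) {
  return score_only(INTEGER(q), q.size(), INTEGER(s), s.size(),
                    REAL(sm), sm.nrow(), gap_open, gap_extend, local);
}

// [[Rcpp::export]]
NumericVector cpp_score_many(IntegerVector q, List subjects, NumericMatrix sm,
                             double gap_open, double gap_extend, bool local) {
  int ns = subjects.size();
  NumericVector out(ns);
  for (int k = 0; k < ns; ++k) {
    IntegerVector s = subjects[k];
    out[k] = score_only(INTEGER(q), q.size(), INTEGER(s), s.size(),
                        REAL(sm), sm.nrow(), gap_open, gap_extend, local);
  }
  return out;
}

// All-vs-all local scores over a protein list; returns triplets (i, j, score)
// for i < j with score >= min_score.  If pairs is non-empty (2-column,
// 1-based), only those pairs are scored (and all are returned).
// [[Rcpp::export]]
List cpp_allvsall_scores(List seqs, NumericMatrix sm, double gap_open,
                         double gap_extend, double min_score,
                         IntegerMatrix pairs) {
  int n = seqs.size();
  std::vector<std::vector<int> > enc(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs[i];
    enc[i].assign(INTEGER(v), INTEGER(v) + v.size());
  }
  std::vector<int> ii, jj;
  std::vector<double> sc;
  const double* S = REAL(sm);
  int A = sm.nrow();
  if (pairs.nrow() > 0) {
    for (int r = 0; r < pairs.nrow(); ++r) {
      int a = pairs(r, 0) - 1, b = pairs(r, 1) - 1;
      double v = score_only(enc[a].data(), enc[a].size(), enc[b].data(),
                            enc[b].size(), S, A, gap_open, gap_extend, true);
      ii.push_back(a + 1); jj.push_back(b + 1); sc.push_back(v);
    }
  } else {
    for (int a = 0; a < n; ++a) {
      for (int b = a + 1; b < n; ++b) {
        double v = score_only(enc[a].data(), enc[a].size(), enc[b].data(),
                              enc[b].size(), S, A, gap_open, gap_extend, true);
        if (v >= min_score) {
          ii.push_back(a + 1); jj.push_back(b + 1); sc.push_back(v);
        }
      }
      if (a % 64 == 0) Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["score"] = wrap(sc));
}

// Full alignment with traceback.  Returns score, 1-based aligned coordinates,
// match/column counts and a CIGAR-like string (M = aligned pair,
// I = gap in subject (query residue), D = gap in query).
// [[Rcpp::export]]
List cpp_pair_align(IntegerVector qv, IntegerVector sv, NumericMatrix sm,
                    double gap_open, double gap_extend, bool local) {
  int n = qv.size(), m = sv.size();
  const int* q = INTEGER(qv);
  const int* s = INTEGER(sv);
  const double* S = REAL(sm);
  int A = sm.nrow();
  size_t W = (size_t)(m + 1);
  std::vector<double> H((n + 1) * W), E((n + 1) * W), F((n + 1) * W);
  // traceback codes: in H: 0 stop(local), 1 diag, 2 from E, 3 from F
  // in E: bit open(1)/extend(0); in F likewise
  std::vector<unsigned char> tH((n + 1) * W), tE((n + 1) * W), tF((n + 1) * W);
  H[0] = 0; E[0] = F[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    H[j] = local ? 0 : -(gap_open + j * gap_extend);
    E[j] = local ? NEG_INF : H[j];
    F[j] = NEG_INF;
    tH[j] = local ? 0 : 2; tE[j] = (j == 1) ? 1 : 0;
  }
  for (int i = 1; i <= n; ++i) {
    size_t r = i * W, rp = (i - 1) * W;
    H[r] = local ? 0 : -(gap_open + i * gap_extend);
    E[r] = NEG_INF;
    F[r] = local ? NEG_INF : H[r];
    tH[r] = local ? 0 : 3; tF[r] = (i == 1) ? 1 : 0;
    for (int j = 1; j <= m; ++j) {
      double eo = H[r + j - 1] - gap_open - gap_extend;
      double ee = E[r + j - 1] - gap_extend;
      if (eo >= ee) { E[r + j] = eo; tE[r + j] = 1; }
      else          { E[r + j] = ee; tE[r + j] = 0; }
      double fo = H[rp + j] - gap_open - gap_extend;
      double fe = F[rp + j] - gap_extend;
      if (fo >= fe) { F[r + j] = fo; tF[r + j] = 1; }
      else          { F[r + j] = fe; tF[r + j] = 0; }
      double diag = H[rp + j - 1] + S[(size_t)q[i - 1] * A + s[j - 1]];
      double h = diag; unsigned char t = 1;
      if (E[r + j] > h) { h = E[r + j]; t = 2; }
      if (F[r + j] > h) { h = F[r + j]; t = 3; }
      if (local && h <= 0) { h = 0; t = 0; }
      H[r + j] = h; tH[r + j] = t;
    }
  }
  // end cell
  int bi = n, bj = m;
  double best = H[n * W + m];
  if (local) {
    best = 0; bi = 0; bj = 0;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j)
        if (H[i * W + j] > best) { best = H[i * W + j]; bi = i; bj = j; }
  }
  // traceback
  std::string ops;
  int i = bi, j = bj, matches = 0, gapopens = 0;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char t = tH[i * W + j];
      if (local && t == 0) break;
      if (!local && i == 0) { state = 1; continue; }
      if (!local && j == 0) { state = 2; continue; }
      if (t == 1) {
        ops.push_back('M');
        if (q[i - 1] == s[j - 1]) ++matches;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char t = tE[i * W + j];
      ops.push_back('D'); // gap in query, subject residue consumed
      --j;
      if (t == 1) { state = 0; ++gapopens; }
    } else {
      unsigned char t = tF[i * W + j];
      ops.push_back('I'); // query residue consumed, gap in subject
      --i;
      if (t == 1) { state = 0; ++gapopens; }
    }
    if (local && i == 0 && j == 0) break;
    if (local && state == 0 && tH[i * W + j] == 0) break;
  }
  std::reverse(ops.begin(), ops.end());
  int qstart = i + 1, sstart = j + 1;
  int cols = ops.size();
  int qal = 0, sal = 0;
  for (int k = 0; k < cols; ++k) {
    if (ops[k] != 'D') ++qal;
    if (ops[k] != 'I') ++sal;
  }
  // compress cigar
  std::string cigar;
  for (int k = 0; k < cols;) {
    int k2 = k;
    while (k2 < cols && ops[k2] == ops[k]) ++k2;
    cigar += std::to_string(k2 - k);
    cigar.push_back(ops[k]);
    k = k2;
  }
  return List::create(
    _["score"] = best, _["qstart"] = qstart, _["qend"] = qstart + qal - 1,
    _["sstart"] = sstart, _["send"] = sstart + sal - 1,
    _["matches"] = matches, _["aligned_cols"] = cols,
    _["q_aligned"] = qal, _["s_aligned"] = sal,
    _["gapopens"] = gapopens, _["cigar"] = cigar);
}

// Local alignment of a sequence against a position-specific score matrix
// (rows = profile columns, cols = alphabet).  Gap penalties are shared by
// profile and sequence gaps.  Returns score and aligned spans.
// [[Rcpp::export]]
List cpp_pssm_align(NumericMatrix pssm, IntegerVector sv, double gap_open,
                    double gap_extend) {
  int n = pssm.nrow(), m = sv.size(), A = pssm.ncol();
  const int* s = INTEGER(sv);
  const double* P = REAL(pssm); // column-major: P[col * n + row]
  size_t W = (size_t)(m + 1);
  std::vector<double> H((n + 1) * W), E((n + 1) * W), F((n + 1) * W);
  std::vector<unsigned char> tH((n + 1) * W), tE((n + 1) * W), tF((n + 1) * W);
  for (int j = 0; j <= m; ++j) { H[j] = 0; E[j] = F[j] = NEG_INF; tH[j] = 0; }
  for (int i = 1; i <= n; ++i) {
    size_t r = i * W, rp = (i - 1) * W;
    H[r] = 0; E[r] = F[r] = NEG_INF; tH[r] = 0;
    for (int j = 1; j <= m; ++j) {
      double eo = H[r + j - 1] - gap_open - gap_extend;
      double ee = E[r + j - 1] - gap_extend;
      if (eo >= ee) { E[r + j] = eo; tE[r + j] = 1; } else { E[r + j] = ee; tE[r + j] = 0; }
      double fo = H[rp + j] - gap_open - gap_extend;
      double fe = F[rp + j] - gap_extend;
      if (fo >= fe) { F[r + j] = fo; tF[r + j] = 1; } else { F[r + j] = fe; tF[r + j] = 0; }
      double diag = H[rp + j - 1] + P[(size_t)s[j - 1] * n + (i - 1)];
      double h = diag; unsigned char t = 1;
      if (E[r + j] > h) { h = E[r + j]; t = 2; }
      if (F[r + j] > h) { h = F[r + j]; t = 3; }
      if (h <= 0) { h = 0; t = 0; }
      H[r + j] = h; tH[r + j] = t;
    }
  }
  int bi = 0, bj = 0; double best = 0;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j)
      if (H[i * W + j] > best) { best = H[i * W + j]; bi = i; bj = j; }
  int i = bi, j = bj, state = 0, pcols = 0, scols = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char t = tH[i * W + j];
      if (t == 0) break;
      if (t == 1) { ++pcols; ++scols; --i; --j; }
      else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char t = tE[i * W + j]; ++scols; --j; if (t == 1) state = 0;
    } else {
      unsigned char t = tF[i * W + j]; ++pcols; --i; if (t == 1) state = 0;
    }
    if (state == 0 && tH[i * W + j] == 0) break;
  }
  return List::create(
    _["score"] = best,
    _["prof_start"] = i + 1, _["prof_end"] = bi,
    _["seq_start"] = j + 1, _["seq_end"] = bj,
    _["prof_cols"] = pcols, _["seq_cols"] = scols);
}

// Maximal-scoring ungapped segments over a +/- score vector (HSPs along
// a shared diagonal), linear scan: each positive excursion of the
// running score contributes its maximal prefix segment, trimmed to
// start and end on matches.  Input: 0/1 match vector; scores:
// match -> match_score, mismatch -> mismatch_score (< 0).
// Returns matrix with columns start, end (1-based inclusive), score, matches.
// [[Rcpp::export]]
NumericMatrix cpp_max_segments(IntegerVector matchvec, double match_score,
                               double mismatch_score, double min_score) {
  int n = matchvec.size();
  std::vector<double> out;
  double c = 0, best_c = 0;
  int s = 0, best_end = -1, nm = 0, best_nm = 0;
  auto emit = [&]() {
    if (best_end >= s && best_c >= min_score) {
      out.push_back(s + 1); out.push_back(best_end + 1);
      out.push_back(best_c); out.push_back(best_nm);
    }
  };
  for (int k = 0; k < n; ++k) {
    int m = matchvec[k];
    c += m ? match_score : mismatch_score;
    nm += m;
    if (c > best_c) { best_c = c; best_end = k; best_nm = nm; }
    if (c < 0) {
      emit();
      c = 0; best_c = 0; nm = 0; best_nm = 0; s = k + 1; best_end = k;
    }
  }
  emit();
  NumericMatrix res(out.size() / 4, 4);
  for (size_t r = 0; r < out.size() / 4; ++r)
    for (int cc = 0; cc < 4; ++cc) res(r, cc) = out[r * 4 + cc];
  colnames(res) = CharacterVector::create("start", "end", "score", "matches");
  return res;
}
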