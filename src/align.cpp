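// Dynamic-programming kernels: local/global affine-gap alignment (full and
// banded), x-drop ungapped extension, frameshift-aware translated alignment,
// and the forward-backward recursion of the tandem-repeat masking model.
//
// Sequences arrive as 0-based integer codes into the scoring matrix.
// Gap model: a gap of length k costs gap_open + k * gap_extend.
// Transcript ops: M aligned pair, I gap in subject (query letter consumed
// alone), D gap in query, '/' reverse frameshift (2 nt), '\' forward
// frameshift (4 nt).

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const int NEG_INF = -100000000;

// traceback codes for H
enum TB { TB_NONE = 0, TB_DIAG = 1, TB_E = 2, TB_F = 3 };

static List empty_alignment() {
  return List::create(_["score"] = 0, _["qstart"] = 0, _["qend"] = -1,
                      _["sstart"] = 0, _["send"] = -1, _["transcript"] = "");
}

// Shared core for full and banded local alignment. Band constraint:
// d_min <= j - i <= d_max on 0-based coordinates; pass a huge band for the
// full-matrix case.
static List sw_core(const IntegerVector& q, const IntegerVector& s,
                    const IntegerMatrix& mat, int gapopen, int gapext,
                    int dmin, int dmax) {
  const int m = q.size(), n = s.size();
  if (m == 0 || n == 0) stop("empty sequence");
  if (dmin > dmax) stop("invalid band");
  // reject a band that excludes every cell
  if (dmax < -(m - 1) || dmin > n - 1) stop("band excludes all cells");

  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG_INF),
      F((m + 1) * (n + 1), NEG_INF);
  std::vector<unsigned char> tbH((m + 1) * (n + 1), TB_NONE),
      tbE((m + 1) * (n + 1), 0), tbF((m + 1) * (n + 1), 0);
  const int W = n + 1;
#define IDX(i, j) ((i) * W + (j))

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int d = (j - 1) - (i - 1);
      if (d < dmin || d > dmax) {
        H[IDX(i, j)] = NEG_INF;  // outside band: unusable
        continue;
      }
      // E: gap in query (consume s[j-1]); predecessor at (i, j-1)
      int e_open = (H[IDX(i, j - 1)] <= NEG_INF / 2)
                       ? NEG_INF
                       : H[IDX(i, j - 1)] - gapopen - gapext;
      int e_ext = (E[IDX(i, j - 1)] <= NEG_INF / 2) ? NEG_INF
                                                    : E[IDX(i, j - 1)] - gapext;
      int e = std::max(e_open, e_ext);
      E[IDX(i, j)] = e;
      tbE[IDX(i, j)] = (e_ext > e_open) ? 1 : 0;
      // F: gap in subject (consume q[i-1]); predecessor at (i-1, j)
      int f_open = (H[IDX(i - 1, j)] <= NEG_INF / 2)
                       ? NEG_INF
                       : H[IDX(i - 1, j)] - gapopen - gapext;
      int f_ext = (F[IDX(i - 1, j)] <= NEG_INF / 2) ? NEG_INF
                                                    : F[IDX(i - 1, j)] - gapext;
      int f = std::max(f_open, f_ext);
      F[IDX(i, j)] = f;
      tbF[IDX(i, j)] = (f_ext > f_open) ? 1 : 0;

      int hd = H[IDX(i - 1, j - 1)];
      int diag = (hd <= NEG_INF / 2) ? NEG_INF : hd + mat(q[i - 1], s[j - 1]);
      int h = 0;
      unsigned char tb = TB_NONE;
      if (diag > h) { h = diag; tb = TB_DIAG; }
      if (e > h) { h = e; tb = TB_E; }
      if (f > h) { h = f; tb = TB_F; }
      H[IDX(i, j)] = h;
      tbH[IDX(i, j)] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0) return empty_alignment();

  // traceback
  std::string tr;
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char tb = tbH[IDX(i, j)];
      if (tb == TB_NONE) break;
      if (tb == TB_DIAG) { tr.push_back('M'); --i; --j; }
      else if (tb == TB_E) state = 1;
      else state = 2;
    } else if (state == 1) {
      tr.push_back('D');
      if (tbE[IDX(i, j)] == 0) state = 0;
      --j;
    } else {
      tr.push_back('I');
      if (tbF[IDX(i, j)] == 0) state = 0;
      --i;
    }
  }
  std::reverse(tr.begin(), tr.end());
#undef IDX
  return List::create(_["score"] = best, _["qstart"] = i, _["qend"] = bi - 1,
                      _["sstart"] = j, _["send"] = bj - 1,
                      _["transcript"] = tr);
}

// [[Rcpp::export]]
List sw_full_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                 int gapopen, int gapext) {
  int m = q.size(), n = s.size();
  return sw_core(q, s, mat, gapopen, gapext, -(m + 1), n + 1);
}

// [[Rcpp::export]]
List sw_banded_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                   int gapopen, int gapext, int dmin, int dmax) {
  return sw_core(q, s, mat, gapopen, gapext, dmin, dmax);
}

// Global (Needleman-Wunsch) affine-gap alignment with traceback.
// [[Rcpp::export]]
List nw_global_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                   int gapopen, int gapext) {
  const int m = q.size(), n = s.size();
  if (m == 0 || n == 0) stop("empty sequence");
  std::vector<int> H((m + 1) * (n + 1), NEG_INF), E((m + 1) * (n + 1), NEG_INF),
      F((m + 1) * (n + 1), NEG_INF);
  std::vector<unsigned char> tbH((m + 1) * (n + 1), 0),
      tbE((m + 1) * (n + 1), 0), tbF((m + 1) * (n + 1), 0);
  const int W = n + 1;
#define IDX(i, j) ((i) * W + (j))
  H[IDX(0, 0)] = 0;
  for (int j = 1; j <= n; ++j) {
    E[IDX(0, j)] = -gapopen - gapext * j;
    tbE[IDX(0, j)] = (j > 1) ? 1 : 0;
    H[IDX(0, j)] = E[IDX(0, j)];
    tbH[IDX(0, j)] = TB_E;
  }
  for (int i = 1; i <= m; ++i) {
    F[IDX(i, 0)] = -gapopen - gapext * i;
    tbF[IDX(i, 0)] = (i > 1) ? 1 : 0;
    H[IDX(i, 0)] = F[IDX(i, 0)];
    tbH[IDX(i, 0)] = TB_F;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e_open = H[IDX(i, j - 1)] - gapopen - gapext;
      int e_ext = E[IDX(i, j - 1)] - gapext;
      E[IDX(i, j)] = std::max(e_open, e_ext);
      tbE[IDX(i, j)] = (e_ext > e_open) ? 1 : 0;
      int f_open = H[IDX(i - 1, j)] - gapopen - gapext;
      int f_ext = F[IDX(i - 1, j)] - gapext;
      F[IDX(i, j)] = std::max(f_open, f_ext);
      tbF[IDX(i, j)] = (f_ext > f_open) ? 1 : 0;
      int diag = H[IDX(i - 1, j - 1)] + mat(q[i - 1], s[j - 1]);
      int h = diag;
      unsigned char tb = TB_DIAG;
      if (E[IDX(i, j)] > h) { h = E[IDX(i, j)]; tb = TB_E; }
      if (F[IDX(i, j)] > h) { h = F[IDX(i, j)]; tb = TB_F; }
      H[IDX(i, j)] = h;
      tbH[IDX(i, j)] = tb;
    }
  }
  std::string tr;
  int i = m, j = n, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char tb = tbH[IDX(i, j)];
      if (tb == TB_DIAG) { tr.push_back('M'); --i; --j; }
      else if (tb == TB_E) state = 1;
      else state = 2;
    } else if (state == 1) {
      tr.push_back('D');
      if (tbE[IDX(i, j)] == 0) state = 0;
      --j;
    } else {
      tr.push_back('I');
      if (tbF[IDX(i, j)] == 0) state = 0;
      --i;
    }
  }
  std::reverse(tr.begin(), tr.end());
  int score = H[IDX(m, n)];
#undef IDX
  return List::create(_["score"] = score, _["transcript"] = tr);
}

// Two-sided x-drop ungapped extension around a seed hit.
// qpos/spos are 0-based starts of the seed span. Returns
// (qstart, sstart, length, score), 0-based start coordinates.
// [[Rcpp::export]]
IntegerVector ungapped_extend_cpp(IntegerVector q, IntegerVector s, int qpos,
                                  int spos, int span, IntegerMatrix mat,
                                  int xdrop) {
  const int m = q.size(), n = s.size();
  if (qpos < 0 || spos < 0 || qpos + span > m || spos + span > n)
    stop("seed out of range");
  int core = 0;
  for (int k = 0; k < span; ++k) core += mat(q[qpos + k], s[spos + k]);
  // left extension
  int run = 0, bestL = 0, lenL = 0;
  for (int i = qpos - 1, j = spos - 1, k = 1; i >= 0 && j >= 0; --i, --j, ++k) {
    run += mat(q[i], s[j]);
    if (run > bestL) { bestL = run; lenL = k; }
    if (run < bestL - xdrop) break;
  }
  // right extension
  run = 0;
  int bestR = 0, lenR = 0;
  for (int i = qpos + span, j = spos + span, k = 1; i < m && j < n;
       ++i, ++j, ++k) {
    run += mat(q[i], s[j]);
    if (run > bestR) { bestR = run; lenR = k; }
    if (run < bestR - xdrop) break;
  }
  return IntegerVector::create(qpos - lenL, spos - lenL, span + lenL + lenR,
                               core + bestL + bestR);
}

// Frameshift-aware local alignment of a nucleotide read (codes 0..3, >=4 =
// ambiguous) against a protein subject. Codon moves consume 3 nt; frameshift
// moves consume 2 or 4 nt at penalty fshift; the emitted residue is always
// the translation of the last 3 nt consumed. Protein-level gaps are affine.
// codon_table: length-64 vector mapping 16*n1+4*n2+n3 to a residue code;
// ambiguous codons translate to x_code.
// [[Rcpp::export]]
List frameshift_sw_cpp(IntegerVector nt, IntegerVector s, IntegerMatrix mat,
                       int gapopen, int gapext, int fshift,
                       IntegerVector codon_table, int x_code) {
  const int n = nt.size(), m = s.size();
  if (n < 3) stop("read shorter than one codon");
  if (m == 0) stop("empty subject");
  std::vector<int> H((n + 1) * (m + 1), NEG_INF), E((n + 1) * (m + 1), NEG_INF),
      F((n + 1) * (m + 1), NEG_INF);
  // tbH: 0 none/stop, 1 codon(3), 2 fs(2), 3 fs(4), 4 from E, 5 from F
  std::vector<unsigned char> tbH((n + 1) * (m + 1), 0),
      tbE((n + 1) * (m + 1), 0), tbF((n + 1) * (m + 1), 0);
  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) H[IDX(i, j)] = 0;  // local: free start

  auto aa_at = [&](int i) {  // residue for the 3 nt ending at position i-1
    int a = nt[i - 3], b = nt[i - 2], c = nt[i - 1];
    if (a > 3 || b > 3 || c > 3) return x_code;
    return (int)codon_table[16 * a + 4 * b + c];
  };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: gap in subject (codon consumed, no subject residue)
      if (i >= 3) {
        int e_open = H[IDX(i - 3, j)] - gapopen - gapext;
        int e_ext =
            (E[IDX(i - 3, j)] <= NEG_INF / 2) ? NEG_INF : E[IDX(i - 3, j)] - gapext;
        E[IDX(i, j)] = std::max(e_open, e_ext);
        tbE[IDX(i, j)] = (e_ext > e_open) ? 1 : 0;
      }
      // F: gap in query (subject residue consumed alone)
      {
        int f_open = H[IDX(i, j - 1)] - gapopen - gapext;
        int f_ext =
            (F[IDX(i, j - 1)] <= NEG_INF / 2) ? NEG_INF : F[IDX(i, j - 1)] - gapext;
        F[IDX(i, j)] = std::max(f_open, f_ext);
        tbF[IDX(i, j)] = (f_ext > f_open) ? 1 : 0;
      }
      int h = 0;
      unsigned char tb = 0;
      if (i >= 3) {
        int em = mat(aa_at(i), s[j - 1]);
        int sc = H[IDX(i - 3, j - 1)] + em;
        if (sc > h) { h = sc; tb = 1; }
        // 2-nt frameshift: translation context is still the 3 nt ending at
        // i-1, but only 2 new nucleotides are consumed
        int sc2 = H[IDX(i - 2, j - 1)] + em - fshift;
        if (sc2 > h) { h = sc2; tb = 2; }
        if (i >= 4) {
          int sc4 = H[IDX(i - 4, j - 1)] + em - fshift;
          if (sc4 > h) { h = sc4; tb = 3; }
        }
      }
      if (E[IDX(i, j)] > h) { h = E[IDX(i, j)]; tb = 4; }
      if (F[IDX(i, j)] > h) { h = F[IDX(i, j)]; tb = 5; }
      H[IDX(i, j)] = h;
      tbH[IDX(i, j)] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0, _["qstart_nt"] = 0, _["qend_nt"] = -1,
                        _["sstart"] = 0, _["send"] = -1, _["transcript"] = "");
  std::string tr;
  int i = bi, j = bj, state = 0;
  while (i > 0 && j >= 0) {
    if (state == 0) {
      unsigned char tb = tbH[IDX(i, j)];
      if (tb == 0) break;
      if (tb == 1) { tr.push_back('M'); i -= 3; --j; }
      else if (tb == 2) { tr.push_back('/'); i -= 2; --j; }
      else if (tb == 3) { tr.push_back('\\'); i -= 4; --j; }
      else if (tb == 4) state = 1;
      else state = 2;
    } else if (state == 1) {
      tr.push_back('I');
      if (tbE[IDX(i, j)] == 0) state = 0;
      i -= 3;
    } else {
      tr.push_back('D');
      if (tbF[IDX(i, j)] == 0) state = 0;
      --j;
    }
  }
  std::reverse(tr.begin(), tr.end());
#undef IDX
  return List::create(_["score"] = best, _["qstart_nt"] = i, _["qend_nt"] = bi - 1,
                      _["sstart"] = j, _["send"] = bj - 1, _["transcript"] = tr);
}

// Forward-backward posteriors of the tandem-repeat model: one background
// state plus repeat states for copy offsets d = 1..D. Emission likelihood
// ratio of repeat state d at position i is exp(scale * S(x[i], x[i-d])).
// Transitions: bg->rep_d = rho * w_d (w_d geometric with 'decay'),
// rep->bg = eps, rep_d->rep_d = 1 - eps.
// [[Rcpp::export]]
NumericVector tantan_posteriors_cpp(IntegerVector x, IntegerMatrix mat,
                                    int D, double rho, double eps,
                                    double decay, double scale) {
  const int n = x.size();
  NumericVector post(n, 0.0);
  if (n == 0) return post;
  int Dn = std::min(D, n - 1);
  if (Dn < 1) return post;
  std::vector<double> w(Dn + 1, 0.0);
  double wsum = 0.0;
  for (int d = 1; d <= Dn; ++d) { w[d] = std::pow(decay, d); wsum += w[d]; }
  for (int d = 1; d <= Dn; ++d) w[d] = w[d] / wsum;

  // likelihood ratios r[i][d]; 0 when i < d
  auto ratio = [&](int i, int d) -> double {
    if (i < d) return 0.0;
    double s = (double)mat(x[i], x[i - d]);
    double e = scale * s;
    if (e > 40) e = 40;  // cap to avoid overflow on long perfect repeats
    return std::exp(e);
  };

  // forward, scaled: fb = background, fr[d] = repeat d
  std::vector<double> fb(n), fr((size_t)n * (Dn + 1), 0.0);
  std::vector<double> cs(n);  // scaling factors
  fb[0] = 1.0;
  cs[0] = 1.0;
  for (int i = 1; i < n; ++i) {
    double sum_fr_prev = 0.0;
    for (int d = 1; d <= Dn; ++d) sum_fr_prev += fr[(size_t)(i - 1) * (Dn + 1) + d];
    double b = fb[i - 1] * (1.0 - rho) + sum_fr_prev * eps;
    double tot = b;
    for (int d = 1; d <= Dn; ++d) {
      double in = fb[i - 1] * rho * w[d] +
                  fr[(size_t)(i - 1) * (Dn + 1) + d] * (1.0 - eps);
      double v = in * ratio(i, d);
      fr[(size_t)i * (Dn + 1) + d] = v;
      tot += v;
    }
    if (tot <= 0) tot = 1e-300;
    cs[i] = tot;
    fb[i] = b / tot;
    for (int d = 1; d <= Dn; ++d) fr[(size_t)i * (Dn + 1) + d] /= tot;
  }
  // backward, same scaling
  std::vector<double> bb(n), br((size_t)n * (Dn + 1), 0.0);
  bb[n - 1] = 1.0;
  for (int d = 1; d <= Dn; ++d) br[(size_t)(n - 1) * (Dn + 1) + d] = 1.0;
  for (int i = n - 2; i >= 0; --i) {
    // from background at i
    double acc = bb[i + 1] * (1.0 - rho);
    for (int d = 1; d <= Dn; ++d)
      acc += rho * w[d] * ratio(i + 1, d) * br[(size_t)(i + 1) * (Dn + 1) + d];
    bb[i] = acc / cs[i + 1];
    for (int d = 1; d <= Dn; ++d) {
      double a = eps * bb[i + 1] +
                 (1.0 - eps) * ratio(i + 1, d) * br[(size_t)(i + 1) * (Dn + 1) + d];
      br[(size_t)i * (Dn + 1) + d] = a / cs[i + 1];
    }
  }
  for (int i = 0; i < n; ++i) {
    double pb = fb[i] * bb[i];
    double pr = 0.0;
    for (int d = 1; d <= Dn; ++d)
      pr += fr[(size_t)i * (Dn + 1) + d] * br[(size_t)i * (Dn + 1) + d];
    double tot = pb + pr;
    post[i] = (tot > 0) ? pr / tot : 0.0;
  }
  return post;
}

// Count identical letters between two equal-length windows (integer codes).
// [[Rcpp::export]]
int count_identities_cpp(IntegerVector a, IntegerVector b) {
  if (a.size() != b.size()) stop("unequal window lengths");
  int c = 0;
  for (int i = 0; i < a.size(); ++i)
    if (a[i] == b[i]) ++c;
  return c;
}

// Fused early-filter kernel: for a batch of seed matches of one shape,
// apply the Hamming window filter, x-drop ungapped extension with a
// per-query minimum-score cut-off, and the leftmost redundancy filter
// (precomputed discard table over the bit-encoded local hit pattern).
// Returns the surviving diagonal segments as rows
// (q_ord, s_ord, qstart, sstart, length, score).
// [[Rcpp::export]]
IntegerMatrix filter_matches_cpp(List qenc, List senc, IntegerVector q_ord,
                                 IntegerVector q_off, IntegerVector s_ord,
                                 IntegerVector s_off, int span,
                                 IntegerMatrix mat, int xdrop,
                                 int hamming_cutoff, int window,
                                 NumericVector min_score_by_query,
                                 LogicalVector discard_table,
                                 int pattern_window) {
  const int nm = q_ord.size();
  std::vector<int> out;
  out.reserve(64 * 6);
  for (int r = 0; r < nm; ++r) {
    IntegerVector q = qenc[q_ord[r] - 1];
    IntegerVector s = senc[s_ord[r] - 1];
    const int qp = q_off[r], sp = s_off[r];
    const int m = q.size(), n = s.size();
    // Hamming window: starts window/2 left of the seed, clipped identically
    int left = std::min(window / 2, std::min(qp, sp));
    int right = std::min(window - left, std::min(m - qp, n - sp));
    int wlen = left + right;
    int ids = 0;
    for (int k = 0; k < wlen; ++k)
      if (q[qp - left + k] == s[sp - left + k]) ++ids;
    if (ids < (hamming_cutoff * wlen) / window) continue;
    // ungapped x-drop extension
    int core = 0;
    for (int k = 0; k < span; ++k) core += mat(q[qp + k], s[sp + k]);
    int run = 0, bestL = 0, lenL = 0;
    for (int i = qp - 1, j = sp - 1, k = 1; i >= 0 && j >= 0; --i, --j, ++k) {
      run += mat(q[i], s[j]);
      if (run > bestL) { bestL = run; lenL = k; }
      if (run < bestL - xdrop) break;
    }
    run = 0;
    int bestR = 0, lenR = 0;
    for (int i = qp + span, j = sp + span, k = 1; i < m && j < n;
         ++i, ++j, ++k) {
      run += mat(q[i], s[j]);
      if (run > bestR) { bestR = run; lenR = k; }
      if (run < bestR - xdrop) break;
    }
    int score = core + bestL + bestR;
    if ((double)score < min_score_by_query[q_ord[r] - 1]) continue;
    // leftmost redundancy filter via the precomputed pattern table
    if (discard_table.size() > 0) {
      int code = 0;
      for (int k = 0; k < pattern_window; ++k) {
        int qi = qp + span - pattern_window + k;
        int si = sp + span - pattern_window + k;
        if (qi >= 0 && si >= 0 && q[qi] == s[si]) code |= (1 << k);
      }
      if (discard_table[code]) continue;
    }
    out.push_back(q_ord[r]);
    out.push_back(s_ord[r]);
    out.push_back(qp - lenL);
    out.push_back(sp - lenL);
    out.push_back(span + lenL + lenR);
    out.push_back(score);
  }
  const int nr = out.size() / 6;
  IntegerMatrix res(nr, 6);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < 6; ++j) res(i, j) = out[6 * i + j];
  return res;
}

// Per-diagonal maximal ungapped scores (query-profile sweep): for every
// diagonal d in [dmin, dmax], the best contiguous ungapped score on that
// diagonal (at least 0). Feeds the gapped-score heuristic filter.
// [[Rcpp::export]]
IntegerMatrix diagonal_max_scores_cpp(IntegerVector q, IntegerVector s,
                                      IntegerMatrix mat, int dmin, int dmax) {
  const int m = q.size(), n = s.size();
  if (dmin < -(m - 1)) dmin = -(m - 1);
  if (dmax > n - 1) dmax = n - 1;
  if (dmin > dmax) return IntegerMatrix(0, 2);
  std::vector<int> diags, bests;
  for (int d = dmin; d <= dmax; ++d) {
    int i0 = (d < 0) ? -d : 0;
    int run = 0, best = 0;
    for (int i = i0; i < m && i + d < n; ++i) {
      run += mat(q[i], s[i + d]);
      if (run < 0) run = 0;
      if (run > best) best = run;
    }
    diags.push_back(d);
    bests.push_back(best);
  }
  IntegerMatrix out(diags.size(), 2);
  for (size_t k = 0; k < diags.size(); ++k) {
    out(k, 0) = diags[k];
    out(k, 1) = bests[k];
  }
  return out;
}
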