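#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh). A gap of length
// L costs gap_open + L * gap_extend. Sequences arrive as 1-based integer
// codes into the rows/cols of the substitution matrix.
//
// Two cores: a score-only pass (fast, used for all-vs-all screening) and a
// full pass that also tracks the origin cell of the best alignment, giving
// the aligned span in each sequence without traceback matrices.

struct SwResult {
  int score;
  int a_start, a_end, b_start, b_end; // 1-based inclusive; 0s when empty
};

// origin encoding: the cell (i0, j0) just BEFORE the alignment start,
// packed as i0 * (m + 1) + j0
static SwResult sw_core(const int *a, int n, const int *b, int m,
                        const int *sub, int nrow,
                        int gap_open, int gap_extend) {
  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_extend;

  std::vector<int> bs(m);
  for (int j = 0; j < m; ++j) bs[j] = (b[j] - 1) * nrow;
  std::vector<int> H(m + 1, 0), Fv(m + 1, NEG);   // Fv: vertical gap state
  std::vector<int> oH(m + 1), oF(m + 1, 0);
  for (int j = 0; j <= m; ++j) oH[j] = j;         // row 0: origin (0, j)

  int best = 0, best_i = 0, best_j = 0, best_o = 0;

  for (int i = 1; i <= n; ++i) {
    int Hdiag = H[0], oDiag = oH[0];
    H[0] = 0; oH[0] = i * (m + 1);
    int E = NEG, oE = 0;                           // horizontal gap state
    const int *srow = sub + (a[i - 1] - 1);
    for (int j = 1; j <= m; ++j) {
      // vertical gap: extend down column j from the previous row
      int f_open = H[j] - open_cost;               // H[j] still = H[i-1][j]
      int f_ext = Fv[j] - gap_extend;
      if (f_open >= f_ext) { Fv[j] = f_open; oF[j] = oH[j]; }
      else Fv[j] = f_ext;
      // horizontal gap: extend along row i from H[i][j-1]
      int e_open = H[j - 1] - open_cost;           // H[j-1] already row i
      int e_ext = E - gap_extend;
      if (e_open >= e_ext) { E = e_open; oE = oH[j - 1]; }
      else E = e_ext;

      int diag = Hdiag + srow[bs[j - 1]];
      int h = 0, oh = (i - 1) * (m + 1) + (j - 1); // fresh start at (i, j)
      if (diag > h) { h = diag; oh = oDiag; }
      if (E > h) { h = E; oh = oE; }
      if (Fv[j] > h) { h = Fv[j]; oh = oF[j]; }

      Hdiag = H[j]; oDiag = oH[j];
      H[j] = h; oH[j] = oh;
      if (h > best) { best = h; best_i = i; best_j = j; best_o = oh; }
    }
  }

  SwResult r;
  r.score = best;
  if (best > 0) {
    r.a_start = best_o / (m + 1) + 1;
    r.b_start = best_o % (m + 1) + 1;
    r.a_end = best_i;
    r.b_end = best_j;
  } else {
    r.a_start = r.a_end = r.b_start = r.b_end = 0;
  }
  return r;
}

// score-only core; bs = pre-scaled codes (b[j]-1)*nrow; H/Fv are caller-
// provided scratch buffers of size >= m+1 (hoisted out of all-vs-all loops)
static int sw_score_core(const int *a, int n, const int *bs, int m,
                         const int *sub, int *H, int *Fv,
                         int gap_open, int gap_extend) {
  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_extend;
  for (int j = 0; j <= m; ++j) { H[j] = 0; Fv[j] = NEG; }
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = H[0];
    int E = NEG;
    const int *srow = sub + (a[i - 1] - 1);
    for (int j = 1; j <= m; ++j) {
      int f = H[j] - open_cost, f2 = Fv[j] - gap_extend;
      Fv[j] = f >= f2 ? f : f2;
      int e = H[j - 1] - open_cost, e2 = E - gap_extend;
      E = e >= e2 ? e : e2;
      int h = Hdiag + srow[bs[j - 1]];
      if (h < 0) h = 0;
      if (E > h) h = E;
      if (Fv[j] > h) h = Fv[j];
      Hdiag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
List sw_align_ints(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                   int gap_open, int gap_extend) {
  if (a.size() == 0 || b.size() == 0)
    return List::create(_["score"] = 0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  SwResult r = sw_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                       INTEGER(sub), sub.nrow(), gap_open, gap_extend);
  return List::create(_["score"] = r.score, _["a_start"] = r.a_start,
                      _["a_end"] = r.a_end, _["b_start"] = r.b_start,
                      _["b_end"] = r.b_end);
}

// All-vs-all score matrix (score-only fast pass).
// [[Rcpp::export]]
NumericMatrix sw_score_only_matrix(List A, List B, IntegerMatrix sub,
                                   int gap_open, int gap_extend) {
  int nA = A.size(), nB = B.size(), nrow = sub.nrow();
  const int *S = INTEGER(sub);
  NumericMatrix score(nA, nB);

  // copy + pre-scale all sequences once
  std::vector< std::vector<int> > av(nA), bv(nB);
  int mmax = 1;
  for (int i = 0; i < nA; ++i) {
    IntegerVector v = A[i];
    av[i].assign(INTEGER(v), INTEGER(v) + v.size());
  }
  for (int j = 0; j < nB; ++j) {
    IntegerVector v = B[j];
    bv[j].resize(v.size());
    for (int k = 0; k < v.size(); ++k) bv[j][k] = (v[k] - 1) * nrow;
    if (v.size() + 1 > mmax) mmax = v.size() + 1;
  }
  std::vector<int> H(mmax + 1), Fv(mmax + 1);

  for (int i = 0; i < nA; ++i) {
    for (int j = 0; j < nB; ++j) {
      if (av[i].empty() || bv[j].empty()) { score(i, j) = 0; continue; }
      score(i, j) = sw_score_core(av[i].data(), av[i].size(),
                                  bv[j].data(), bv[j].size(), S,
                                  H.data(), Fv.data(),
                                  gap_open, gap_extend);
    }
    Rcpp::checkUserInterrupt();
  }
  return score;
}

// Aligned-span coverage for selected (i, j) pairs: fraction of the shorter
// sequence covered by the optimal local alignment.
// [[Rcpp::export]]
NumericVector sw_cov_pairs(List A, List B, IntegerVector ii, IntegerVector jj,
                           IntegerMatrix sub, int gap_open, int gap_extend) {
  int np = ii.size();
  NumericVector cov(np);
  for (int k = 0; k < np; ++k) {
    IntegerVector a = as<IntegerVector>(A[ii[k] - 1]);
    IntegerVector b = as<IntegerVector>(B[jj[k] - 1]);
    if (a.size() == 0 || b.size() == 0) { cov[k] = 0; continue; }
    SwResult r = sw_core(INTEGER(a), a.size(), INTEGER(b), b.size(),
                         INTEGER(sub), sub.nrow(), gap_open, gap_extend);
    if (r.score <= 0) { cov[k] = 0; continue; }
    int span_a = r.a_end - r.a_start + 1;
    int span_b = r.b_end - r.b_start + 1;
    cov[k] = a.size() <= b.size() ? (double)span_a / a.size()
                                  : (double)span_b / b.size();
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return cov;
}
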