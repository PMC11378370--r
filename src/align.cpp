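#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>

using namespace Rcpp;

// Affine gap convention throughout: a gap run of length k costs
// gap_open + k * gap_extend (both arguments are negative scores).

static const int NEG = INT_MIN / 4; // safe -infinity

static inline int sub_score(char a, char b, int match, int mismatch) {
  return (a == b) ? match : mismatch;
}

// Glocal (global in query, local in target) affine-gap score, O(n) memory.
// Returns the best score and the 1-based target end position of an optimal
// alignment. Ties: smallest end position unless tie_last, in which case the
// largest (used by the reverse pass to find the leftmost start).
// [[Rcpp::export]]
List glocal_score_cpp(std::string q, std::string t,
                      int match, int mismatch, int gap_open, int gap_extend,
                      bool tie_last = false) {
  int m = q.size(), n = t.size();
  if (m == 0) stop("empty query");
  std::vector<int> M(n + 1), X(n + 1), Y(n + 1);
  std::vector<int> Mp(n + 1), Xp(n + 1), Yp(n + 1);
  // row 0: free start anywhere in the target
  for (int j = 0; j <= n; ++j) { Mp[j] = 0; Xp[j] = NEG; Yp[j] = NEG; }
  for (int i = 1; i <= m; ++i) {
    // column 0: whole query prefix gapped
    M[0] = NEG; Y[0] = NEG;
    X[0] = gap_open + i * gap_extend;
    for (int j = 1; j <= n; ++j) {
      int diag = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      M[j] = (diag <= NEG) ? NEG : diag + sub_score(q[i - 1], t[j - 1], match, mismatch);
      int x1 = (Mp[j] <= NEG) ? NEG : Mp[j] + gap_open + gap_extend;
      int x2 = (Xp[j] <= NEG) ? NEG : Xp[j] + gap_extend;
      int x3 = (Yp[j] <= NEG) ? NEG : Yp[j] + gap_open + gap_extend;
      X[j] = std::max(x1, std::max(x2, x3));
      int y1 = (M[j - 1] <= NEG) ? NEG : M[j - 1] + gap_open + gap_extend;
      int y2 = (Y[j - 1] <= NEG) ? NEG : Y[j - 1] + gap_extend;
      int y3 = (X[j - 1] <= NEG) ? NEG : X[j - 1] + gap_open + gap_extend;
      Y[j] = std::max(y1, std::max(y2, y3));
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  int best = NEG, bestj = 0;
  for (int j = 0; j <= n; ++j) {
    int s = std::max(Mp[j], Xp[j]); // ending in a gapped target char is never better
    if (s > best || (tie_last && s == best)) { best = s; bestj = j; }
  }
  return List::create(_["score"] = best, _["end"] = bestj);
}

// Full glocal alignment with traceback. Intended for window-sized targets;
// find_orthologue() locates the window with the score-only scan first.
// [[Rcpp::export]]
List glocal_align_cpp(std::string q, std::string t,
                      int match, int mismatch, int gap_open, int gap_extend) {
  int m = q.size(), n = t.size();
  if (m == 0) stop("empty query");
  if ((double)(m + 1) * (n + 1) > 6e7)
    stop("target too long for traceback; use the score scan first");
  int W = n + 1;
  std::vector<int> M((m + 1) * W, NEG), X((m + 1) * W, NEG), Y((m + 1) * W, NEG);
  // traceback: predecessor state 0=M,1=X,2=Y,3=free start
  std::vector<unsigned char> TM((m + 1) * W), TX((m + 1) * W), TY((m + 1) * W);
  for (int j = 0; j <= n; ++j) M[j] = 0;           // free start row
  for (int i = 1; i <= m; ++i) {
    X[i * W] = gap_open + i * gap_extend;
    TX[i * W] = (i == 1) ? 3 : 1;
    for (int j = 1; j <= n; ++j) {
      int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j, l = i * W + (j - 1);
      // M
      int bs = M[d]; unsigned char bt = (i == 1) ? 3 : 0;
      if (X[d] > bs) { bs = X[d]; bt = 1; }
      if (Y[d] > bs) { bs = Y[d]; bt = 2; }
      if (bs > NEG) { M[c] = bs + sub_score(q[i - 1], t[j - 1], match, mismatch); TM[c] = bt; }
      // X (query char vs gap)
      bs = (M[u] <= NEG) ? NEG : M[u] + gap_open + gap_extend; bt = (i == 1) ? 3 : 0;
      int cand = (X[u] <= NEG) ? NEG : X[u] + gap_extend;
      if (cand > bs) { bs = cand; bt = 1; }
      cand = (Y[u] <= NEG) ? NEG : Y[u] + gap_open + gap_extend;
      if (cand > bs) { bs = cand; bt = 2; }
      if (bs > NEG) { X[c] = bs; TX[c] = bt; }
      // Y (target char vs gap)
      bs = (M[l] <= NEG) ? NEG : M[l] + gap_open + gap_extend; bt = 0;
      cand = (Y[l] <= NEG) ? NEG : Y[l] + gap_extend;
      if (cand > bs) { bs = cand; bt = 2; }
      cand = (X[l] <= NEG) ? NEG : X[l] + gap_open + gap_extend;
      if (cand > bs) { bs = cand; bt = 1; }
      if (bs > NEG) { Y[c] = bs; TY[c] = bt; }
    }
  }
  int best = NEG, bestj = 0, bestst = 0;
  for (int j = 0; j <= n; ++j) {
    int c = m * W + j;
    if (M[c] > best) { best = M[c]; bestj = j; bestst = 0; }
    if (X[c] > best) { best = X[c]; bestj = j; bestst = 1; }
  }
  // traceback
  std::string qa, ta;
  int i = m, j = bestj, st = bestst;
  int tend = bestj;
  while (i > 0) {
    int c = i * W + j;
    unsigned char pr;
    if (st == 0) {
      pr = TM[c];
      qa.push_back(q[i - 1]); ta.push_back(t[j - 1]);
      --i; --j;
    } else if (st == 1) {
      pr = TX[c];
      qa.push_back(q[i - 1]); ta.push_back('-');
      --i;
    } else {
      pr = TY[c];
      qa.push_back('-'); ta.push_back(t[j - 1]);
      --j;
    }
    if (pr == 3) break;
    st = pr;
  }
  int tstart = j + 1;
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  return List::create(_["score"] = best, _["query_aligned"] = qa,
                      _["target_aligned"] = ta,
                      _["target_start"] = tstart, _["target_end"] = tend);
}

// Progressive-MSA step: global affine alignment of two base-count profiles
// (4 x L integer matrices, rows A,C,G,T; gaps carry zero counts).
// Column-pair score = mean pairwise substitution score over base draws.
// End gaps are costed (true global alignment).
// Returns op codes along the merged alignment: 1 = column from both,
// 2 = column from A (gap in B), 3 = column from B (gap in A).
// [[Rcpp::export]]
List profile_align_cpp(IntegerMatrix A, IntegerMatrix B,
                       double match, double mismatch,
                       double gap_open, double gap_extend) {
  if (A.nrow() != 4 || B.nrow() != 4) stop("profiles must have 4 rows (A,C,G,T)");
  int m = A.ncol(), n = B.ncol();
  const double DNEG = -1e18;
  // precompute column totals
  std::vector<double> na(m), nb(n);
  for (int i = 0; i < m; ++i) { double s = 0; for (int r = 0; r < 4; ++r) s += A(r, i); na[i] = s; }
  for (int j = 0; j < n; ++j) { double s = 0; for (int r = 0; r < 4; ++r) s += B(r, j); nb[j] = s; }
  int W = n + 1;
  std::vector<double> M((m + 1) * W, DNEG), X((m + 1) * W, DNEG), Y((m + 1) * W, DNEG);
  std::vector<unsigned char> TM((m + 1) * W), TX((m + 1) * W), TY((m + 1) * W);
  M[0] = 0;
  for (int i = 1; i <= m; ++i) { X[i * W] = gap_open + i * gap_extend; TX[i * W] = (i == 1) ? 0 : 1; }
  for (int j = 1; j <= n; ++j) { Y[j] = gap_open + j * gap_extend; TY[j] = (j == 1) ? 0 : 2; }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // column score
      double agree = 0;
      for (int r = 0; r < 4; ++r) agree += (double)A(r, i - 1) * B(r, j - 1);
      double tot = na[i - 1] * nb[j - 1];
      double s = (tot > 0) ? (agree * match + (tot - agree) * mismatch) / tot : 0.0;
      int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j, l = i * W + (j - 1);
      double bs = M[d]; unsigned char bt = 0;
      if (X[d] > bs) { bs = X[d]; bt = 1; }
      if (Y[d] > bs) { bs = Y[d]; bt = 2; }
      M[c] = bs + s; TM[c] = bt;
      bs = M[u] + gap_open + gap_extend; bt = 0;
      if (X[u] + gap_extend > bs) { bs = X[u] + gap_extend; bt = 1; }
      if (Y[u] + gap_open + gap_extend > bs) { bs = Y[u] + gap_open + gap_extend; bt = 2; }
      X[c] = bs; TX[c] = bt;
      bs = M[l] + gap_open + gap_extend; bt = 0;
      if (Y[l] + gap_extend > bs) { bs = Y[l] + gap_extend; bt = 2; }
      if (X[l] + gap_open + gap_extend > bs) { bs = X[l] + gap_open + gap_extend; bt = 1; }
      Y[c] = bs; TY[c] = bt;
    }
  }
  int c = m * W + n;
  double best = M[c]; int st = 0;
  if (X[c] > best) { best = X[c]; st = 1; }
  if (Y[c] > best) { best = Y[c]; st = 2; }
  std::vector<int> ops;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    int cc = i * W + j;
    if (st == 0) { ops.push_back(1); st = TM[cc]; --i; --j; }
    else if (st == 1) { ops.push_back(2); st = TX[cc]; --i; }
    else { ops.push_back(3); st = TY[cc]; --j; }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
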