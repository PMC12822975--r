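#include <Rcpp.h>
using namespace Rcpp;

// Semi-global affine-gap alignment of a candidate sequence to a fixed
// profile (one score per column x residue). Deletions (candidate skips a
// profile column) are scaled by the column's non-gap occupancy and are
// free before the first and after the last candidate residue, so fragment
// candidates are not penalised for the anchor span they do not cover.
// Insertions (candidate residues creating no column) are penalised and
// dropped from the returned placement.
//
// cand:   0-based residue indices into the alphabet, length m
// smat:   ncol x nres matrix, smat(j, a) = score of residue a at column j
// occ:    per-column non-gap occupancy in [0,1], length ncol
// Returns an integer vector of length ncol: 1-based candidate index
// placed at each column, or 0 for a gap.
// [[Rcpp::export]]
IntegerVector profile_align_cpp(IntegerVector cand, NumericMatrix smat,
                                NumericVector occ, double gap_open,
                                double gap_ext) {
  const int m = cand.size();
  const int n = smat.nrow();
  const double NEG = -1e30;
  // state matrices, (m+1) x (n+1)
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  IntegerMatrix tM(m + 1, n + 1), tX(m + 1, n + 1), tY(m + 1, n + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int j = 1; j <= n; ++j) {      // free leading deletions
    M(0, j) = NEG; X(0, j) = NEG; Y(0, j) = 0.0; tY(0, j) = 2;
  }
  for (int i = 1; i <= m; ++i) {      // leading insertions are penalised
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + (i - 1) * gap_ext);
    tX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int i = 1; i <= m; ++i) {
    const bool last = (i == m);
    for (int j = 1; j <= n; ++j) {
      const double s = smat(j - 1, cand[i - 1]);
      // match: best predecessor at (i-1, j-1); prefer M, then X, then Y
      double bm = M(i - 1, j - 1); int am = 0;
      if (X(i - 1, j - 1) > bm) { bm = X(i - 1, j - 1); am = 1; }
      if (Y(i - 1, j - 1) > bm) { bm = Y(i - 1, j - 1); am = 2; }
      M(i, j) = bm + s; tM(i, j) = am;
      // insertion: consume candidate residue i, stay at column j
      double bx = M(i - 1, j) - gap_open; int ax = 0;
      if (X(i - 1, j) - gap_ext > bx) { bx = X(i - 1, j) - gap_ext; ax = 1; }
      if (Y(i - 1, j) - gap_open > bx) { bx = Y(i - 1, j) - gap_open; ax = 2; }
      X(i, j) = bx; tX(i, j) = ax;
      // deletion: gap column j; free after the last candidate residue
      const double dgo = last ? 0.0 : gap_open * occ[j - 1];
      const double dge = last ? 0.0 : gap_ext * occ[j - 1];
      double by = M(i, j - 1) - dgo; int ay = 0;
      if (X(i, j - 1) - dgo > by) { by = X(i, j - 1) - dgo; ay = 1; }
      if (Y(i, j - 1) - dge > by) { by = Y(i, j - 1) - dge; ay = 2; }
      Y(i, j) = by; tY(i, j) = ay;
    }
  }
  // traceback from (m, n), best of the three states (prefer M, X, Y)
  int st = 0; double best = M(m, n);
  if (X(m, n) > best) { best = X(m, n); st = 1; }
  if (Y(m, n) > best) { best = Y(m, n); st = 2; }
  IntegerVector placement(n, 0);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (st == 0) {                    // match consumed (i, j)
      if (i == 0 || j == 0) break;
      placement[j - 1] = i;
      st = tM(i, j); --i; --j;
    } else if (st == 1) {             // insertion consumed i
      st = tX(i, j); --i;
    } else {                          // deletion consumed column j
      st = tY(i, j); --j;
      if (i == 0 && j == 0) break;
    }
  }
  return placement;
}
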