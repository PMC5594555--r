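#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch / Gotoh) alignment of two profiles given the
// precomputed column-vs-column score matrix S (rows = profile A columns,
// cols = profile B columns). Affine gaps: a gap of length L costs
// gap_open + gap_extend * L. End gaps are penalized like internal gaps.
// Returns 1-based column indices into A and B along the alignment path,
// with 0 marking a gap.

// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow();
  const int m = S.ncol();
  const double NEG = -1e18;
  // DP layers: M (match), X (gap in B, consume A), Y (gap in A, consume B)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG;
    Y(i, 0) = NEG;
    X(i, 0) = -gap_open - gap_extend * i;
    tbX(i, 0) = 1; // from X
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG;
    X(0, j) = NEG;
    Y(0, j) = -gap_open - gap_extend * j;
    tbY(0, j) = 2; // from Y
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume one column of each
      double m0 = M(i - 1, j - 1), x0 = X(i - 1, j - 1), y0 = Y(i - 1, j - 1);
      int tb = 0; double best = m0;
      if (x0 > best) { best = x0; tb = 1; }
      if (y0 > best) { best = y0; tb = 2; }
      M(i, j) = best + S(i - 1, j - 1);
      tbM(i, j) = tb;
      // X: gap in B (consume A column i)
      double openx = M(i - 1, j) - gap_open - gap_extend;
      double extx = X(i - 1, j) - gap_extend;
      double ycrossx = Y(i - 1, j) - gap_open - gap_extend;
      if (openx >= extx && openx >= ycrossx) { X(i, j) = openx; tbX(i, j) = 0; }
      else if (extx >= ycrossx) { X(i, j) = extx; tbX(i, j) = 1; }
      else { X(i, j) = ycrossx; tbX(i, j) = 2; }
      // Y: gap in A (consume B column j)
      double openy = M(i, j - 1) - gap_open - gap_extend;
      double exty = Y(i, j - 1) - gap_extend;
      double xcrossy = X(i, j - 1) - gap_open - gap_extend;
      if (openy >= exty && openy >= xcrossy) { Y(i, j) = openy; tbY(i, j) = 0; }
      else if (exty >= xcrossy) { Y(i, j) = exty; tbY(i, j) = 1; }
      else { Y(i, j) = xcrossy; tbY(i, j) = 2; }
    }
  }
  // traceback
  int i = n, j = m;
  int layer = 0;
  double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); layer = 1; }
  if (Y(n, m) > best) { best = Y(n, m); layer = 2; }
  std::vector<int> ai, bi;
  while (i > 0 || j > 0) {
    if (layer == 0) {
      int prev = tbM(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      layer = prev;
    } else if (layer == 1) {
      int prev = tbX(i, j);
      ai.push_back(i); bi.push_back(0);
      --i;
      layer = prev;
    } else {
      int prev = tbY(i, j);
      ai.push_back(0); bi.push_back(j);
      --j;
      layer = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi), _["score"] = best);
}
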