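#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Gotoh global alignment with affine gap costs.
//
// a, b: 1-based indices into the substitution matrix rows/cols.
// A gap of length l costs gap_open + gap_extend * l. With
// penalize_ends = false, leading and trailing gaps are free (ends-free
// global alignment, the convention of EMBOSS Needle's default endweight).
//
// Returns the optimal score and one optimal alignment as two integer
// vectors over the alignment columns: the 1-based residue position in each
// sequence, or 0 for a gap.
//
// States: M ends in an aligned pair, X ends with a gap in b (consumes a),
// Y ends with a gap in a (consumes b).
// [[Rcpp::export]]
List needle_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                      double gap_open, double gap_extend,
                      bool penalize_ends) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  if ((double)(n + 1) * (double)(m + 1) > 4e7)
    stop("sequences too long for pairwise alignment");
  const double NEG = -1e30;
  const double GO = gap_open + gap_extend;  // cost of a new length-1 gap
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i)
    X[i * W] = penalize_ends ? -(gap_open + gap_extend * i) : 0.0;
  for (int j = 1; j <= m; ++j)
    Y[j] = penalize_ends ? -(gap_open + gap_extend * j) : 0.0;

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, up = c - W, lf = c - 1, dg = up - 1;
      const double s = sub(ai, b[j - 1] - 1);
      M[c] = s + std::max(M[dg], std::max(X[dg], Y[dg]));
      X[c] = std::max(M[up] - GO, std::max(X[up] - gap_extend, Y[up] - GO));
      Y[c] = std::max(M[lf] - GO, std::max(Y[lf] - gap_extend, X[lf] - GO));
    }
  }

  // end cell: (n, m) if end gaps are charged, otherwise the best cell on
  // the last row/column (remaining residues become free trailing gaps)
  int bi = n, bj = m;
  double best = std::max(M[n * W + m], std::max(X[n * W + m], Y[n * W + m]));
  if (!penalize_ends) {
    for (int j = m; j >= 0; --j) {
      const size_t c = n * W + j;
      const double v = std::max(M[c], std::max(X[c], Y[c]));
      if (v > best) { best = v; bi = n; bj = j; }
    }
    for (int i = n; i >= 0; --i) {
      const size_t c = i * W + m;
      const double v = std::max(M[c], std::max(X[c], Y[c]));
      if (v > best) { best = v; bi = i; bj = m; }
    }
  }

  // traceback (columns collected right-to-left, reversed at the end)
  std::vector<int> colA, colB;
  colA.reserve(n + m);
  colB.reserve(n + m);
  for (int j = m; j > bj; --j) { colA.push_back(0); colB.push_back(j); }
  for (int i = n; i > bi; --i) { colA.push_back(i); colB.push_back(0); }

  int i = bi, j = bj;
  size_t c = (size_t)i * W + j;
  int state;  // 0 = M, 1 = X, 2 = Y, preference M > X > Y on ties
  if (M[c] >= X[c] && M[c] >= Y[c]) state = 0;
  else if (X[c] >= Y[c]) state = 1;
  else state = 2;

  while (i > 0 && j > 0) {
    c = (size_t)i * W + j;
    if (state == 0) {
      colA.push_back(i); colB.push_back(j);
      const size_t dg = c - W - 1;
      if (M[dg] >= X[dg] && M[dg] >= Y[dg]) state = 0;
      else if (X[dg] >= Y[dg]) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      colA.push_back(i); colB.push_back(0);
      const size_t up = c - W;
      const double v = X[c];
      if (v == M[up] - GO) state = 0;
      else if (v == X[up] - gap_extend) state = 1;
      else state = 2;
      --i;
    } else {
      colA.push_back(0); colB.push_back(j);
      const size_t lf = c - 1;
      const double v = Y[c];
      if (v == M[lf] - GO) state = 0;
      else if (v == Y[lf] - gap_extend) state = 2;
      else state = 1;
      --j;
    }
  }
  for (; j > 0; --j) { colA.push_back(0); colB.push_back(j); }
  for (; i > 0; --i) { colA.push_back(i); colB.push_back(0); }

  std::reverse(colA.begin(), colA.end());
  std::reverse(colB.begin(), colB.end());
  return List::create(_["score"] = best,
                      _["a_pos"] = IntegerVector(colA.begin(), colA.end()),
                      _["b_pos"] = IntegerVector(colB.begin(), colB.end()));
}
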