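#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Best-scoring window of one protein against a query composition.
//
// seq:  residue codes, 1..20 canonical (AA_CANONICAL order), 21 non-canonical
// qnum, qden: query percent of amino acid a is 100 * qnum[a] / qden
//   (qnum = integer residue counts and qden = query length when the query is
//   a sequence, so distances have exact integer-valued numerators and ties
//   can be broken exactly by cross-multiplication).
//
// Window distance: d = 100/(qden*w) * sum_a |qnum[a]*w - cnt[a]*qden|
// (Manhattan), or the analogous root-sum-square for Euclidean. Counts are
// maintained incrementally (slide off one residue, on the next), so each
// window costs O(20) regardless of window size.
//
// Tie-breaking: smallest distance, then leftmost start, then largest window.
// [[Rcpp::export]]
List scan_best_window_cpp(IntegerVector seq, NumericVector qnum, double qden,
                          int minw, int maxw, bool euclidean, bool strict_nc) {
  const int L = seq.size();
  if (qnum.size() != 20) stop("query composition must have 20 entries");
  if (minw < 1 || minw > maxw) stop("invalid window range");
  double q[20];
  for (int a = 0; a < 20; ++a) q[a] = qnum[a];

  bool found = false;
  double bestKey = 0.0;   // metric numerator of the best window
  double bestNm = 0.0;    // Manhattan numerator of the best window (for CI)
  int bestW = 0, bestS = 0;
  double nwin = 0;
  std::vector<int> cnt(21);

  const int wmax = std::min(maxw, L);
  for (int w = minw; w <= wmax; ++w) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < w; ++i) cnt[seq[i] - 1]++;
    for (int s = 0; s + w <= L; ++s) {
      if (s > 0) {
        cnt[seq[s - 1] - 1]--;
        cnt[seq[s + w - 1] - 1]++;
      }
      nwin += 1;
      if (strict_nc && cnt[20] > 0) continue;
      double Nm = 0.0, Se = 0.0;
      for (int a = 0; a < 20; ++a) {
        double d = q[a] * w - (double)cnt[a] * qden;
        Nm += std::fabs(d);
        if (euclidean) Se += d * d;
      }
      const double key = euclidean ? Se : Nm;
      bool better, tie;
      if (!found) {
        better = true;
        tie = false;
      } else if (euclidean) {
        // d^2 = 1e4 * Se / (qden*w)^2 : compare Se cross-multiplied by w^2
        const double lhs = key * (double)bestW * (double)bestW;
        const double rhs = bestKey * (double)w * (double)w;
        better = lhs < rhs;
        tie = lhs == rhs;
      } else {
        // d = 100 * Nm / (qden*w) : compare Nm cross-multiplied by w
        const double lhs = key * (double)bestW;
        const double rhs = bestKey * (double)w;
        better = lhs < rhs;
        tie = lhs == rhs;
      }
      if (better || (tie && (s < bestS || (s == bestS && w > bestW)))) {
        found = true;
        bestKey = key;
        bestNm = Nm;
        bestW = w;
        bestS = s;
      }
    }
  }

  if (!found)
    return List::create(_["found"] = false, _["windows_evaluated"] = nwin);
  const double denom = qden * (double)bestW;
  const double dist = euclidean ? 100.0 * std::sqrt(bestKey) / denom
                                : 100.0 * bestKey / denom;
  const double ci = 100.0 - 50.0 * bestNm / denom;
  return List::create(_["found"] = true,
                      _["start"] = bestS + 1,
                      _["end"] = bestS + bestW,
                      _["window_length"] = bestW,
                      _["distance"] = dist,
                      _["ci"] = ci,
                      _["windows_evaluated"] = nwin);
}
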