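#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Sample-entropy pair counts (Richman & Moorman formulation).
//
// Over the N - m template vectors x_m(i) = (x[i], ..., x[i+m-1]),
// i = 0 .. N-m-1, counts unordered pairs i != j with Chebyshev distance
// <= r for length m (B) and for length m+1 (A). Self-matches excluded by
// construction; both counts use the same index range so the m+1 point
// x[i+m] always exists.
//
// A match requires |x[i] - x[j]| <= r in the first coordinate, so templates
// are visited in order of their first value and each is compared only
// against the window of templates within r of it; the counts are identical
// to the full pairwise scan.
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  if (N < m + 2) stop("series too short for pattern length m");
  const int nt = N - m;
  const double* p = x.begin();

  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return p[a] < p[b]; });

  double A = 0.0, B = 0.0;
  for (int a = 0; a < nt - 1; ++a) {
    const int i = ord[a];
    const double xi = p[i];
    for (int b = a + 1; b < nt; ++b) {
      const int j = ord[b];
      if (p[j] - xi > r) break;
      bool match = true;
      for (int k = 1; k < m; ++k) {
        if (std::abs(p[i + k] - p[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::abs(p[i + m] - p[j + m]) <= r) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
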