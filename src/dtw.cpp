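#include <Rcpp.h>
using namespace Rcpp;

// Weighted dynamic time warping between `seq` and `ref`.
//
// Local cost of matching seq[i] to ref[j] is w[|i-j|] * (seq[i]-ref[j])^2,
// with steps {(1,0),(0,1),(1,1)} over monotone, continuous, boundary-anchored
// paths. `w` must be indexable by phase lag 0 .. max(n,m)-1.
//
// Returns the optimal path cost and the warped sequence: for every ref index
// j, the mean of the seq values matched to j on the optimal path (ties in the
// DP broken towards the diagonal step, then the seq-advance step).
// [[Rcpp::export]]
List dtw_align_cpp(NumericVector seq, NumericVector ref, NumericVector w) {
  const int n = seq.size(), m = ref.size();
  if (n < 1 || m < 1) stop("sequences must be non-empty");
  if (w.size() < std::max(n, m)) stop("weight vector too short");

  NumericMatrix D(n, m);
  IntegerMatrix from(n, m);  // 0 = diag, 1 = seq-advance (i-1,j), 2 = ref-advance (i,j-1)

  auto lcost = [&](int i, int j) {
    const double d = seq[i] - ref[j];
    return w[std::abs(i - j)] * d * d;
  };

  D(0, 0) = lcost(0, 0);
  for (int i = 1; i < n; ++i) { D(i, 0) = D(i - 1, 0) + lcost(i, 0); from(i, 0) = 1; }
  for (int j = 1; j < m; ++j) { D(0, j) = D(0, j - 1) + lcost(0, j); from(0, j) = 2; }
  for (int i = 1; i < n; ++i) {
    for (int j = 1; j < m; ++j) {
      double best = D(i - 1, j - 1);
      int arg = 0;
      if (D(i - 1, j) < best) { best = D(i - 1, j); arg = 1; }
      if (D(i, j - 1) < best) { best = D(i, j - 1); arg = 2; }
      D(i, j) = best + lcost(i, j);
      from(i, j) = arg;
    }
  }

  NumericVector sums(m);
  IntegerVector counts(m);
  int i = n - 1, j = m - 1;
  for (;;) {
    sums[j] += seq[i];
    counts[j] += 1;
    if (i == 0 && j == 0) break;
    const int step = from(i, j);
    if (step == 0) { --i; --j; }
    else if (step == 1) { --i; }
    else { --j; }
  }
  NumericVector aligned(m);
  for (int k = 0; k < m; ++k) aligned[k] = sums[k] / counts[k];

  return List::create(_["aligned"] = aligned, _["cost"] = D(n - 1, m - 1));
}
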