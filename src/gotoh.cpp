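#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh) over a precomputed column-score matrix.
//
// States: 0 = M (a[i] paired with b[j]), 1 = X (gap in b, consumes a[i]),
// 2 = Y (gap in a, consumes b[j]).  A gap run of length k costs
// gap_open + (k - 1) * gap_extend; terminal gaps are penalized like internal
// ones (true global alignment).  Every argmax uses the fixed preference
// M > X > Y so the traceback is deterministic.
//
// Returns 1-based index paths into a and b (0 marks a gap) plus the score.
// [[Rcpp::export]]
List gotoh_core(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // traceback: predecessor state for each cell/state
  std::vector<signed char> tbM((n + 1) * W, -1), tbX((n + 1) * W, -1),
      tbY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = (i == 1) ? gap_open : X[(i - 1) * W] + gap_extend;
    tbX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = (j == 1) ? gap_open : Y[j - 1] + gap_extend;
    tbY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                l = i * W + (j - 1);
      // M: diagonal step
      double best = M[d];
      signed char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      M[c] = best + S(i - 1, j - 1);
      tbM[c] = arg;
      // X: vertical step (gap in b)
      best = M[u] + gap_open;
      arg = 0;
      if (X[u] + gap_extend > best) { best = X[u] + gap_extend; arg = 1; }
      if (Y[u] + gap_open > best) { best = Y[u] + gap_open; arg = 2; }
      X[c] = best;
      tbX[c] = arg;
      // Y: horizontal step (gap in a)
      best = M[l] + gap_open;
      arg = 0;
      if (X[l] + gap_open > best) { best = X[l] + gap_open; arg = 1; }
      if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; arg = 2; }
      Y[c] = best;
      tbY[c] = arg;
    }
  }

  const int end = n * W + m;
  double score = M[end];
  int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::vector<int> pa, pb;
  pa.reserve(n + m);
  pb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      state = tbM[c]; --i; --j;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      state = tbX[c]; --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      state = tbY[c]; --j;
    }
  }
  const int L = pa.size();
  IntegerVector ia(L), ib(L);
  for (int k = 0; k < L; ++k) {
    ia[k] = pa[L - 1 - k];
    ib[k] = pb[L - 1 - k];
  }
  return List::create(_["a"] = ia, _["b"] = ib, _["score"] = score);
}
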