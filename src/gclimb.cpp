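#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Maximal climb of the G function, G_k = k/n - x_k/L, over event pairs
// i < j for one sorted 1-based position vector.
static double max_climb(const int *x, int n, int L) {
  double best = R_NegInf, lo = R_PosInf;
  for (int k = 1; k <= n; ++k) {
    double g = (double)k / n - (double)x[k - 1] / L;
    if (k >= 2 && g - lo > best) best = g - lo;
    if (g < lo) lo = g;
  }
  return best;
}

// [[Rcpp::export(name = ".null_max_climb")]]
NumericVector null_max_climb(int n, int L, int B) {
  if (n < 2 || n > L) stop("need 2 <= n <= L");
  NumericVector out(B);
  std::vector<int> x(n);
  for (int b = 0; b < B; ++b) {
    IntegerVector s = sample(L, n, false); // uses R's RNG; values 1..L
    std::copy(s.begin(), s.end(), x.begin());
    std::sort(x.begin(), x.end());
    out[b] = max_climb(x.data(), n, L);
  }
  return out;
}
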