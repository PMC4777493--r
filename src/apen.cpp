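#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ApEn(m, r, N) = Phi_m(r) - Phi_{m+1}(r), Pincus definition: Phi_m is the
// mean over template positions of log(C_i^m(r)) with self-matches included
// and Chebyshev distance between epochs. Matching is symmetric, so each
// unordered pair is tested once and both template counts (length m and,
// where both templates extend, length m+1) are updated in the same pass.
// [[Rcpp::export]]
double apen_core(NumericVector x, int m, double r) {
  const int N = x.size();
  if (N < m + 2) stop("series too short for ApEn");
  if (r < 0) stop("tolerance r must be non-negative");
  const int M2 = N - m + 1;   // templates of length m
  const int M3 = N - m;       // templates of length m + 1
  const double* p = REAL(x);

  std::vector<double> c2(M2, 1.0), c3(M3, 1.0);  // self-matches
  for (int i = 0; i < M2; ++i) {
    for (int j = i + 1; j < M2; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(p[i + k] - p[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      c2[i] += 1.0; c2[j] += 1.0;
      if (i < M3 && j < M3 && std::fabs(p[i + m] - p[j + m]) <= r) {
        c3[i] += 1.0; c3[j] += 1.0;
      }
    }
  }

  double phi2 = 0.0, phi3 = 0.0;
  for (int i = 0; i < M2; ++i) phi2 += std::log(c2[i] / M2);
  for (int i = 0; i < M3; ++i) phi3 += std::log(c3[i] / M3);
  return phi2 / M2 - phi3 / M3;
}
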