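#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Rosenstein divergence curve: for every embedded point find its nearest
// neighbour at temporal separation > theiler, then average the log Euclidean
// separation of the pair as both trajectories evolve s = 0..max_steps.
// emb is the M x dim delay-embedding matrix. Returns mean log distance per
// step (NA where no pair contributed).
// [[Rcpp::export]]
NumericVector lle_divergence(NumericMatrix emb, int theiler, int max_steps) {
  const int M = emb.nrow();
  const int d = emb.ncol();
  const int usable = M - max_steps;
  if (usable < 2) stop("too few embedded points for the divergence horizon");

  std::vector<double> sums(max_steps + 1, 0.0);
  std::vector<long> counts(max_steps + 1, 0);

  for (int i = 0; i < usable; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < usable; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double dist = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = emb(i, k) - emb(j, k);
        dist += diff * diff;
        if (dist >= best) break;
      }
      if (dist < best) { best = dist; bj = j; }
    }
    if (bj < 0) continue;
    for (int s = 0; s <= max_steps; ++s) {
      double dist = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = emb(i + s, k) - emb(bj + s, k);
        dist += diff * diff;
      }
      if (dist > 0.0) {
        sums[s] += 0.5 * std::log(dist);
        counts[s] += 1;
      }
    }
  }

  NumericVector out(max_steps + 1);
  for (int s = 0; s <= max_steps; ++s) {
    out[s] = counts[s] > 0 ? sums[s] / counts[s] : NA_REAL;
  }
  return out;
}
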