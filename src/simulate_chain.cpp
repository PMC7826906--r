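#include <Rcpp.h>
using namespace Rcpp;

// Sequential sampling of a two-state chain; uses R's RNG so that
// set.seed() governs reproducibility. x0 is drawn by the caller.
// [[Rcpp::export(name = ".simulate_chain")]]
IntegerVector simulate_chain(int n, int x0, double p10, double p01) {
  IntegerVector out(n);
  int state = x0;
  out[0] = state;
  for (int k = 1; k < n; ++k) {
    double u = unif_rand();
    if (state == 0) {
      if (u < p10) state = 1;
    } else {
      if (u < p01) state = 0;
    }
    out[k] = state;
  }
  return out;
}
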