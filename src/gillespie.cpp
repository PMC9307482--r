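#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven (Gillespie) simulation of a linear birth-death process.
// Every cell divides at rate b and dies at rate d, so the population-level
// rates are n*b and n*d; 0 is absorbing. The path is recorded at t_grid.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cf_gillespie(int n_rep, double n0, double b, double d,
                           NumericVector t_grid) {
  const int K = t_grid.size();
  NumericMatrix out(n_rep, K);
  for (int rep = 0; rep < n_rep; ++rep) {
    double t = 0.0;
    double n = n0;
    for (int k = 0; k < K; ++k) {
      const double t_target = t_grid[k];
      while (n > 0.0) {
        const double rate = n * (b + d);
        const double dt = R::exp_rand() / rate;
        if (t + dt > t_target) break;
        t += dt;
        if (R::unif_rand() * (b + d) < b)
          n += 1.0;
        else
          n -= 1.0;
      }
      if (n <= 0.0) t = t_target; // absorbed; fast-forward
      out(rep, k) = n;
    }
    if (rep % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
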