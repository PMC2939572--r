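#include <Rcpp.h>
using namespace Rcpp;

// Closed-tour length of sigma (0-based indices) under dm.
static double tour_len(const NumericMatrix& dm, const std::vector<int>& s) {
  const int n = s.size();
  double e = dm(s[n - 1], s[0]);
  for (int k = 0; k + 1 < n; ++k) e += dm(s[k], s[k + 1]);
  return e;
}

// Simulated-annealing kernel. The move extracts the element at position k
// (1 <= k <= n-2, 0-based) and appends it at the end; only three tour edges
// change, so the energy delta is O(1). Random draws come from R's RNG
// (RNGScope), so set.seed() / withr::with_seed() on the R side makes runs
// reproducible. The uniform acceptance variate is drawn only for uphill
// proposals, matching the annealing pseudocode.
// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(NumericMatrix dm, IntegerVector sigma0, double t0,
                double cooling, double t_low, int reps) {
  const int n = dm.nrow();
  std::vector<int> sigma(n), best(n);
  for (int i = 0; i < n; ++i) sigma[i] = sigma0[i] - 1;
  best = sigma;
  double e = tour_len(dm, sigma);
  double best_e = e;
  long uphill = 0, iters = 0;
  std::vector<double> tr_temp, tr_cur, tr_best;

  RNGScope scope;
  double temp = t0;
  while (temp > t_low) {
    for (int r = 0; r < reps; ++r) {
      int k = 1 + (int)(unif_rand() * (n - 2));
      if (k > n - 2) k = n - 2;
      const int a = sigma[k - 1], b = sigma[k], c = sigma[k + 1];
      const int z = sigma[n - 1], h = sigma[0];
      const double delta = dm(a, c) + dm(z, b) + dm(b, h)
                         - dm(a, b) - dm(b, c) - dm(z, h);
      bool ok = delta <= 0.0;
      if (!ok) {
        ok = unif_rand() < std::exp(-delta / temp);
        if (ok) ++uphill;
      }
      if (ok) {
        sigma.erase(sigma.begin() + k);
        sigma.push_back(b);
        e += delta;
        if (e < best_e) {
          // recompute exactly so accumulated rounding cannot corrupt best
          e = tour_len(dm, sigma);
          if (e < best_e) {
            best_e = e;
            best = sigma;
          }
        }
      }
    }
    iters += reps;
    e = tour_len(dm, sigma);
    tr_temp.push_back(temp);
    tr_cur.push_back(e);
    tr_best.push_back(best_e);
    temp *= cooling;
  }

  IntegerVector out_sigma(n), out_best(n);
  for (int i = 0; i < n; ++i) {
    out_sigma[i] = sigma[i] + 1;
    out_best[i] = best[i] + 1;
  }
  return List::create(
    _["sigma"] = out_sigma, _["energy"] = e,
    _["best_sigma"] = out_best, _["best_energy"] = best_e,
    _["accepted_uphill"] = (double)uphill, _["iterations"] = (double)iters,
    _["trace_temperature"] = tr_temp, _["trace_current"] = tr_cur,
    _["trace_best"] = tr_best);
}
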