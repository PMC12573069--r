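#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Simulated-annealing minimization of the signed Spinglass Hamiltonian
//   H(c) = -sum_{i<j} M_ij * 1[c_i = c_j]
// where M is the signed null-adjusted coupling matrix
// (W+ - g+ P+) - (W- - g- P-), precomputed in R. Single-node Metropolis
// moves with geometric cooling; returns the lowest-energy assignment
// visited. Own RNG (mt19937) so runs are reproducible from a seed and
// independent of R's RNG stream.

// [[Rcpp::export]]
List spinglass_anneal(NumericMatrix M, int q, int seed,
                      double start_temp = 1.0, double stop_temp = 0.01,
                      double cooling = 0.99, int sweeps_per_temp = 5) {
  int p = M.ncol();
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_int_distribution<int> rlab(0, q - 1);
  std::uniform_int_distribution<int> rnode(0, p - 1);
  std::uniform_real_distribution<double> runif(0.0, 1.0);

  std::vector<int> c(p), best(p);
  for (int i = 0; i < p; ++i) c[i] = rlab(rng);

  double H = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j)
      if (c[i] == c[j]) H -= M(i, j);
  double bestH = H;
  best = c;

  for (double T = start_temp; T >= stop_temp; T *= cooling) {
    for (int s = 0; s < sweeps_per_temp; ++s) {
      for (int m = 0; m < p; ++m) {
        int node = rnode(rng);
        int oldc = c[node];
        int newc = rlab(rng);
        if (newc == oldc) continue;
        double a_old = 0.0, a_new = 0.0;
        for (int j = 0; j < p; ++j) {
          if (j == node) continue;
          if (c[j] == oldc) a_old += M(node, j);
          else if (c[j] == newc) a_new += M(node, j);
        }
        double dH = a_old - a_new;  // H_new - H_old
        if (dH <= 0.0 || runif(rng) < std::exp(-dH / T)) {
          c[node] = newc;
          H += dH;
          if (H < bestH - 1e-12) { bestH = H; best = c; }
        }
      }
    }
  }

  // zero-temperature refinement: move nodes to their best label until
  // no single-node move improves the energy (local optimum), starting
  // from the best assignment visited during cooling
  c = best;
  H = bestH;
  std::vector<double> gain(q);
  bool moved = true;
  int guard = 0;
  while (moved && guard++ < 1000) {
    moved = false;
    for (int node = 0; node < p; ++node) {
      std::fill(gain.begin(), gain.end(), 0.0);
      for (int j = 0; j < p; ++j) {
        if (j == node) continue;
        gain[c[j]] += M(node, j);
      }
      int oldc = c[node];
      int bestlab = oldc;
      double bestgain = gain[oldc];
      for (int l = 0; l < q; ++l)
        if (gain[l] > bestgain + 1e-12) { bestgain = gain[l]; bestlab = l; }
      if (bestlab != oldc) {
        H -= (gain[bestlab] - gain[oldc]);
        c[node] = bestlab;
        moved = true;
      }
    }
  }
  if (H < bestH - 1e-12) { bestH = H; best = c; }

  IntegerVector memb(p);
  for (int i = 0; i < p; ++i) memb[i] = best[i] + 1;
  return List::create(_["membership"] = memb, _["hamiltonian"] = bestH);
}
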