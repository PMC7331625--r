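#include <Rcpp.h>
using namespace Rcpp;

// Kingman coalescent with piecewise-constant diploid population size
// (epochs run backward in time from sampling; the last epoch is unbounded)
// and a bounded stepwise mutation model: mutations are a Poisson process at
// rate mu per generation along each branch, each mutation moves the allele
// state +/-1 with probability 1/2, and a move that would leave
// [0, k_max - 1] is either discarded (state unchanged) or reflected.
//
// Time is continuous, in generations; with j lineages in an epoch of
// diploid size N the total coalescence rate is j (j - 1) / (4 N) per
// generation (pairwise rate 1 / (2 N) gene copies). Epoch boundaries bound
// the exponential waiting times. Uses R's RNG, so results are reproducible
// under set.seed().
//
// [[Rcpp::export]]
List sim_bounded_smm_cpp(int n_copies, NumericVector epoch_len,
                         NumericVector epoch_N, double mu, int k_max,
                         int root_state, bool reflect) {
  if (n_copies < 2) stop("n_copies must be >= 2");
  const int n = n_copies, total = 2 * n - 1;
  std::vector<int> parent(total, -1);
  std::vector<double> ntime(total, 0.0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;

  int j = n, next_id = n, ep = 0;
  double t = 0.0, ep_end = epoch_len[0];
  while (j > 1) {
    double N = epoch_N[ep];
    double rate = (double)j * (j - 1) / (4.0 * N);
    double wait = exp_rand() / rate;
    if (t + wait > ep_end) {
      t = ep_end;
      ++ep;
      ep_end += epoch_len[ep];
      continue;
    }
    t += wait;
    int i1 = (int)(unif_rand() * j); if (i1 >= j) i1 = j - 1;
    int a = active[i1];
    active[i1] = active[j - 1];
    --j;
    int i2 = (int)(unif_rand() * j); if (i2 >= j) i2 = j - 1;
    int b = active[i2];
    parent[a] = next_id;
    parent[b] = next_id;
    ntime[next_id] = t;
    active[i2] = next_id;
    ++next_id;
  }

  // Drop states root -> tips; node ids increase with creation time, so every
  // parent has a larger id than its children.
  std::vector<int> state(total);
  state[total - 1] = root_state;
  for (int id = total - 2; id >= 0; --id) {
    double len = ntime[parent[id]] - ntime[id];
    int m = (int)R::rpois(mu * len);
    int s = state[parent[id]];
    for (int k = 0; k < m; ++k) {
      int step = (unif_rand() < 0.5) ? -1 : 1;
      int s2 = s + step;
      if (s2 < 0 || s2 >= k_max) s2 = reflect ? s - step : s;
      s = s2;
    }
    state[id] = s;
  }

  IntegerVector tips(n);
  for (int i = 0; i < n; ++i) tips[i] = state[i];
  return List::create(_["states"] = tips, _["tmrca"] = t);
}
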