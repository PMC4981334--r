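#include <Rcpp.h>
using namespace Rcpp;

// Moran death-Birth process on a regular graph, run to absorption.
//
// adj: N x k matrix of 1-based neighbor indices; a, b: payoff vectors of the
// (k+1)-player game, 0-indexed by the number of A co-players; w: selection
// intensity. Each run starts from a single mutant at a uniformly random
// vertex. Payoffs of the competing neighbors are evaluated on the state
// before the focal death (the dying individual still counts in its
// neighbors' groups). Uses R's RNG, so results are reproducible under
// set.seed(). Fitness positivity (1 - w + w * payoff > 0) is enforced by
// the R wrapper before this is called.
//
// Deaths at a vertex whose neighbors all share its strategy replace it with
// an identical copy and cannot change the state, whatever the fitnesses.
// The sampler therefore draws the dying vertex uniformly from the "active"
// set (vertices with at least one disagreeing neighbor) instead of from all
// vertices: the embedded jump chain over state changes is identical, so
// absorption (fixation) probabilities are unchanged while runs skip the
// no-op updates that dominate large sparse graphs. mean_steps counts these
// effective updates.

// [[Rcpp::export]]
List run_fixation_cpp(IntegerMatrix adj_in, NumericVector a, NumericVector b,
                      double w, int runs, bool mutant_is_A) {
  const int N = adj_in.nrow(), k = adj_in.ncol();
  // flat 0-based adjacency, row-major: nbr[v * k + e]
  std::vector<int> nbr((size_t)N * k);
  for (int v = 0; v < N; ++v)
    for (int e = 0; e < k; ++e) nbr[(size_t)v * k + e] = adj_in(v, e) - 1;

  std::vector<int> state(N), active(N), pos(N, -1);
  std::vector<double> wt(k);
  int n_active = 0;

  // indexed set with swap-remove; is_active(v) <=> pos[v] >= 0
  auto set_active = [&](int v, bool on) {
    if (on && pos[v] < 0) {
      pos[v] = n_active;
      active[n_active++] = v;
    } else if (!on && pos[v] >= 0) {
      int last = active[--n_active];
      active[pos[v]] = last;
      pos[last] = pos[v];
      pos[v] = -1;
    }
  };
  auto recompute_active = [&](int v) {
    bool any = false;
    for (int e = 0; e < k; ++e)
      if (state[nbr[(size_t)v * k + e]] != state[v]) { any = true; break; }
    set_active(v, any);
  };

  double fixed = 0.0, total_steps = 0.0;

  for (int r = 0; r < runs; ++r) {
    const int resident = mutant_is_A ? 0 : 1;
    std::fill(state.begin(), state.end(), resident);
    int m = (int)(unif_rand() * N);
    if (m >= N) m = N - 1;
    state[m] = 1 - resident;
    int countA = mutant_is_A ? 1 : N - 1;

    std::fill(pos.begin(), pos.end(), -1);
    n_active = 0;
    recompute_active(m);
    for (int e = 0; e < k; ++e) recompute_active(nbr[(size_t)m * k + e]);

    while (countA > 0 && countA < N) {
      total_steps += 1.0;
      int idx = (int)(unif_rand() * n_active);
      if (idx >= n_active) idx = n_active - 1;
      const int die = active[idx];
      double tot = 0.0;
      for (int e = 0; e < k; ++e) {
        const int v = nbr[(size_t)die * k + e];
        int j = 0;
        for (int e2 = 0; e2 < k; ++e2) j += state[nbr[(size_t)v * k + e2]];
        const double pay = state[v] ? a[j] : b[j];
        const double f = 1.0 - w + w * pay;
        wt[e] = f;
        tot += f;
      }
      const double u = unif_rand() * tot;
      int chosen = k - 1;
      double cum = 0.0;
      for (int e = 0; e < k; ++e) {
        cum += wt[e];
        if (u < cum) { chosen = e; break; }
      }
      const int s = state[nbr[(size_t)die * k + chosen]];
      if (s != state[die]) {
        countA += s - state[die];
        state[die] = s;
        recompute_active(die);
        for (int e = 0; e < k; ++e) recompute_active(nbr[(size_t)die * k + e]);
      }
    }
    if ((mutant_is_A && countA == N) || (!mutant_is_A && countA == 0))
      fixed += 1.0;
  }
  return List::create(_["fixations"] = fixed,
                      _["mean_steps"] = total_steps / runs);
}
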