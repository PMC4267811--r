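#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Simulated-annealing minimum-set selector over a branch x PU incidence
// matrix.  Score(S) = sum of selected PU costs + beta * sum of weights of
// unmet branches (a branch is unmet while no selected PU contains it).
// The cost cap is a hard constraint: additions that would exceed the cap
// are turned into swap moves.  Each run keeps its best-visited state and
// finishes with a deterministic steepest-descent pass over single
// adds/removes/swaps, so every reported solution is locally optimal.
//
// Uses R's RNG so results are reproducible under set.seed().

namespace {

struct State {
  std::vector<int> selected;     // 0/1 per PU
  std::vector<int> cover;        // per-branch count of selected PUs containing it
  double cost;
  double penalty;                // sum of w over uncovered branches
};

double delta_add(const State &s, int p,
                 const std::vector<std::vector<int> > &pu_br,
                 const std::vector<double> &w, const std::vector<double> &costs,
                 double beta) {
  double dpen = 0.0;
  for (size_t i = 0; i < pu_br[p].size(); ++i) {
    int b = pu_br[p][i];
    if (s.cover[b] == 0) dpen -= w[b];
  }
  return costs[p] + beta * dpen;
}

double delta_remove(const State &s, int p,
                    const std::vector<std::vector<int> > &pu_br,
                    const std::vector<double> &w, const std::vector<double> &costs,
                    double beta) {
  double dpen = 0.0;
  for (size_t i = 0; i < pu_br[p].size(); ++i) {
    int b = pu_br[p][i];
    if (s.cover[b] == 1) dpen += w[b];
  }
  return -costs[p] + beta * dpen;
}

// add p_in, remove p_out (p_in not selected, p_out selected)
double delta_swap(const State &s, int p_in, int p_out,
                  const std::vector<std::vector<int> > &pu_br,
                  const IntegerMatrix &inc,
                  const std::vector<double> &w, const std::vector<double> &costs,
                  double beta) {
  double dpen = 0.0;
  for (size_t i = 0; i < pu_br[p_out].size(); ++i) {
    int b = pu_br[p_out][i];
    if (s.cover[b] == 1 && inc(b, p_in) == 0) dpen += w[b];  // lost
  }
  for (size_t i = 0; i < pu_br[p_in].size(); ++i) {
    int b = pu_br[p_in][i];
    if (s.cover[b] == 0) dpen -= w[b];                        // gained
  }
  return costs[p_in] - costs[p_out] + beta * dpen;
}

void apply_add(State &s, int p, const std::vector<std::vector<int> > &pu_br,
               const std::vector<double> &w, const std::vector<double> &costs) {
  for (size_t i = 0; i < pu_br[p].size(); ++i) {
    int b = pu_br[p][i];
    if (s.cover[b] == 0) s.penalty -= w[b];
    s.cover[b]++;
  }
  s.selected[p] = 1;
  s.cost += costs[p];
}

void apply_remove(State &s, int p, const std::vector<std::vector<int> > &pu_br,
                  const std::vector<double> &w, const std::vector<double> &costs) {
  for (size_t i = 0; i < pu_br[p].size(); ++i) {
    int b = pu_br[p][i];
    s.cover[b]--;
    if (s.cover[b] == 0) s.penalty += w[b];
  }
  s.selected[p] = 0;
  s.cost -= costs[p];
}

double score_of(const State &s, double beta) {
  return s.cost + beta * s.penalty;
}

// steepest-descent over single adds, removes and swaps until no move improves
void hill_climb(State &s, const std::vector<std::vector<int> > &pu_br,
                const IntegerMatrix &inc, const std::vector<double> &w,
                const std::vector<double> &costs, double beta, double cap) {
  int n = (int)s.selected.size();
  bool improved = true;
  while (improved) {
    improved = false;
    double best_delta = -1e-12;
    int best_kind = -1, best_p = -1, best_q = -1;
    for (int p = 0; p < n; ++p) {
      if (s.selected[p]) {
        double d = delta_remove(s, p, pu_br, w, costs, beta);
        if (d < best_delta) { best_delta = d; best_kind = 1; best_p = p; }
      } else {
        if (s.cost + costs[p] <= cap + 1e-12) {
          double d = delta_add(s, p, pu_br, w, costs, beta);
          if (d < best_delta) { best_delta = d; best_kind = 0; best_p = p; }
        }
        for (int q = 0; q < n; ++q) {
          if (!s.selected[q]) continue;
          if (s.cost + costs[p] - costs[q] > cap + 1e-12) continue;
          double d = delta_swap(s, p, q, pu_br, inc, w, costs, beta);
          if (d < best_delta) { best_delta = d; best_kind = 2; best_p = p; best_q = q; }
        }
      }
    }
    if (best_kind == 0) { apply_add(s, best_p, pu_br, w, costs); improved = true; }
    else if (best_kind == 1) { apply_remove(s, best_p, pu_br, w, costs); improved = true; }
    else if (best_kind == 2) {
      apply_remove(s, best_q, pu_br, w, costs);
      apply_add(s, best_p, pu_br, w, costs);
      improved = true;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List anneal_runs_cpp(IntegerMatrix inc, NumericVector weights,
                     NumericVector costs, double cap, int iterations,
                     int n_runs, double beta, double t_init, double t_final_frac) {
  int nb = inc.nrow(), n = inc.ncol();
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<double> cs(costs.begin(), costs.end());
  std::vector<std::vector<int> > pu_br(n);
  for (int p = 0; p < n; ++p)
    for (int b = 0; b < nb; ++b)
      if (inc(b, p) != 0) pu_br[p].push_back(b);
  double base_penalty = 0.0;
  for (int b = 0; b < nb; ++b) base_penalty += w[b];

  IntegerMatrix sel_out(n_runs, n);
  NumericVector score_out(n_runs), cost_out(n_runs), pen_out(n_runs);

  for (int run = 0; run < n_runs; ++run) {
    State s;
    s.selected.assign(n, 0);
    s.cover.assign(nb, 0);
    s.cost = 0.0;
    s.penalty = base_penalty;

    // adaptive initial temperature: spread of sampled random-move deltas
    double T0 = t_init;
    if (T0 <= 0.0) {
      std::vector<double> deltas;
      State probe = s;
      for (int i = 0; i < 100; ++i) {
        int p = (int)std::floor(unif_rand() * n);
        if (p >= n) p = n - 1;
        double d;
        if (probe.selected[p]) {
          d = delta_remove(probe, p, pu_br, w, cs, beta);
          apply_remove(probe, p, pu_br, w, cs);
        } else if (probe.cost + cs[p] <= cap + 1e-12) {
          d = delta_add(probe, p, pu_br, w, cs, beta);
          apply_add(probe, p, pu_br, w, cs);
        } else {
          continue;
        }
        deltas.push_back(std::fabs(d));
      }
      double m = 0.0, v = 0.0;
      for (size_t i = 0; i < deltas.size(); ++i) m += deltas[i];
      if (!deltas.empty()) m /= deltas.size();
      for (size_t i = 0; i < deltas.size(); ++i)
        v += (deltas[i] - m) * (deltas[i] - m);
      if (deltas.size() > 1) v /= (deltas.size() - 1);
      T0 = std::sqrt(v);
      if (T0 <= 0.0) T0 = (m > 0.0 ? m : 1.0);
    }
    double cool = std::pow(t_final_frac, 1.0 / std::max(1, iterations));
    double T = T0;

    State best = s;
    double best_score = score_of(s, beta);

    for (int it = 0; it < iterations; ++it) {
      int p = (int)std::floor(unif_rand() * n);
      if (p >= n) p = n - 1;
      if (s.selected[p]) {
        double d = delta_remove(s, p, pu_br, w, cs, beta);
        if (d <= 0.0 || unif_rand() < std::exp(-d / T))
          apply_remove(s, p, pu_br, w, cs);
      } else if (s.cost + cs[p] <= cap + 1e-12) {
        double d = delta_add(s, p, pu_br, w, cs, beta);
        if (d <= 0.0 || unif_rand() < std::exp(-d / T))
          apply_add(s, p, pu_br, w, cs);
      } else {
        // cap would be exceeded: swap with a random selected PU
        int nsel = 0;
        for (int q = 0; q < n; ++q) nsel += s.selected[q];
        if (nsel == 0) { T *= cool; continue; }
        int pick = (int)std::floor(unif_rand() * nsel);
        int q = -1, cnt = 0;
        for (int j = 0; j < n; ++j) {
          if (s.selected[j]) {
            if (cnt == pick) { q = j; break; }
            cnt++;
          }
        }
        if (s.cost + cs[p] - cs[q] <= cap + 1e-12) {
          double d = delta_swap(s, p, q, pu_br, inc, w, cs, beta);
          if (d <= 0.0 || unif_rand() < std::exp(-d / T)) {
            apply_remove(s, q, pu_br, w, cs);
            apply_add(s, p, pu_br, w, cs);
          }
        }
      }
      double sc = score_of(s, beta);
      if (sc < best_score - 1e-12) { best_score = sc; best = s; }
      T *= cool;
    }

    hill_climb(best, pu_br, inc, w, cs, beta, cap);

    for (int p = 0; p < n; ++p) sel_out(run, p) = best.selected[p];
    score_out[run] = score_of(best, beta);
    cost_out[run] = best.cost;
    pen_out[run] = best.penalty;
  }

  return List::create(_["selected"] = sel_out, _["score"] = score_out,
                      _["cost"] = cost_out, _["penalty"] = pen_out);
}
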