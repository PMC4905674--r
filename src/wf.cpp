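#include <Rcpp.h>
using namespace Rcpp;

// Wright-Fisher resampling of a new ERV allele starting at one copy among
// `slots` chromosome slots, with LTR mutations arising on carrier copies as
// a Poisson process at rate `mu_copy` per copy per generation.
//
// mode 0: trajectory only (absorption outcome and time)
// mode 1: additionally record the first class-wide mutation event; the run
//         stops at that event (used for first-difference statistics)
// mode 2: record the first event but run on to absorption
//
// outcome codes: 0 = lost, 1 = fixed, 2 = still segregating at max_gen,
//                3 = stopped at first mutation while segregating (mode 1)
// [[Rcpp::export]]
DataFrame wf_sim_cpp(int nrep, int slots, double mu_copy, int max_gen,
                     int mode) {
  IntegerVector outcome(nrep), t_abs(nrep), first_gen(nrep),
      first_count(nrep);
  for (int r = 0; r < nrep; ++r) {
    double x = 1.0;
    int gen = 0, fgen = -1, fcount = -1, out = 2;
    while (gen < max_gen) {
      ++gen;
      x = R::rbinom(slots, x / slots);
      if (x <= 0.0) { out = 0; break; }
      if (x >= slots) {
        if (mode >= 1 && fgen < 0) { out = 1; break; }
        out = 1; break;
      }
      if (mode >= 1 && fgen < 0) {
        // at least one mutation among x carrier copies this generation
        if (unif_rand() < -expm1(-mu_copy * x)) {
          fgen = gen;
          fcount = (int)x;
          if (mode == 1) { out = 3; break; }
        }
      }
    }
    if (out == 1 || out == 0) t_abs[r] = gen; else t_abs[r] = gen;
    outcome[r] = out;
    first_gen[r] = fgen;
    first_count[r] = fcount;
  }
  return DataFrame::create(_["outcome"] = outcome, _["t_abs"] = t_abs,
                           _["first_gen"] = first_gen,
                           _["first_count"] = first_count);
}

// Single-run trajectory recorder: per-generation copy counts and mutation
// event log (generation, carrier copies at the event).
// [[Rcpp::export]]
List wf_trajectory_cpp(int slots, double mu_copy, int max_gen) {
  std::vector<int> traj;
  std::vector<int> ev_gen, ev_count;
  double x = 1.0;
  int gen = 0, out = 2;
  traj.push_back(1);
  while (gen < max_gen) {
    ++gen;
    x = R::rbinom(slots, x / slots);
    traj.push_back((int)x);
    if (x <= 0.0) { out = 0; break; }
    int k = (int)R::rpois(mu_copy * x);
    for (int j = 0; j < k; ++j) { ev_gen.push_back(gen); ev_count.push_back((int)x); }
    if (x >= slots) { out = 1; break; }
  }
  return List::create(_["outcome"] = out, _["t_abs"] = gen,
                      _["copies"] = wrap(traj),
                      _["event_gen"] = wrap(ev_gen),
                      _["event_copies"] = wrap(ev_count));
}
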