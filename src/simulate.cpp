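#include <Rcpp.h>
using namespace Rcpp;

// Exact continuous-time jump simulation of an aggregated Markov model,
// merged to class-level dwells: within-class jumps are invisible in the
// observable open/closed record, so consecutive sojourns in states of the
// same class are summed into one dwell.  Uses R's RNG so results are
// reproducible under set.seed().

// [[Rcpp::export]]
List sim_dwells_cpp(NumericMatrix Q, LogicalVector is_open, int start_state,
                    int n_events) {
  const int n = Q.nrow();
  std::vector<double> exit_rate(n);
  std::vector<std::vector<double>> cumprob(n);
  std::vector<std::vector<int>> target(n);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != i && Q(i, j) > 0.0) tot += Q(i, j);
    if (tot <= 0.0) stop("absorbing state reached in simulation setup");
    exit_rate[i] = tot;
    double acc = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != i && Q(i, j) > 0.0) {
        acc += Q(i, j) / tot;
        cumprob[i].push_back(acc);
        target[i].push_back(j);
      }
    cumprob[i].back() = 1.0;  // guard rounding
  }

  IntegerVector cls(n_events);
  NumericVector dur(n_events);
  int state = start_state - 1;
  bool cur_open = is_open[state];
  double cur_dwell = 0.0;
  int k = 0;
  RNGScope scope;
  while (k < n_events) {
    cur_dwell += R::rexp(1.0 / exit_rate[state]);
    double u = R::unif_rand();
    int idx = std::lower_bound(cumprob[state].begin(), cumprob[state].end(), u) -
              cumprob[state].begin();
    int next = target[state][idx];
    if (is_open[next] != cur_open) {
      cls[k] = cur_open ? 1 : 0;
      dur[k] = cur_dwell;
      ++k;
      cur_open = is_open[next];
      cur_dwell = 0.0;
    }
    state = next;
  }
  return List::create(_["open"] = cls, _["duration"] = dur);
}
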