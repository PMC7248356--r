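#include <Rcpp.h>
using namespace Rcpp;

// Event-driven simulation of the G-network continuous-time Markov chain.
// Competing exponential clocks: external excitatory/inhibitory Poisson
// arrivals per neuron and firing of every neuron with positive potential.
// A firing neuron decrements its own potential and routes the impulse with
// the transition probabilities: +1 to a target, -1 to a target (floored at
// zero), or departure. Uses R's RNG so runs are reproducible via set.seed().
//
// hist_cap >= 0 additionally accumulates time-weighted occupancy of the
// joint state with per-neuron potentials clipped at hist_cap.
// [[Rcpp::export(name = ".simulate_gnet_cpp")]]
List simulate_gnet_cpp(NumericMatrix p_plus, NumericMatrix p_minus,
                       NumericVector d, NumericVector r,
                       NumericVector Lambda, NumericVector lambda_minus,
                       double n_events, int hist_cap) {
  const int n = r.size();
  std::vector<double> k(n, 0.0);        // potentials (integer-valued)
  std::vector<double> active_time(n, 0.0);
  std::vector<double> touched(n, 0.0);  // events addressing each neuron
  double total_time = 0.0;

  double ext_rate = 0.0;
  for (int i = 0; i < n; ++i) ext_rate += Lambda[i] + lambda_minus[i];

  std::vector<double> hist;
  long hist_size = 0;
  if (hist_cap >= 0) {
    double sz = 1.0;
    for (int i = 0; i < n; ++i) sz *= (hist_cap + 1);
    if (sz > 5e7) stop("joint histogram too large; lower hist_cap or n");
    hist_size = (long)sz;
    hist.assign(hist_size, 0.0);
  }

  RNGScope scope;
  double events_done = 0.0;
  while (events_done < n_events) {
    double fire_rate = 0.0;
    for (int i = 0; i < n; ++i) if (k[i] > 0) fire_rate += r[i];
    double total = ext_rate + fire_rate;
    if (total <= 0.0) break;   // absorbing state: nothing can ever happen

    double dt = R::rexp(1.0 / total);
    total_time += dt;
    for (int i = 0; i < n; ++i) if (k[i] > 0) active_time[i] += dt;
    if (hist_cap >= 0) {
      long idx = 0, mult = 1;
      for (int i = 0; i < n; ++i) {
        int ki = (int)std::min(k[i], (double)hist_cap);
        idx += ki * mult;
        mult *= (hist_cap + 1);
      }
      hist[idx] += dt;
    }

    double u = R::runif(0.0, total);
    bool done = false;
    for (int i = 0; i < n && !done; ++i) {       // external arrivals
      if (u < Lambda[i]) { k[i] += 1.0; touched[i] += 1.0; done = true; break; }
      u -= Lambda[i];
      if (u < lambda_minus[i]) {
        if (k[i] > 0) k[i] -= 1.0;               // floor at zero
        touched[i] += 1.0;
        done = true; break;
      }
      u -= lambda_minus[i];
    }
    if (!done) {                                  // a neuron fires
      int src = -1;
      for (int i = 0; i < n; ++i) {
        if (k[i] > 0) {
          if (u < r[i]) { src = i; break; }
          u -= r[i];
        }
      }
      if (src < 0) src = n - 1;                   // numerical guard
      k[src] -= 1.0;
      touched[src] += 1.0;
      double v = R::unif_rand();
      int tgt = -1; bool excit = true;
      for (int j = 0; j < n; ++j) {
        if (v < p_plus(src, j)) { tgt = j; excit = true; break; }
        v -= p_plus(src, j);
      }
      if (tgt < 0) {
        for (int j = 0; j < n; ++j) {
          if (v < p_minus(src, j)) { tgt = j; excit = false; break; }
          v -= p_minus(src, j);
        }
      }
      if (tgt >= 0) {
        if (excit) k[tgt] += 1.0;
        else if (k[tgt] > 0) k[tgt] -= 1.0;
        touched[tgt] += 1.0;
      }                                           // else: departure
    }
    events_done += 1.0;
  }

  NumericVector activation(n);
  for (int i = 0; i < n; ++i)
    activation[i] = total_time > 0 ? active_time[i] / total_time : 0.0;

  List out = List::create(
    _["activation"] = activation,
    _["total_time"] = total_time,
    _["n_events"] = events_done,
    _["n_touched"] = NumericVector(touched.begin(), touched.end()));
  if (hist_cap >= 0) {
    NumericVector h(hist.begin(), hist.end());
    out["state_hist"] = h;
  }
  return out;
}
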