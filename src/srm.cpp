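#include <Rcpp.h>
using namespace Rcpp;

// Sequential simulation of one escape-noise neuron on the time grid.
// `drive` holds u_rest + summed synaptic PSPs per step; the reset kernel
// state is folded in sequentially because each emitted spike feeds back
// onto the potential at later steps. A spike at step t contributes
// -kappa_amp * exp(-(t' - t) * dt / tau_m) at steps t' > t.
// [[Rcpp::export]]
List srm_simulate_cpp(NumericVector drive, double rho0, double theta,
                      double delta_u, double dt, double kappa_amp,
                      double tau_m, NumericVector unif) {
  int n = drive.size();
  NumericVector u(n), p(n);
  std::vector<int> spike_steps;
  double reset = 0.0;
  const double decay = std::exp(-dt / tau_m);
  for (int t = 0; t < n; ++t) {
    if (t > 0) reset *= decay;
    u[t] = drive[t] + reset;
    double pt = rho0 * std::exp((u[t] - theta) / delta_u) * dt;
    if (pt > 1.0) pt = 1.0;
    p[t] = pt;
    if (unif[t] < pt) {
      spike_steps.push_back(t + 1);  // 1-based grid index
      reset -= kappa_amp;
    }
  }
  return List::create(_["u"] = u, _["p"] = p,
                      _["spike_steps"] = wrap(spike_steps));
}
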