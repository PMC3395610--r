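#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire with dynamic threshold (LIFDT), Euler-Maruyama
// integration on the stimulus grid.  The drive is the half-wave rectified
// stimulus (Heaviside gate) times the input gain; intrinsic noise enters as
// sqrt(2 D dt) * N(0,1) per step.  A spike is emitted when v >= theta; the
// voltage resets to zero and the threshold jumps by dtheta, relaxing back
// to its baseline with its own time constant.  Uses R's RNG (norm_rand) so
// results are reproducible via set.seed() from R.
//
// Time unit throughout is milliseconds.
// [[Rcpp::export]]
List lifdt_core(NumericVector stim, double dt, double tau_v, double tau_th,
                double dtheta, double theta0, double gain, double D,
                bool return_traces) {
  const int n = stim.size();
  const double noise_amp = std::sqrt(2.0 * D * dt);
  double v = 0.0, theta = theta0;
  std::vector<int> spikes;
  NumericVector vtr, thtr;
  if (return_traces) { vtr = NumericVector(n); thtr = NumericVector(n); }

  GetRNGstate();
  for (int k = 0; k < n; ++k) {
    double s = stim[k];
    double drive = (s > 0.0) ? gain * s : 0.0;
    double eta = (D > 0.0) ? noise_amp * norm_rand() : 0.0;
    v += dt * (-v + drive) / tau_v + eta;
    theta += dt * (theta0 - theta) / tau_th;
    if (v >= theta) {
      spikes.push_back(k);
      v = 0.0;
      theta += dtheta;
    }
    if (return_traces) { vtr[k] = v; thtr[k] = theta; }
  }
  PutRNGstate();

  IntegerVector sp(spikes.begin(), spikes.end());
  if (return_traces)
    return List::create(_["spike_index"] = sp, _["v"] = vtr,
                        _["theta"] = thtr);
  return List::create(_["spike_index"] = sp);
}
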