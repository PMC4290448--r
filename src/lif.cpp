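#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler leaky integrate-and-fire simulation of one song rendition.
//
// Units: ms, mV, pA, GOhm (so R * I is in mV).  Synaptic events arrive as
// pre-computed step indices (times floored onto the dt grid) with their
// current increments in pA.  The NMDA increment is scaled at arrival by the
// magnesium-block gating factor G(V) evaluated with the membrane potential
// at the start of that step, i.e. before the step's Euler update and
// threshold processing.  Threshold crossings are detected after the Euler
// update; V then resets and stays clamped at v_r for t_ref ms while the
// synaptic currents keep evolving.
//
// An optional spike-triggered adaptation current (increment w_adapt pA,
// decay tau_adapt ms, subtracted from the drive) supports adapting-neuron
// fixtures; w_adapt = 0 disables it.
//
// [[Rcpp::export]]
List lif_simulate_cpp(int n_steps, double dt,
                      double tau_m, double v_r, double v_th,
                      double r_gohm, double t_ref,
                      double tau_s, double tau_nmda,
                      double v_inh, double i_inj,
                      IntegerVector hvc_steps, NumericVector hvc_amps,
                      IntegerVector lman_steps,
                      double amp_ampa, double amp_nmda,
                      double mg, double mg_scale, double mg_slope,
                      double w_adapt, double tau_adapt,
                      bool gate_continuous, bool return_v) {
  if (dt <= 0) stop("dt must be positive");
  double v = v_r, i_hvc = 0.0, i_ampa = 0.0, i_nmda = 0.0, i_ad = 0.0;
  double refr = 0.0;
  const double dec_s = 1.0 - dt / tau_s;
  const double dec_n = 1.0 - dt / tau_nmda;
  const double dec_a = tau_adapt > 0 ? 1.0 - dt / tau_adapt : 0.0;
  std::vector<double> spikes;
  NumericVector vtrace;
  if (return_v) vtrace = NumericVector(n_steps + 1);
  if (return_v) vtrace[0] = v;
  int ih = 0, il = 0;
  const int nh = hvc_steps.size(), nl = lman_steps.size();

  for (int n = 0; n < n_steps; ++n) {
    // synaptic increments for events on this step, gated by pre-update V
    while (ih < nh && hvc_steps[ih] == n) i_hvc += hvc_amps[ih++];
    while (il < nl && lman_steps[il] == n) {
      i_ampa += amp_ampa;
      if (amp_nmda != 0.0) {
        if (gate_continuous) i_nmda += amp_nmda;
        else {
          double g =
            1.0 / (1.0 + (mg / mg_scale) * std::exp(-v / mg_slope));
          i_nmda += amp_nmda * g;
        }
      }
      ++il;
    }

    double i_nmda_eff = i_nmda;
    if (gate_continuous && i_nmda != 0.0)
      i_nmda_eff *=
        1.0 / (1.0 + (mg / mg_scale) * std::exp(-v / mg_slope));
    double drive = r_gohm * (i_hvc + i_ampa + i_nmda_eff + i_inj - i_ad);
    if (refr > 0.0) {
      refr -= dt;
      v = v_r;  // clamped; currents still evolve below
    } else {
      v += dt / tau_m * ((v_r - v) + drive - v_inh);
      if (v >= v_th) {
        spikes.push_back((n + 1) * dt);
        v = v_r;
        refr = t_ref;
        i_ad += w_adapt;
      }
    }
    i_hvc *= dec_s;
    i_ampa *= dec_s;
    i_nmda *= dec_n;
    i_ad *= dec_a;
    if (return_v) vtrace[n + 1] = v;
  }
  List out = List::create(_["spike_times"] = wrap(spikes));
  if (return_v) out["v"] = vtrace;
  return out;
}
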