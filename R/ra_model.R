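#' Biophysical parameters of the RA model neuron
#'
#' Collects all constants of the leaky integrate-and-fire RA projection
#' neuron and its synapses.  Defaults are the standard-model values; the
#' membrane time constant is the gain knob (swept 16-25 ms, i.e. +/-20%
#' F-I slope around 20 ms).
#'
#' @param tau_m membrane time constant (ms, default 20).
#' @param v_r resting/reset potential (mV, default -70).
#' @param v_th spike threshold (mV, default -50).
#' @param r_in input resistance (MOhm, default 260).
#' @param t_ref absolute refractory period (ms, default 1.5).
#' @param tau_s fast (AMPA-type) synaptic time constant (ms, default 5),
#'   shared by HVC synapses and the LMAN AMPA component.
#' @param tau_nmda NMDA synaptic time constant (ms, default 100).
#' @param w_lman peak EPSC of the LMAN input (pA, default 120).
#' @param r_ampa AMPA fraction of the LMAN input, in \[0, 1\]
#'   (default 0.1, i.e. 90% NMDA).
#' @param mg extracellular magnesium concentration (mM, default 0.5).
#' @param mg_scale,mg_slope magnesium-block constants (3.57 mM, 16.13 mV).
#' @param r_inh inhibitory proportionality constant (MOhm, default 800);
#'   its large value reflects that the tonic inhibition balances the
#'   pooled drive of 100 excitatory HVC inputs.
#' @param dt forward-Euler integration step (ms, default 0.2).
#' @param n_hvc number of HVC neurons (default 100).
#' @param song_dur song duration (ms, default 1000).
#' @param e_rev excitatory reversal potential (mV, default 0); used by the
#'   receptor-ratio arithmetic, not by the current-based synapse model.
#' @param nmda_mode how the magnesium block gates the NMDA current:
#'   `"arrival"` (default) scales each synaptic increment once, by `G(V)`
#'   at the presynaptic spike's arrival step; `"continuous"` accumulates
#'   ungated increments and multiplies the stored current by `G(V(t))` at
#'   every step.  The arrival form is the literal reading of a
#'   delta-driven synaptic equation; the continuous form is the common
#'   biophysical alternative.  Both give closely similar network behavior
#'   here.
#' @return An object of class `ra_params` (named list).
#' @export
ra_params <- function(tau_m = 20, v_r = -70, v_th = -50, r_in = 260,
                      t_ref = 1.5, tau_s = 5, tau_nmda = 100,
                      w_lman = 120, r_ampa = 0.1, mg = 0.5,
                      mg_scale = 3.57, mg_slope = 16.13, r_inh = 800,
                      dt = 0.2, n_hvc = 100L, song_dur = 1000,
                      e_rev = 0,
                      nmda_mode = c("arrival", "continuous")) {
  p <- list(tau_m = tau_m, v_r = v_r, v_th = v_th, r_in = r_in,
            t_ref = t_ref, tau_s = tau_s, tau_nmda = tau_nmda,
            w_lman = w_lman, r_ampa = r_ampa, mg = mg,
            mg_scale = mg_scale, mg_slope = mg_slope, r_inh = r_inh,
            dt = dt, n_hvc = as.integer(n_hvc), song_dur = song_dur,
            e_rev = e_rev, nmda_mode = match.arg(nmda_mode))
  stopifnot(p$tau_m > 0, p$tau_s > 0, p$tau_nmda > 0, p$t_ref > 0,
            p$dt > 0, p$v_th > p$v_r, p$r_ampa >= 0, p$r_ampa <= 1)
  if (p$dt >= min(p$tau_s, p$t_ref))
    stop("dt must be smaller than min(tau_s, t_ref)", call. = FALSE)
  structure(p, class = "ra_params")
}

#' @export
print.ra_params <- function(x, ...) {
  cat(sprintf(paste0("RA model parameters: tau_m %g ms, R %g MOhm, ",
                     "V_R %g mV, V_th %g mV, W_LMAN %g pA (AMPA ",
                     "fraction %g), dt %g ms\n"),
              x$tau_m, x$r_in, x$v_r, x$v_th, x$w_lman, x$r_ampa,
              x$dt))
  invisible(x)
}

#' Voltage-dependent magnesium-block gating of the NMDA current
#'
#' `G(V) = 1 / (1 + (Mg / 3.57 mM) * exp(-V / 16.13 mV))`, strictly
#' increasing in `V` and approaching 1 at depolarized potentials.
#'
#' @param v membrane potential(s), mV.
#' @param params an [ra_params()] object (supplies `mg`, `mg_scale`,
#'   `mg_slope`).
#' @return gating factor(s) in (0, 1\].
#' @export
nmda_gating <- function(v, params = ra_params()) {
  1 / (1 + (params$mg / params$mg_scale) * exp(-v / params$mg_slope))
}

#' Tonic inhibition proportional to the HVC drive
#'
#' `V_INH = R_INH * m * rho` with `R_INH` in GOhm internally, so that the
#' result is in mV.  `m` is the mean of the active-weight *distribution*
#' (not the realized sample mean), so the inhibition is constant within a
#' rendition and across realizations at the same grid point.
#'
#' @param m mean active HVC->RA weight (pA), > 0.
#' @param rho fraction of active HVC inputs, in (0, 1\].
#' @param params an [ra_params()] object (supplies `r_inh`).
#' @return tonic inhibition (mV).
#' @export
tonic_inhibition <- function(m, rho, params = ra_params()) {
  stopifnot(m > 0, rho > 0, rho <= 1)
  (params$r_inh / 1000) * m * rho
}

# flatten HVC trains + weights into event (step, amplitude) arrays on the
# dt grid; trains with zero weight contribute nothing
hvc_events <- function(profile, hvc, params) {
  w <- profile$weights
  if (length(w) != length(hvc))
    stop("profile and HVC raster disagree on n_hvc", call. = FALSE)
  act <- which(w > 0)
  times <- unlist(lapply(act, function(i) hvc[[i]]$times))
  amps <- rep(w[act], times = vapply(hvc[act], function(tr)
    length(tr$times), integer(1)))
  ord <- order(times)
  list(steps = as.integer(floor(times[ord] / params$dt)),
       amps = amps[ord])
}

#' Simulate one song rendition of the RA model neuron
#'
#' Forward-Euler integration of the leaky integrate-and-fire membrane
#' equation
#' `tau_m dV/dt = (V_R - V) + R I_HVC + R I_LMAN - V_INH`,
#' where `I_HVC` decays with `tau_s` and jumps by the synaptic weight
#' `W_i` on each spike of HVC neuron *i*; the LMAN AMPA current jumps by
#' `r_ampa * W_LMAN` (decay `tau_s`); the LMAN NMDA current jumps by
#' `(1 - r_ampa) * W_LMAN * G(V)` with the magnesium gating evaluated at
#' the presynaptic spike's arrival step using the pre-update membrane
#' potential (decay `tau_nmda`).  Crossing `V_th` (detected after the
#' Euler update) emits a spike, resets `V` to `V_R` and clamps it there
#' for `t_ref` ms while the synaptic currents continue to evolve.  Event
#' times are snapped to the integration grid by flooring.
#'
#' @param profile a `connectivity_profile` from [sample_weights()].
#' @param hvc list of HVC `spike_train`s from [hvc_song()].
#' @param lman an LMAN `spike_train` (or `NULL` for a silenced LMAN).
#' @param params an [ra_params()] object.
#' @param v_inh tonic inhibition (mV); default recomputed from the
#'   profile's `(m, rho)` via [tonic_inhibition()].
#' @param i_inj constant injected current (pA, default 0); bypasses the
#'   synapses, e.g. for current-step protocols.
#' @param return_v also return the membrane-potential trace.
#' @return A `spike_train` of RA spike times (source `"RA"`); if
#'   `return_v`, attribute `"v"` holds the voltage at each grid point
#'   (length `n_steps + 1`).
#' @export
simulate_rendition <- function(profile, hvc, lman, params = ra_params(),
                               v_inh = NULL, i_inj = 0,
                               return_v = FALSE) {
  dur <- params$song_dur
  if (!is.null(lman) && !isTRUE(all.equal(lman$duration, dur)))
    stop("LMAN train duration does not match song_dur", call. = FALSE)
  if (length(hvc) && !isTRUE(all.equal(hvc[[1]]$duration, dur)))
    stop("HVC raster duration does not match song_dur", call. = FALSE)
  if (is.null(v_inh))
    v_inh <- if (is.null(profile)) 0 else
      tonic_inhibition(profile$m, profile$rho, params)
  ev <- if (is.null(profile) || length(hvc) == 0L)
    list(steps = integer(0), amps = numeric(0))
  else hvc_events(profile, hvc, params)
  lsteps <- if (is.null(lman)) integer(0) else
    as.integer(floor(lman$times / params$dt))
  n_steps <- as.integer(round(dur / params$dt))
  res <- lif_simulate_cpp(
    n_steps, params$dt, params$tau_m, params$v_r, params$v_th,
    params$r_in / 1000, params$t_ref, params$tau_s, params$tau_nmda,
    v_inh, i_inj, ev$steps, ev$amps, lsteps,
    params$r_ampa * params$w_lman, (1 - params$r_ampa) * params$w_lman,
    params$mg, params$mg_scale, params$mg_slope,
    0, 0, identical(params$nmda_mode, "continuous"), return_v)
  out <- spike_train(res$spike_times, dur, source = "RA")
  if (return_v) attr(out, "v") <- res$v
  out
}
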