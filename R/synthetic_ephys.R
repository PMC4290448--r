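#' Reference synaptic summary statistics by age group
#'
#' Group-level summary statistics of HVC->RA and LMAN->RA synaptic
#' measurements in zebra finch RA slice recordings across the three
#' song-learning stages (subsong ~40-45 dph, plastic song ~60-65 dph,
#' crystallized adult ~90-130 dph).  These numbers parameterize the
#' synthetic population generator and the receptor-ratio arithmetic:
#' mean SF amplitude and mean MAX current per group for the HVC pathway,
#' the -70/+40 mV SF amplitude ratio for the LMAN pathway, and the
#' mean-SF-method input-count truth used by [gen_population()].
#'
#' @return data.frame with columns `age_group`, `sf_mean_pa`,
#'   `max_mean_na`, `ratio_m70_p40`, `n_inputs`.
#' @export
synaptic_summary <- function() {
  data.frame(
    age_group = c("subsong", "plastic", "adult"),
    sf_mean_pa = c(29.52, 49.60, 73.56),   # HVC pathway
    max_mean_na = c(0.55, 1.31, 0.80),     # HVC pathway
    ratio_m70_p40 = c(0.17, 0.10, 0.11),   # LMAN pathway
    n_inputs = c(19L, 26L, 11L))
}

#' Fiber-level ground truth for a synthetic minimal-stimulation experiment
#'
#' Describes the afferent fibers recruited by a stimulating electrode:
#' each fiber has a recruitment threshold, a peak EPSC weight, a release
#' probability *at* its threshold intensity (transmission becomes reliable
#' above it), and a shared EPSC waveform (difference of exponentials).
#'
#' @param thresholds recruitment thresholds (uA), strictly ascending.
#' @param weights peak EPSC amplitudes (pA), > 0, one per fiber.
#' @param p_release success probability at the threshold intensity.
#' @param stoch_span fibers remain stochastic for intensities up to
#'   `threshold * stoch_span` (default 1.2) and reliable beyond.
#' @param rise_ms,decay_ms EPSC waveform time constants (default 1, 5).
#' @param latency_ms mean synaptic onset latency (ms, default 5).
#' @param latency_jitter_ms SD of the per-trial latency jitter (ms).
#' @return An object of class `fiber_truth`.
#' @export
fiber_truth <- function(thresholds, weights, p_release = 0.5,
                        stoch_span = 1.2, rise_ms = 1, decay_ms = 5,
                        latency_ms = 5, latency_jitter_ms = 1) {
  stopifnot(length(thresholds) == length(weights),
            all(thresholds > 0), all(weights > 0),
            !is.unsorted(thresholds), p_release > 0, p_release <= 1,
            decay_ms > rise_ms)
  structure(list(thresholds = thresholds, weights = weights,
                 p_release = p_release, stoch_span = stoch_span,
                 rise_ms = rise_ms, decay_ms = decay_ms,
                 latency_ms = latency_ms,
                 latency_jitter_ms = latency_jitter_ms),
            class = "fiber_truth")
}

# unit-peak difference-of-exponentials EPSC waveform sampled at dt
epsc_waveform <- function(t_ms, rise_ms, decay_ms) {
  tpk <- log(decay_ms / rise_ms) * rise_ms * decay_ms /
    (decay_ms - rise_ms)
  peak <- exp(-tpk / decay_ms) - exp(-tpk / rise_ms)
  ifelse(t_ms < 0, 0,
         (exp(-t_ms / decay_ms) - exp(-t_ms / rise_ms)) / peak)
}

#' Synthetic evoked-EPSC intensity series
#'
#' Emulates a minimal-stimulation experiment: at each stimulation
#' intensity, every fiber whose threshold is at or below the intensity
#' contributes its EPSC (linear summation), with Bernoulli failures while
#' the intensity is still within the fiber's stochastic span; Gaussian
#' baseline noise (2-5 pA RMS regime) is added throughout.
#'
#' @param truth a [fiber_truth()].
#' @param intensities ascending stimulation intensities (uA).
#' @param n_trials trials per intensity (default 10).
#' @param noise_rms baseline noise RMS (pA, default 3).
#' @param dt_ms sampling interval (ms, default 0.01 = 100 kHz).
#' @param pre_ms,post_ms baseline and post-stimulus record spans (ms).
#' @param seed optional integer seed.
#' @return list of `list(intensity, traces)` as ingested by
#'   [detect_sf()] / [detect_max()], with the generating `truth` attached
#'   as an attribute.
#' @export
gen_epsc_series <- function(truth, intensities, n_trials = 10L,
                            noise_rms = 3, dt_ms = 0.01, pre_ms = 50,
                            post_ms = 30, seed = NULL) {
  stopifnot(inherits(truth, "fiber_truth"), !is.unsorted(intensities))
  n_samp <- round((pre_ms + post_ms) / dt_ms)
  t_abs <- seq_len(n_samp) * dt_ms
  out <- with_opt_seed(seed, lapply(intensities, function(I) {
    traces <- lapply(seq_len(n_trials), function(trial) {
      x <- rnorm(n_samp, 0, noise_rms)
      # latency jitter is trial-level (stimulus/conduction), shared by
      # all recruited fibers, so evoked peaks sum linearly by
      # construction
      onset <- pre_ms + truth$latency_ms +
        rnorm(1, 0, truth$latency_jitter_ms)
      for (f in seq_along(truth$thresholds)) {
        thr <- truth$thresholds[f]
        if (I < thr) next
        p <- if (I <= thr * truth$stoch_span) truth$p_release else 1
        if (runif(1) > p) next
        x <- x + truth$weights[f] *
          epsc_waveform(t_abs - onset, truth$rise_ms, truth$decay_ms)
      }
      evoked_trace(x, dt_ms, stim_time = pre_ms, stim_intensity = I)
    })
    list(intensity = I, traces = traces)
  }))
  attr(out, "truth") <- truth
  out
}

#' Synthetic cell population for input-count estimator recovery
#'
#' Generates per-cell summary records with known ground truth: each cell
#' receives a fixed, known number of inputs with weights drawn from the
#' age group's log-normal SF distribution; its MAX current is the linear
#' sum of the weights with multiplicative measurement noise, and its
#' observed SFs are a random subset (up to 3) of its true weights.
#'
#' @param age_group `"subsong"`, `"plastic"` or `"adult"`; sets the SF
#'   mean and the true input count from [synaptic_summary()].
#' @param n_cells number of cells (default 50).
#' @param n_inputs true inputs per cell; default the group value.
#' @param sf_mean mean of the SF weight distribution (pA); default the
#'   group value.
#' @param sf_cv coefficient of variation of the weight distribution
#'   (default 0.8, the log-normal spread seen in the fitted amplitude
#'   distributions).
#' @param noise_cv multiplicative SD of the MAX measurement (default
#'   0.05).
#' @param sf_per_cell observed SFs per cell (default 2, max 3).
#' @param seed optional integer seed.
#' @return list with `cells` (list of [cell_record()]) and `truth`
#'   (data.frame of per-cell `n_inputs` and noiseless `sum_w_pa`).
#' @export
gen_population <- function(age_group = c("subsong", "plastic", "adult"),
                           n_cells = 50L, n_inputs = NULL,
                           sf_mean = NULL, sf_cv = 0.8,
                           noise_cv = 0.05, sf_per_cell = 2L,
                           seed = NULL) {
  age_group <- match.arg(age_group)
  ref <- synaptic_summary()
  ref <- ref[ref$age_group == age_group, ]
  if (is.null(n_inputs)) n_inputs <- ref$n_inputs
  if (is.null(sf_mean)) sf_mean <- ref$sf_mean_pa
  sf_per_cell <- min(as.integer(sf_per_cell), 3L, n_inputs)
  par <- params_from_moments(sf_mean, sf_mean * sf_cv)
  with_opt_seed(seed, {
    cells <- vector("list", n_cells)
    truth <- data.frame(cell = seq_len(n_cells), n_inputs = n_inputs,
                        sum_w_pa = NA_real_)
    for (i in seq_len(n_cells)) {
      w <- if (sf_cv > 0)
        rlnorm(n_inputs, par$mu, par$sigma) else rep(sf_mean, n_inputs)
      truth$sum_w_pa[i] <- sum(w)
      max_na <- sum(w) * (1 + rnorm(1, 0, noise_cv)) / 1000
      sf_obs <- w[sample.int(n_inputs, sf_per_cell)]
      cells[[i]] <- cell_record(i, age_group, sf = sf_obs,
                                max_na = max_na)
    }
    list(cells = cells, truth = truth)
  })
}

#' Closed-form firing rate of the leaky integrate-and-fire neuron
#'
#' Under constant drive `D = R * I - V_INH` (mV above rest) the LIF
#' inter-spike interval is `t_ref + tau_m * log(D / (D - (V_th - V_R)))`;
#' subthreshold drive gives rate 0.
#'
#' @param i_inj injected current (pA).
#' @param params an [ra_params()] object.
#' @param v_inh tonic inhibition (mV, default 0).
#' @return firing rate (Hz).
#' @export
lif_rate_closed_form <- function(i_inj, params = ra_params(),
                                 v_inh = 0) {
  d <- (params$r_in / 1000) * i_inj - v_inh
  dv <- params$v_th - params$v_r
  ifelse(d <= dv, 0,
         1000 / (params$t_ref + params$tau_m * log(d / (d - dv))))
}

# paint action-potential waveforms (one sample at +20 mV, reset sample at
# v_r) onto a subthreshold voltage trace
paint_spikes <- function(v, spike_times, dt_ms, v_reset) {
  idx <- pmin(pmax(round(spike_times / dt_ms), 1L), length(v))
  v[idx] <- 20
  after <- pmin(idx + 1L, length(v))
  v[after] <- v_reset
  v
}

#' Synthetic current-clamp F-I sweeps
#'
#' Generates 0.5 s current-step voltage responses for the F-I analysis,
#' with spikes rendered as brief +20 mV deflections so that
#' threshold-crossing detection applies:
#'
#' * `kind = "lif"`: a leaky integrate-and-fire neuron simulated with the
#'   same Euler core as the network model (no adaptation; its rate obeys
#'   [lif_rate_closed_form()]).
#' * `kind = "adapting"`: a spike-frequency-adapting neuron whose IFF
#'   decays exactly exponentially from `adapt_factor` times the
#'   steady-state rate with a known time constant `tau_adapt` - the
#'   ground truth for decay-fit recovery.  Spike times are obtained by
#'   integrating the instantaneous-rate profile.
#'
#' Subthreshold steps produce the exponential membrane charging
#' `V(t) = V_R + R I (1 - exp(-t / tau_m))` and no spikes.
#'
#' @param kind `"lif"` or `"adapting"`.
#' @param intensities injected currents (pA), default the -200 pA..2 nA
#'   protocol in 200 pA steps.
#' @param params an [ra_params()] object (passive properties, threshold).
#' @param tau_adapt adaptation decay time constant (ms, adapting kind).
#' @param adapt_factor initial IFF relative to steady state (default 2).
#' @param n_sweeps repeated sweeps per intensity (default 3).
#' @param dt_ms sampling interval (ms, default 0.05).
#' @param stim_dur step duration (ms, default 500).
#' @param seed optional integer seed (reserved; the generators are
#'   deterministic by default).
#' @return list of `list(intensity_pA, sweeps)` as ingested by
#'   [fi_analysis()], with attributes `dt_ms`, `stim_dur` and `truth`
#'   (kind, tau_adapt).
#' @export
gen_current_clamp <- function(kind = c("lif", "adapting"),
                              intensities = seq(-200, 2000, by = 200),
                              params = ra_params(), tau_adapt = 30,
                              adapt_factor = 2, n_sweeps = 3L,
                              dt_ms = 0.05, stim_dur = 500,
                              seed = NULL) {
  kind <- match.arg(kind)
  n_steps <- round(stim_dur / dt_ms)
  t_grid <- seq_len(n_steps) * dt_ms
  sub_v <- function(I)
    params$v_r + (params$r_in / 1000) * I *
      (1 - exp(-t_grid / params$tau_m))
  out <- lapply(intensities, function(I) {
    v <- switch(kind,
      lif = {
        res <- lif_simulate_cpp(
          n_steps, dt_ms, params$tau_m, params$v_r, params$v_th,
          params$r_in / 1000, params$t_ref, params$tau_s,
          params$tau_nmda, 0, I, integer(0), numeric(0), integer(0),
          0, 0, params$mg, params$mg_scale, params$mg_slope, 0, 0,
          FALSE, TRUE)
        vv <- res$v[-1]
        if (length(res$spike_times))
          vv <- paint_spikes(vv, res$spike_times, dt_ms, params$v_r)
        vv
      },
      adapting = {
        f_ss <- lif_rate_closed_form(I, params)
        if (f_ss <= 0) sub_v(I)
        else {
          f0 <- adapt_factor * f_ss
          # cumulative expected spike count of the exponential IFF decay
          lam <- (f_ss * t_grid + (f0 - f_ss) * tau_adapt *
                    (1 - exp(-t_grid / tau_adapt))) / 1000
          n_spk <- floor(lam[n_steps])
          st <- if (n_spk >= 1)
            approx(lam, t_grid, xout = seq_len(n_spk))$y else numeric(0)
          vv <- pmin(sub_v(I), params$v_th - 2)
          paint_spikes(vv, st, dt_ms, params$v_r)
        }
      })
    list(intensity_pA = I, sweeps = rep(list(v), n_sweeps))
  })
  attr(out, "dt_ms") <- dt_ms
  attr(out, "stim_dur") <- stim_dur
  attr(out, "truth") <- list(kind = kind,
                             tau_adapt = if (kind == "adapting")
                               tau_adapt else NA_real_)
  out
}
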