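# test-owned synthetic-trace builder, independent of the package's
# generator: a noise-free EPSC-shaped deflection of exact peak amplitude
# on a flat baseline, plus optional Gaussian noise
make_epsc_trace <- function(peak, dt_ms = 0.1, pre_ms = 50, post_ms = 30,
                            onset_ms = 5, rise = 1, decay = 5,
                            noise_sd = 0, stim_intensity = NA) {
  n <- round((pre_ms + post_ms) / dt_ms)
  t <- seq_len(n) * dt_ms - (pre_ms + onset_ms)
  tpk <- log(decay / rise) * rise * decay / (decay - rise)
  norm <- exp(-tpk / decay) - exp(-tpk / rise)
  y <- ifelse(t < 0, 0, (exp(-t / decay) - exp(-t / rise)) / norm) * peak
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  evoked_trace(y, dt_ms, stim_time = pre_ms,
               stim_intensity = stim_intensity)
}

# test-owned threshold-crossing spike detector (independent of the
# package's internal one)
detect_spikes_v_test <- function(v, dt_ms, thr = -20) {
  which(v[-1] >= thr & v[-length(v)] < thr) * dt_ms
}

# population of cells with exactly n equal inputs (noiseless fixture)
make_equal_cells <- function(n_cells, n_inputs, w_pa, age_group) {
  lapply(seq_len(n_cells), function(i)
    cell_record(i, age_group, sf = w_pa,
                max_na = n_inputs * w_pa / 1000))
}
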