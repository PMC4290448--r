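#' Construct an evoked-current trace
#'
#' A single stimulus-locked current record on a regular time base.
#'
#' @param samples current samples (pA).
#' @param dt_ms sampling interval (ms); 0.01 at the 100 kHz digitization
#'   default.
#' @param stim_time stimulus time (ms from record start).
#' @param stim_intensity stimulation intensity (uA).
#' @param holding holding potential (mV), -70 or +40.
#' @return An object of class `evoked_trace`.
#' @export
evoked_trace <- function(samples, dt_ms = 0.01, stim_time = 50,
                         stim_intensity = NA_real_, holding = -70) {
  if (stim_time < 0 || stim_time > length(samples) * dt_ms)
    stop("stim_time outside the record", call. = FALSE)
  structure(list(samples = as.numeric(samples), dt_ms = dt_ms,
                 stim_time = stim_time, stim_intensity = stim_intensity,
                 holding = holding),
            class = "evoked_trace")
}

# 1 ms sliding-window (moving average) smoothing of a sample vector
sliding_smooth <- function(x, dt_ms, window_ms = 1) {
  w <- max(1L, round(window_ms / dt_ms))
  if (w == 1L) return(x)
  k <- rep(1 / w, w)
  sm <- stats::filter(x, k, sides = 2)
  # shrink the window at the edges instead of returning NA
  na <- which(is.na(sm))
  for (i in na) {
    lo <- max(1L, i - w %/% 2L)
    hi <- min(length(x), i + w %/% 2L)
    sm[i] <- mean(x[lo:hi])
  }
  as.numeric(sm)
}

# smoothed peak of one trace in the post-stimulus search window
trace_peak <- function(trace, window_ms = c(2, 30)) {
  sm <- sliding_smooth(trace$samples, trace$dt_ms)
  t_rel <- seq_along(sm) * trace$dt_ms - trace$stim_time
  idx <- which(t_rel >= window_ms[1] & t_rel <= window_ms[2])
  if (!length(idx)) stop("empty peak-search window", call. = FALSE)
  pk <- idx[which.max(sm[idx])]
  list(peak = sm[pk], latency = t_rel[pk])
}

# RMS of the pre-stimulus baseline (about its mean), raw samples
baseline_rms <- function(trace, baseline_ms = 50) {
  t_rel <- seq_along(trace$samples) * trace$dt_ms - trace$stim_time
  idx <- which(t_rel < 0 & t_rel >= -baseline_ms)
  if (length(idx) < 2L)
    stop("no pre-stimulus baseline to estimate noise from",
         call. = FALSE)
  x <- trace$samples[idx]
  sqrt(mean((x - mean(x))^2))
}

#' Single-fiber EPSC estimation from minimal-stimulation trials
#'
#' Classifies repeated trials at one (minimal) stimulation intensity into
#' successes and failures and quantifies the unitary single-fiber (SF)
#' input.  Traces are smoothed with a 1 ms sliding window; a trial is a
#' success when its post-stimulus peak (searched 2-30 ms after the
#' stimulus, excluding the artifact window) exceeds twice the baseline
#' noise RMS.  An SF is accepted only when the failure rate lies in the
#' 25-75% band and more than 3 successes were observed; otherwise the
#' measurement is returned flagged as rejected.
#'
#' @param traces list of `evoked_trace`s recorded at one intensity (>= 4).
#' @param noise_rms baseline noise RMS (pA); estimated from the 50 ms
#'   pre-stimulus baseline when `NULL`.
#' @param window_ms peak-search window after the stimulus (ms).
#' @return An object of class `sf_measurement`: `peak_amplitude` (pA, mean
#'   over successes), `cv` (SD/mean of success peaks), `latency_to_peak`
#'   (ms, from the mean success trace), `failure_rate`, `n_successes`,
#'   `success_peaks`, `accepted`, `reason`.
#' @export
detect_sf <- function(traces, noise_rms = NULL, window_ms = c(2, 30)) {
  if (length(traces) < 4L)
    stop("need at least 4 trials at the minimal intensity",
         call. = FALSE)
  if (is.null(noise_rms))
    noise_rms <- mean(vapply(traces, baseline_rms, numeric(1)))
  peaks <- lapply(traces, trace_peak, window_ms = window_ms)
  amp <- vapply(peaks, `[[`, numeric(1), "peak")
  success <- amp > 2 * noise_rms
  n_succ <- sum(success)
  failure_rate <- 1 - n_succ / length(traces)
  latency <- NA_real_
  if (n_succ > 0) {
    mean_tr <- traces[[which(success)[1]]]
    mean_tr$samples <- rowMeans(vapply(traces[success], `[[`,
      numeric(length(mean_tr$samples)), "samples"))
    latency <- trace_peak(mean_tr, window_ms)$latency
  }
  reason <- NULL
  if (failure_rate < 0.25 || failure_rate > 0.75)
    reason <- sprintf("failure rate %.2f outside the 25-75%% band",
                      failure_rate)
  else if (n_succ <= 3L)
    reason <- sprintf("only %d successes (need > 3)", n_succ)
  structure(list(
    peak_amplitude = if (n_succ) mean(amp[success]) else NA_real_,
    cv = if (n_succ >= 2L) sd(amp[success]) / mean(amp[success])
         else NA_real_,
    latency_to_peak = latency,
    failure_rate = failure_rate,
    n_successes = n_succ,
    success_peaks = amp[success],
    noise_rms = noise_rms,
    accepted = is.null(reason),
    reason = if (is.null(reason)) NA_character_ else reason),
    class = "sf_measurement")
}

#' @export
print.sf_measurement <- function(x, ...) {
  if (x$accepted)
    cat(sprintf(paste0("SF: %.1f pA (CV %.2f), failure rate %.2f, ",
                       "latency %.1f ms, %d successes\n"),
                x$peak_amplitude, x$cv, x$failure_rate,
                x$latency_to_peak, x$n_successes))
  else cat("SF rejected:", x$reason, "\n")
  invisible(x)
}

#' Inclusion test for a second single fiber in the same cell
#'
#' When two SF measurements are obtained in one cell from contiguous
#' stimulation-electrode pairs, the second is included only if the evoked
#' success amplitudes differ significantly (Student's t test, p < alpha),
#' i.e. the two electrode pairs plausibly recruited different fibers.
#'
#' @param peaks_a,peaks_b success peak amplitudes (pA) of the two
#'   candidate SFs (each n >= 2).
#' @param alpha significance level (default 0.05).
#' @return list with `include` (logical) and `p_value`.
#' @export
accept_second_sf <- function(peaks_a, peaks_b, alpha = 0.05) {
  if (length(peaks_a) < 2L || length(peaks_b) < 2L)
    stop("need >= 2 success peaks per candidate", call. = FALSE)
  p <- t.test(peaks_a, peaks_b, var.equal = TRUE)$p.value
  list(include = p < alpha, p_value = p)
}

#' Maximal evoked current from an intensity series
#'
#' Finds the saturating (MAX) stimulation intensity: the lowest intensity
#' whose mean smoothed peak no longer increases - all mean peaks at higher
#' intensities stay within `tol` (relative) of it - verified over at least
#' a threefold intensity range.  The MAX current is the mean peak at that
#' intensity, with a CV gate of 0.2.
#'
#' @param series list of `list(intensity = uA, traces = list of
#'   evoked_trace)`, ascending intensities.
#' @param tol relative plateau tolerance (default 0.10).
#' @param cv_max CV gate at the plateau (default 0.2).
#' @param window_ms peak-search window (ms post-stimulus).
#' @return An object of class `max_measurement`: `peak_amplitude` (nA),
#'   `cv`, `latency_to_peak` (ms), `plateau_intensity` (uA), `accepted`,
#'   `reason`.  Errors with "no saturation" when no plateau exists within
#'   the series.
#' @export
detect_max <- function(series, tol = 0.10, cv_max = 0.2,
                       window_ms = c(2, 30)) {
  intens <- vapply(series, `[[`, numeric(1), "intensity")
  if (is.unsorted(intens, strictly = TRUE))
    stop("intensities must be strictly ascending", call. = FALSE)
  stats <- lapply(series, function(lv) {
    pk <- lapply(lv$traces, trace_peak, window_ms = window_ms)
    amp <- vapply(pk, `[[`, numeric(1), "peak")
    lat <- vapply(pk, `[[`, numeric(1), "latency")
    list(mean = mean(amp), cv = sd(amp) / mean(amp),
         latency = mean(lat), n = length(amp))
  })
  means <- vapply(stats, `[[`, numeric(1), "mean")
  plateau <- NA_integer_
  for (i in seq_along(intens)) {
    if (max(intens) < 3 * intens[i]) break
    higher <- means[intens > intens[i]]
    if (all(abs(higher - means[i]) <= tol * means[i])) {
      plateau <- i
      break
    }
  }
  if (is.na(plateau))
    stop("no saturation: EPSC peak keeps increasing within the series",
         call. = FALSE)
  st <- stats[[plateau]]
  if (st$n < 4L)
    stop("need >= 4 traces at the plateau intensity", call. = FALSE)
  reason <- if (st$cv > cv_max)
    sprintf("plateau CV %.2f exceeds %.2f", st$cv, cv_max)
  structure(list(peak_amplitude = st$mean / 1000, cv = st$cv,
                 latency_to_peak = st$latency,
                 plateau_intensity = intens[plateau],
                 accepted = is.null(reason),
                 reason = if (is.null(reason)) NA_character_ else reason),
            class = "max_measurement")
}

#' @export
print.max_measurement <- function(x, ...) {
  cat(sprintf("MAX: %.2f nA (CV %.2f) at %g uA%s\n", x$peak_amplitude,
              x$cv, x$plateau_intensity,
              if (x$accepted) "" else paste0(" [rejected: ", x$reason,
                                             "]")))
  invisible(x)
}

#' Construct a per-cell record of evoked-current measurements
#'
#' @param id cell identifier.
#' @param age_group one of `"subsong"`, `"plastic"`, `"adult"`.
#' @param sf numeric vector of SF peak amplitudes (pA), at most 3.
#' @param max_na MAX current (nA), or `NA` when not measured.
#' @param pathway `"HVC"` or `"LMAN"`.
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(id, age_group, sf = numeric(0), max_na = NA_real_,
                        pathway = "HVC") {
  age_group <- match.arg(age_group, c("subsong", "plastic", "adult"))
  if (length(sf) > 3L)
    stop("at most 3 SFs per cell", call. = FALSE)
  structure(list(id = id, age_group = age_group, sf = as.numeric(sf),
                 max_na = max_na, pathway = pathway),
            class = "cell_record")
}

#' Estimate the number of synaptic inputs per cell and age group
#'
#' Two estimators of the relative number of converging inputs, both
#' assuming linear summation:
#'
#' * `"mean_sf"`: each cell's MAX current is divided by the *group-mean*
#'   SF current; the per-cell counts are averaged (mean and SD reported).
#' * `"fiber_fraction"`: every SF contributes its fiber fraction
#'   SF/MAX within its own cell; the group estimate is the inverse of the
#'   group-mean fiber fraction.
#' * `"group_means"`: group-mean MAX divided by group-mean SF (the
#'   summary-table shortcut; equal to `"mean_sf"` up to averaging order).
#'
#' All estimates are lower bounds on the true input count.
#'
#' @param cells list of [cell_record()]s.
#' @param method `"mean_sf"` (default), `"fiber_fraction"` or
#'   `"group_means"`.
#' @return data.frame with one row per age group present: `age_group`,
#'   `n_inputs`, `sd_inputs` (mean_sf only), `n_cells`, `n_sfs`.
#' @export
estimate_n_inputs <- function(cells,
                              method = c("mean_sf", "fiber_fraction",
                                         "group_means")) {
  method <- match.arg(method)
  groups <- vapply(cells, `[[`, character(1), "age_group")
  rows <- lapply(unique(groups), function(g) {
    cg <- cells[groups == g]
    sfs <- unlist(lapply(cg, `[[`, "sf"))
    maxs <- vapply(cg, `[[`, numeric(1), "max_na") * 1000  # pA
    has_max <- is.finite(maxs)
    if (!length(sfs) || !any(has_max))
      stop(sprintf("group '%s' lacks SF or MAX measurements", g),
           call. = FALSE)
    est <- switch(method,
      mean_sf = {
        counts <- maxs[has_max] / mean(sfs)
        c(mean(counts), sd(counts))
      },
      fiber_fraction = {
        ff <- unlist(lapply(cg, function(cc) {
          if (!is.finite(cc$max_na) || !length(cc$sf)) return(NULL)
          cc$sf / (cc$max_na * 1000)
        }))
        if (!length(ff))
          stop(sprintf("group '%s' has no cell with both SF and MAX", g),
               call. = FALSE)
        c(1 / mean(ff), NA_real_)
      },
      group_means = c(mean(maxs[has_max]) / mean(sfs), NA_real_))
    data.frame(age_group = g, n_inputs = est[1], sd_inputs = est[2],
               n_cells = sum(has_max), n_sfs = length(sfs))
  })
  do.call(rbind, rows)
}

#' NMDA:AMPA receptor composition from holding-potential amplitude ratios
#'
#' At -70 mV the magnesium block silences the NMDA component, so the
#' evoked current is essentially AMPA; at +40 mV the block is relieved
#' and both components contribute.  With peak conductances `g_A`, `g_N`
#' and reversal potential `E`, the amplitude ratio is
#' `g_A (E + 70) / ((g_A + g_N)(E - 40))`; inverting in magnitude gives
#' the AMPA fraction `r = ratio * |E - 40| / |E + 70|` (`= ratio * 40/70`
#' at `E = 0`) and the conductance ratio `g_N : g_A = (1 - r) / r`.
#'
#' @param ratio measured |-70 mV| / |+40 mV| peak-amplitude ratio, >= 0.
#' @param e_rev excitatory reversal potential (mV, default 0).
#' @param v_hold holding potentials (mV), default `c(-70, 40)`.
#' @return list with `r` (AMPA fraction) and `nmda_ampa_ratio`
#'   (`(1 - r)/r`, `Inf` for pure NMDA).
#' @export
estimate_receptor_ratio <- function(ratio, e_rev = 0,
                                    v_hold = c(-70, 40)) {
  if (!is.finite(ratio) || ratio < 0)
    stop("ratio must be non-negative", call. = FALSE)
  r <- ratio * abs(e_rev - v_hold[2]) / abs(e_rev - v_hold[1])
  if (r > 1)
    stop("implied AMPA fraction exceeds 1: inconsistent measurement",
         call. = FALSE)
  list(r = r, nmda_ampa_ratio = if (r > 0) (1 - r) / r else Inf)
}

#' Forward holding-potential amplitude ratio for a given AMPA fraction
#'
#' Inverse companion of [estimate_receptor_ratio()]; useful for
#' round-trip checks and for generating synthetic measurements.
#'
#' @inheritParams estimate_receptor_ratio
#' @param r AMPA fraction of the synaptic conductance, in \[0, 1\].
#' @return expected |-70| / |+40| amplitude ratio.
#' @export
receptor_ratio_forward <- function(r, e_rev = 0, v_hold = c(-70, 40)) {
  stopifnot(r >= 0, r <= 1)
  r * abs(e_rev - v_hold[1]) / abs(e_rev - v_hold[2])
}

# threshold-crossing spike detection on a voltage sweep
detect_spikes_v <- function(v, dt_ms, threshold = -20, refract_ms = 1) {
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (!length(up)) return(numeric(0))
  times <- up * dt_ms
  keep <- c(TRUE, diff(times) >= refract_ms)
  # enforce the dead time sequentially, not just pairwise
  out <- times[1]
  for (t in times[-1]) if (t - out[length(out)] >= refract_ms)
    out <- c(out, t)
  out
}

#' F-I curve and spike-frequency adaptation analysis
#'
#' Quantifies intrinsic excitability from current-clamp responses to 0.5 s
#' current steps (-200 pA to 2 nA in 200 pA steps by protocol).  Spikes
#' are detected by upward threshold crossing (default -20 mV, 1 ms dead
#' time); per sweep the instantaneous firing frequency (IFF) is the
#' reciprocal inter-spike interval, evaluated on a 1 ms grid and averaged
#' across the repeated sweeps of each intensity.  Reported per intensity:
#' the mean IFF, the adaptation ratio (mean IFF in the first 5 ms of the
#' step over the last 5 ms), and the adaptation time constant from a
#' single-exponential fit to the first 100 ms of the IFF decay.  The F-I
#' slope is a linear fit of mean IFF against injected current restricted
#' to steps <= 1.4 nA.
#'
#' Sweeps with fewer than 2 spikes have no defined IFF and are excluded
#' (counted in `n_excluded_sweeps`).
#'
#' @param recordings list of `list(intensity_pA =, sweeps = list of
#'   voltage vectors (mV))`; all sweeps share `dt_ms` and cover the step.
#' @param dt_ms sampling interval (ms).
#' @param stim_dur step duration (ms, default 500).
#' @param spike_threshold detection threshold (mV, default -20).
#' @param edge_ms width of the first/last averaging windows (ms,
#'   default 5).
#' @param fit_ms decay-fit span from the first spike (ms, default 100).
#' @return An object of class `fi_curve`: `table` (data.frame with
#'   `intensity_pA`, `mean_iff`, `adaptation_ratio`, `decay_tau`,
#'   `n_sweeps`, `n_excluded_sweeps`), `slope_linear` (Hz/nA),
#'   `slope_r2`, and `iff_traces` (per-intensity average IFF on the 1 ms
#'   grid).
#' @export
fi_analysis <- function(recordings, dt_ms, stim_dur = 500,
                        spike_threshold = -20, edge_ms = 5,
                        fit_ms = 100) {
  grid <- seq(0, stim_dur, by = 1)
  per <- lapply(recordings, function(rec) {
    iffs <- excl <- 0L
    traces <- list()
    for (v in rec$sweeps) {
      st <- detect_spikes_v(v, dt_ms, spike_threshold)
      if (length(st) < 2L) { excl <- excl + 1L; next }
      tr <- instantaneous_rate(spike_train(st, stim_dur), grid,
                               fill = "na")
      traces[[length(traces) + 1L]] <- tr$values
    }
    if (!length(traces))
      return(list(iff = rep(NA_real_, length(grid)), excl = excl,
                  n = length(rec$sweeps)))
    mat <- do.call(cbind, traces)
    avg <- rowMeans(mat, na.rm = TRUE)
    avg[!is.finite(avg)] <- NA_real_
    list(iff = avg, excl = excl, n = length(rec$sweeps))
  })
  intens <- vapply(recordings, `[[`, numeric(1), "intensity_pA")
  tab <- do.call(rbind, lapply(seq_along(per), function(i) {
    iff <- per[[i]]$iff
    first <- iff[grid <= edge_ms]
    last <- iff[grid >= stim_dur - edge_ms]
    f_i <- if (any(is.finite(first))) mean(first, na.rm = TRUE)
           else NA_real_
    f_f <- if (any(is.finite(last))) mean(last, na.rm = TRUE)
           else NA_real_
    data.frame(intensity_pA = intens[i],
               mean_iff = if (any(is.finite(iff)))
                 mean(iff, na.rm = TRUE) else NA_real_,
               adaptation_ratio = if (is.finite(f_i) && is.finite(f_f) &&
                                      f_f > 0) f_i / f_f else NA_real_,
               decay_tau = fit_iff_decay(grid, iff, fit_ms),
               n_sweeps = per[[i]]$n,
               n_excluded_sweeps = per[[i]]$excl)
  }))
  lin <- tab[tab$intensity_pA <= 1400 & is.finite(tab$mean_iff), ]
  slope <- r2 <- NA_real_
  if (nrow(lin) >= 2L) {
    fit <- lm(mean_iff ~ I(intensity_pA / 1000), data = lin)
    slope <- coef(fit)[[2]]
    r2 <- summary(fit)$r.squared
  }
  structure(list(table = tab, slope_linear = slope, slope_r2 = r2,
                 iff_traces = lapply(per, `[[`, "iff"), grid = grid),
            class = "fi_curve")
}

# single-exponential fit f(t) = a exp(-t/tau) + c to the IFF decay over
# fit_ms from the first defined IFF sample; NA when the curve does not
# decay or the fit fails
fit_iff_decay <- function(grid, iff, fit_ms = 100) {
  ok <- which(is.finite(iff))
  if (length(ok) < 5L) return(NA_real_)
  t0 <- grid[ok[1]]
  sel <- ok[grid[ok] <= t0 + fit_ms]
  t <- grid[sel] - t0
  y <- iff[sel]
  if (length(y) < 5L || y[1] <= 1.05 * mean(tail(y, 3)))
    return(NA_real_)
  c0 <- max(min(y), 0)
  a0 <- max(y[1] - c0, 1e-6)
  fit <- tryCatch(
    nls(y ~ a * exp(-t / tau) + c,
        start = list(a = a0, tau = fit_ms / 3, c = c0),
        control = list(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  tau <- coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0 || tau > 10 * fit_ms) NA_real_ else tau
}

#' @export
print.fi_curve <- function(x, ...) {
  cat(sprintf("F-I analysis: slope %.1f Hz/nA (R^2 %.3f) over %d steps\n",
              x$slope_linear, x$slope_r2, nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
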