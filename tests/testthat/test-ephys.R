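test_that("single-fiber detection classifies successes and failures", {
  withr::with_seed(61, {
    # 4 successes of known peaks + 4 failures, light noise
    peaks <- c(48, 50, 52, 50)
    traces <- c(lapply(peaks, make_epsc_trace, noise_sd = 0),
                lapply(1:4, function(i) make_epsc_trace(0, noise_sd = 0)))
    sf <- detect_sf(traces, noise_rms = 3)
    expect_true(sf$accepted)
    expect_equal(sf$failure_rate, 0.5)
    expect_identical(sf$n_successes, 4L)
    # the 1 ms sliding window shaves ~1% off the double-exponential peak
    expect_equal(sf$peak_amplitude, mean(peaks), tolerance = 0.02)
    # CV is invariant to the common waveform shape
    expect_equal(sf$cv, sd(peaks) / mean(peaks), tolerance = 1e-6)
    # latency to peak: onset 5 ms + double-exponential peak ~2.01 ms
    expect_equal(sf$latency_to_peak, 5 + log(5) * 5 / 4, tolerance = 0.2)
  })
})

test_that("single-fiber gates reject bad failure rates and low counts", {
  withr::with_seed(62, {
    all_fail <- lapply(1:8, function(i)
      make_epsc_trace(0, noise_sd = 3))
    sf <- detect_sf(all_fail, noise_rms = 3)
    expect_false(sf$accepted)
    expect_match(sf$reason, "failure rate")
    # 3 successes is not enough (N > 3 required)
    few <- c(lapply(1:3, function(i) make_epsc_trace(50, noise_sd = 0)),
             lapply(1:5, function(i) make_epsc_trace(0, noise_sd = 0)))
    sf2 <- detect_sf(few, noise_rms = 3)
    expect_false(sf2$accepted)
    expect_match(sf2$reason, "successes")
    expect_error(detect_sf(all_fail[1:3]), "at least 4")
  })
})

test_that("noise RMS is estimated from the pre-stimulus baseline", {
  withr::with_seed(63, {
    traces <- lapply(1:6, function(i) make_epsc_trace(0, noise_sd = 3))
    sf <- detect_sf(traces)
    expect_equal(sf$noise_rms, 3, tolerance = 0.3)
  })
})

test_that("second-SF inclusion follows the two-sample t test", {
  same <- accept_second_sf(c(20, 21, 19, 20), c(20, 21, 19, 20))
  expect_false(same$include)
  expect_equal(same$p_value, 1)
  diff <- accept_second_sf(c(20, 21, 19, 20), c(80, 82, 78, 81))
  expect_true(diff$include)
  # oracle: direct t statistic for the distinct case
  expect_equal(diff$p_value,
               t.test(c(20, 21, 19, 20), c(80, 82, 78, 81),
                      var.equal = TRUE)$p.value)
  expect_error(accept_second_sf(5, c(1, 2)), ">= 2")
})

test_that("second-SF test is calibrated at the nominal type-I level", {
  withr::with_seed(64, {
    hits <- replicate(600, {
      accept_second_sf(rnorm(6, 50, 5), rnorm(6, 50, 5))$include
    })
    rate <- mean(hits)
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 600))
  })
})

test_that("MAX detection finds the plateau and enforces its gates", {
  withr::with_seed(65, {
    # recruitment curve saturating at 800 pA past 100 uA
    mk_level <- function(I, mean_peak) list(
      intensity = I,
      traces = lapply(1:6, function(k)
        make_epsc_trace(mean_peak, noise_sd = 3, stim_intensity = I)))
    series <- list(mk_level(10, 100), mk_level(30, 350),
                   mk_level(100, 800), mk_level(300, 800),
                   mk_level(1000, 800))
    mx <- detect_max(series)
    expect_true(mx$accepted)
    expect_equal(mx$plateau_intensity, 100)
    expect_equal(mx$peak_amplitude, 0.8, tolerance = 0.02)
    expect_lt(mx$cv, 0.2)
    # strictly growing response: no saturation error
    grow <- list(mk_level(10, 100), mk_level(30, 200),
                 mk_level(100, 400), mk_level(300, 700),
                 mk_level(1000, 1100))
    expect_error(detect_max(grow), "no saturation")
    # unstable plateau: CV gate trips
    noisy <- list(mk_level(10, 100),
                  list(intensity = 100, traces = lapply(
                    c(400, 900, 1200, 500, 1000, 800), make_epsc_trace)),
                  list(intensity = 400, traces = lapply(
                    c(900, 700, 850, 780, 810, 760), make_epsc_trace)))
    mx2 <- detect_max(noisy)
    expect_false(mx2$accepted)
    expect_match(mx2$reason, "CV")
  })
})

test_that("input counting is exact on equal-input populations", {
  cells <- make_equal_cells(6, n_inputs = 15, w_pa = 40,
                            age_group = "plastic")
  for (meth in c("mean_sf", "fiber_fraction", "group_means")) {
    est <- estimate_n_inputs(cells, method = meth)
    expect_equal(est$n_inputs, 15, tolerance = 1e-9)
  }
  expect_error(estimate_n_inputs(list(
    cell_record(1, "adult", sf = numeric(0), max_na = 1))), "lacks")
  expect_error(cell_record(1, "adult", sf = c(1, 2, 3, 4)), "at most 3")
})

test_that("receptor-ratio inversion matches the printed arithmetic", {
  expect_equal(estimate_receptor_ratio(0)$r, 0)
  expect_identical(estimate_receptor_ratio(0)$nmda_ampa_ratio, Inf)
  # plastic-song ratio 0.10 -> r = 0.10 * 40/70 = 0.0571 -> 0.06
  expect_equal(round(estimate_receptor_ratio(0.10)$r, 2), 0.06)
  # subsong ratio 0.17 -> NMDA:AMPA ~ 9.3 -> 9:1
  expect_equal(round(estimate_receptor_ratio(0.17)$nmda_ampa_ratio), 9)
  expect_error(estimate_receptor_ratio(2), "exceeds 1")
  expect_error(estimate_receptor_ratio(-0.1), "non-negative")
  # round trip over the full AMPA-fraction range
  for (r in seq(0, 1, by = 0.1))
    expect_equal(estimate_receptor_ratio(receptor_ratio_forward(r))$r, r,
                 tolerance = 1e-12)
})

test_that("F-I analysis of a non-adapting LIF matches the closed form", {
  cc <- gen_current_clamp("lif", intensities = seq(-200, 2000, 200),
                          dt_ms = 0.02)
  fi <- fi_analysis(cc, dt_ms = attr(cc, "dt_ms"))
  tab <- fi$table
  # subthreshold steps: no IFF
  expect_true(all(is.na(tab$mean_iff[tab$intensity_pA <= 0])))
  # non-adapting: ratio 1 where both edge windows contain spikes
  high <- tab$intensity_pA >= 1200 & is.finite(tab$adaptation_ratio)
  expect_true(any(high))
  expect_true(all(abs(tab$adaptation_ratio[high] - 1) < 0.02))
  # no exponential decay to fit
  expect_true(all(is.na(tab$decay_tau)))
  # slope vs closed-form secant over the same fitted intensities
  lif_f <- function(I) {
    d <- 0.26 * I
    ifelse(d <= 20, 0, 1000 / (1.5 + 20 * log(d / (d - 20))))
  }
  used <- tab$intensity_pA[tab$intensity_pA <= 1400 &
                             is.finite(tab$mean_iff)]
  secant <- (lif_f(max(used)) - lif_f(min(used))) /
    ((max(used) - min(used)) / 1000)
  expect_equal(fi$slope_linear, secant, tolerance = 0.05)
  expect_gt(fi$slope_r2, 0.95)
})

test_that("F-I analysis recovers a known IFF decay time constant", {
  cc <- gen_current_clamp("adapting", intensities = c(800, 1200, 1600),
                          tau_adapt = 30, dt_ms = 0.02)
  fi <- fi_analysis(cc, dt_ms = attr(cc, "dt_ms"))
  tau <- fi$table$decay_tau
  expect_true(all(is.finite(tau)))
  expect_true(all(abs(tau - 30) / 30 < 0.1))
  # adaptation ratio reflects the factor-2 initial elevation
  expect_true(all(fi$table$adaptation_ratio > 1.5))
})

test_that("sweeps with too few spikes are excluded and flagged", {
  # one sweep with a single painted spike: IFF undefined
  v <- rep(-70, 2000)
  v[1000] <- 20
  fi <- fi_analysis(list(list(intensity_pA = 100,
                              sweeps = list(v, v))),
                    dt_ms = 0.25)
  expect_identical(fi$table$n_excluded_sweeps, 2L)
  expect_true(is.na(fi$table$mean_iff))
})
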