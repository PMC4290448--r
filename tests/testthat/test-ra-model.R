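test_that("magnesium-block gating matches direct arithmetic", {
  # 1 / (1 + (0.5/3.57) e^{-V/16.13}) at V = 0 and V = -70
  expect_equal(nmda_gating(0), 3.57 / (3.57 + 0.5), tolerance = 1e-12)
  expect_equal(nmda_gating(-70),
               1 / (1 + (0.5 / 3.57) * exp(70 / 16.13)),
               tolerance = 1e-12)
  expect_equal(nmda_gating(-70), 0.0852, tolerance = 1e-3)
  # strictly increasing, saturating at 1
  v <- seq(-120, 120, by = 1)
  expect_true(all(diff(nmda_gating(v)) > 0))
  expect_equal(nmda_gating(1e4), 1, tolerance = 1e-12)
})

test_that("tonic inhibition follows R_INH * m * rho in mV", {
  expect_equal(tonic_inhibition(50, 0.9), 36)
  expect_equal(tonic_inhibition(70, 0.37), 20.72)
  # linear in rho and m
  expect_equal(tonic_inhibition(50, 0.4), 2 * tonic_inhibition(50, 0.2))
  expect_equal(tonic_inhibition(80, 0.5), 2 * tonic_inhibition(40, 0.5))
})

test_that("membrane settles to V_R - V_INH without synaptic input", {
  p <- ra_params(song_dur = 500, n_hvc = 50L)
  st <- simulate_rendition(NULL, list(), NULL, p, v_inh = 10,
                           return_v = TRUE)
  expect_length(st$times, 0)
  v <- attr(st, "v")
  expect_equal(tail(v, 1), -80, tolerance = 1e-3)
})

test_that("constant-drive firing matches the closed-form LIF rate", {
  # R I = 40 mV: ISI = t_ref + tau_m ln(40 / (40 - 20)) = 15.3629 ms
  expected_hz <- 1000 / (1.5 + 20 * log(2))
  p <- ra_params(song_dur = 5000, n_hvc = 500L)
  st <- simulate_rendition(NULL, list(), NULL, p, v_inh = 0,
                           i_inj = 40 / 0.26)
  rate <- length(st$times) / 5
  expect_equal(rate, expected_hz, tolerance = 0.02)
  # refractory clamp: no two spikes closer than t_ref
  expect_true(all(diff(st$times) >= p$t_ref))
  # integration convergence: halving dt changes the count by < 1%
  p2 <- ra_params(song_dur = 5000, n_hvc = 500L, dt = 0.1)
  st2 <- simulate_rendition(NULL, list(), NULL, p2, v_inh = 0,
                            i_inj = 40 / 0.26)
  expect_lt(abs(length(st2$times) - length(st$times)) /
              length(st$times), 0.01)
})

test_that("with LMAN silenced the rendition is deterministic (CC = 1)", {
  # all rendition-to-rendition variability originates from LMAN; with it
  # silenced (and inhibition removed so HVC alone drives spikes at this
  # operating point) every rendition is identical
  p <- ra_params()
  hvc <- hvc_song()
  prof <- sample_weights(0.9, seed = 31)
  rends <- lapply(1:3, function(i)
    simulate_rendition(prof, hvc, NULL, p, v_inh = 0))
  expect_identical(rends[[1]]$times, rends[[2]]$times)
  expect_gt(length(rends[[1]]$times), 0)
  expect_equal(cc_average(rends)$mean_cc, 1)
})

test_that("full rendition pipeline is seed-deterministic and validated", {
  p <- ra_params()
  hvc <- hvc_song()
  prof <- sample_weights(0.9, seed = 32)
  a <- simulate_rendition(prof, hvc, lman_poisson(80, 1000, seed = 33), p)
  b <- simulate_rendition(prof, hvc, lman_poisson(80, 1000, seed = 33), p)
  expect_identical(a$times, b$times)
  expect_true(all(diff(a$times) >= p$t_ref))
  expect_error(
    simulate_rendition(prof, hvc, lman_poisson(80, 500, seed = 1), p),
    "duration")
  expect_error(ra_params(dt = 5), "dt must be smaller")
})

test_that("both NMDA gating modes run and agree to first order", {
  hvc <- hvc_song()
  prof <- sample_weights(0.9, seed = 34)
  lman <- lman_poisson(80, 1000, seed = 35)
  ra_arr <- simulate_rendition(prof, hvc, lman,
                               ra_params(nmda_mode = "arrival"))
  ra_con <- simulate_rendition(prof, hvc, lman,
                               ra_params(nmda_mode = "continuous"))
  expect_gt(length(ra_arr$times), 5)
  expect_gt(length(ra_con$times), 5)
  # same qualitative operating point: rates within 35% of each other
  expect_lt(abs(length(ra_con$times) - length(ra_arr$times)) /
              length(ra_arr$times), 0.35)
})
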