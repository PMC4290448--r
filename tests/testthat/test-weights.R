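test_that("log-normal MLE uses the printed estimators (1/n variance)", {
  # degenerate: identical samples
  f <- fit_lognormal(rep(7.5, 5))
  expect_equal(f$mu, log(7.5))
  expect_equal(f$sigma, 0)
  # {e^1, e^3}: logs are 1 and 3, population variance 1
  f <- fit_lognormal(c(exp(1), exp(3)))
  expect_equal(f$mu, 2)
  expect_equal(f$sigma^2, 1)
  expect_equal(f$n, 2L)
  # error paths
  expect_error(fit_lognormal(c(1, -2)), "positive")
  expect_error(fit_lognormal(5), "at least 2")
})

test_that("MLE recovers generating parameters at n = 10^4", {
  mu <- 3.9; sigma <- 0.83; n <- 1e4
  withr::with_seed(71, {
    x <- rlnorm(n, mu, sigma)
    f <- fit_lognormal(x)
    # analytic standard errors of the ML estimators
    expect_lt(abs(f$mu - mu), 3 * sigma / sqrt(n))
    expect_lt(abs(f$sigma - sigma), 3 * sigma / sqrt(2 * n))
  })
})

test_that("log-normal pdf is normalized with known value and mode", {
  f <- structure(list(mu = 4, sigma = 0.8, n = 0L),
                 class = "lognormal_fit")
  int <- integrate(function(x) lognormal_pdf(x, f), 0 + 1e-12, 1e6,
                   rel.tol = 1e-9)
  expect_equal(int$value, 1, tolerance = 1e-6)
  # direct arithmetic: pdf(e^4; mu=4, sigma=1) = 1/(e^4 sqrt(2 pi))
  f1 <- structure(list(mu = 4, sigma = 1, n = 0L),
                  class = "lognormal_fit")
  expect_equal(lognormal_pdf(exp(4), f1), 1 / (exp(4) * sqrt(2 * pi)),
               tolerance = 1e-10)
  # mode at exp(mu - sigma^2) dominates a sampled grid
  xmode <- exp(f$mu - f$sigma^2)
  grid <- seq(0.5, 500, length.out = 2000)
  expect_true(all(lognormal_pdf(xmode, f) >= lognormal_pdf(grid, f)))
  # error paths
  expect_error(lognormal_pdf(-1, f), "positive")
  expect_error(lognormal_pdf(1, structure(list(mu = 1, sigma = 0),
                                          class = "lognormal_fit")),
               "degenerate")
})

test_that("moment inversion hits the closed form and target moments", {
  p <- params_from_moments(70, 70)
  expect_equal(p$sigma^2, log(2), tolerance = 1e-12)
  expect_equal(p$mu, log(70) - log(2) / 2, tolerance = 1e-12)
  p0 <- params_from_moments(42, 0)
  expect_equal(p0$sigma, 0)
  expect_equal(p0$mu, log(42))
  expect_error(params_from_moments(-5, 1), "positive")
  # Monte-Carlo: sampled moments match the targets
  withr::with_seed(72, {
    x <- rlnorm(1e5, params_from_moments(50, 35)$mu,
                params_from_moments(50, 35)$sigma)
    expect_lt(abs(mean(x) - 50), 3 * 35 / sqrt(1e5))
    expect_lt(abs(sd(x) - 35), 0.02 * 35)
  })
})

test_that("connectivity profile is anchored, linear and clipped", {
  expect_equal(profile_at(0.9), c(m = 50, s = 35))
  expect_equal(profile_at(0.37), c(m = 70, s = 70))
  expect_equal(profile_at((0.9 + 0.37) / 2), c(m = 60, s = 52.5))
  expect_error(profile_at(0), "rho")
  expect_error(profile_at(1.2), "rho")
  # affine along the axis: midpoint value is the mean of the endpoints
  withr::with_seed(3, {
    for (i in 1:20) {
      r <- sort(runif(2, 0.2, 1))
      expect_equal(profile_at(r[1]) + profile_at(r[2]),
                   2 * profile_at(mean(r)), tolerance = 1e-10)
    }
  })
})

test_that("weight sampling conserves the active count and the moments", {
  pr <- sample_weights(1, n_hvc = 100, seed = 5)
  expect_true(all(pr$weights > 0))
  pr <- sample_weights(0.37, n_hvc = 100, seed = 5)
  expect_identical(sum(pr$weights > 0), 37L)
  # seed determinism
  expect_identical(sample_weights(0.5, n_hvc = 50, seed = 9)$weights,
                   sample_weights(0.5, n_hvc = 50, seed = 9)$weights)
  # exact count across random cases
  withr::with_seed(6, {
    for (i in 1:15) {
      rho <- runif(1, 0.15, 1)
      n <- sample(20:300, 1)
      if (round(rho * n) == 0) next
      pr <- sample_weights(rho, n_hvc = n)
      expect_identical(sum(pr$weights > 0), as.integer(round(rho * n)))
    }
  })
  expect_error(sample_weights(0.004, n_hvc = 100), "no active")
  # Monte-Carlo mean of active weights at the adult anchor
  withr::with_seed(7, {
    w <- replicate(400, {
      x <- sample_weights(0.37, 70, 70, n_hvc = 100)$weights
      mean(x[x > 0])
    })
    expect_lt(abs(mean(w) - 70), 3 * 70 / sqrt(400 * 37))
  })
})

test_that("sampling then refitting recovers the generating parameters", {
  par <- params_from_moments(50, 35)
  withr::with_seed(8, {
    x <- rlnorm(1e4, par$mu, par$sigma)
    f <- fit_lognormal(x)
    expect_lt(abs(f$mu - par$mu), 3 * par$sigma / sqrt(1e4))
    expect_lt(abs(f$sigma - par$sigma), 3 * par$sigma / sqrt(2e4))
  })
})
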