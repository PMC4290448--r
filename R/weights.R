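#' Maximum-likelihood log-normal fit to synaptic amplitudes
#'
#' Fits a log-normal distribution to a sample of positive peak-EPSC
#' amplitudes by maximum likelihood: `mu` is the mean of the log amplitudes
#' and `sigma^2` the *population* (1/n) variance of the log amplitudes.
#' The 1/n form is the ML estimator, not the unbiased 1/(n-1) form.
#'
#' @param samples numeric vector of positive amplitudes (pA).
#' @return An object of class `lognormal_fit`: list with `mu` (log-pA),
#'   `sigma` (>= 0) and `n`.
#' @seealso [lognormal_pdf()], [params_from_moments()]
#' @examples
#' fit_lognormal(c(exp(1), exp(3)))  # mu = 2, sigma = 1
#' @export
fit_lognormal <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("need at least 2 samples to estimate sigma", call. = FALSE)
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop("all samples must be positive and finite", call. = FALSE)
  lx <- log(samples)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  structure(list(mu = mu, sigma = sigma, n = length(samples)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("log-normal fit: mu = %.4f, sigma = %.4f (n = %d)\n",
              x$mu, x$sigma, x$n))
  cat(sprintf("  implied mean %.2f pA, SD %.2f pA\n",
              exp(x$mu + x$sigma^2 / 2),
              exp(x$mu + x$sigma^2 / 2) * sqrt(exp(x$sigma^2) - 1)))
  invisible(x)
}

#' Log-normal probability density
#'
#' Density of the fitted log-normal distribution,
#' `exp(-(log x - mu)^2 / (2 sigma^2)) / (x sigma sqrt(2 pi))`.
#'
#' @param x positive amplitude(s), pA.
#' @param fit a `lognormal_fit`, or any list with `mu` and `sigma`.
#' @return density values (1/pA).
#' @export
lognormal_pdf <- function(x, fit) {
  if (any(x <= 0)) stop("x must be positive", call. = FALSE)
  if (fit$sigma <= 0)
    stop("degenerate fit (sigma = 0) has no density", call. = FALSE)
  dlnorm(x, meanlog = fit$mu, sdlog = fit$sigma)
}

#' Log-normal parameters from a target mean and SD
#'
#' Inverts the moment relations of the log-normal distribution: a draw with
#' the returned `(mu, sigma)` has mean `m` and standard deviation `s`.
#' This is the bridge between the measured (mean, SD) anchors of the
#' HVC->RA amplitude distribution and log-normal sampling.
#'
#' @param m target mean (pA), > 0.
#' @param s target SD (pA), >= 0.
#' @return A `lognormal_fit` with `sigma^2 = log(1 + s^2/m^2)` and
#'   `mu = log(m) - sigma^2/2` (`n = 0`; not fitted from data).
#' @export
params_from_moments <- function(m, s) {
  if (!is.finite(m) || m <= 0) stop("m must be positive", call. = FALSE)
  if (!is.finite(s) || s < 0) stop("s must be non-negative", call. = FALSE)
  sigma2 <- log(1 + s^2 / m^2)
  structure(list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2), n = 0L),
            class = "lognormal_fit")
}

# anchors of the developmental axis: (rho, mean pA, SD pA) measured for the
# plastic-song and adult connectivity profiles
.profile_anchors <- list(plastic = c(rho = 0.9, m = 50, s = 35),
                         adult   = c(rho = 0.37, m = 70, s = 70))

#' Connectivity moments along the strengthening-and-pruning axis
#'
#' The developmental axis is parameterized by the fraction `rho` of HVC
#' inputs that remain active.  The mean `m` and SD `s` of the active-weight
#' distribution are linear functions of `rho`, anchored so that
#' `rho = 0.9 -> (50, 35) pA` (plastic-song connectivity) and
#' `rho = 0.37 -> (70, 70) pA` (adult connectivity), linearly extrapolated
#' outside the anchors and clipped at `m > 0`, `s >= 0`.
#'
#' @param rho fraction of active HVC inputs, in (0, 1].
#' @return named numeric vector `c(m = , s = )` in pA.
#' @export
profile_at <- function(rho) {
  if (any(!is.finite(rho)) || any(rho <= 0) || any(rho > 1))
    stop("rho must lie in (0, 1]", call. = FALSE)
  a <- .profile_anchors$plastic
  b <- .profile_anchors$adult
  f <- (rho - a["rho"]) / (b["rho"] - a["rho"])
  m <- pmax(a["m"] + f * (b["m"] - a["m"]), .Machine$double.eps)
  s <- pmax(a["s"] + f * (b["s"] - a["s"]), 0)
  c(m = unname(m), s = unname(s))
}

#' Sample a realized HVC->RA connectivity profile
#'
#' Draws one weight vector for the `n_hvc` HVC inputs: a uniformly random
#' subset of `round(rho * n_hvc)` inputs receives i.i.d. log-normal weights
#' with mean `m` and SD `s`; the remaining (pruned) inputs have weight
#' exactly 0.  Pruned indices are random because the HVC index maps to song
#' time, and deterministic pruning would impose temporal structure.
#'
#' @param rho fraction of active inputs, in (0, 1].
#' @param m,s mean and SD of the active-weight distribution (pA); defaults
#'   taken from [profile_at()] at `rho`.
#' @param n_hvc number of HVC neurons (default 100).
#' @param seed optional integer; fixes the draw.
#' @return An object of class `connectivity_profile`: list with `rho`, `m`,
#'   `s` and `weights` (length `n_hvc`, pA, zero = pruned).
#' @export
sample_weights <- function(rho, m = NULL, s = NULL, n_hvc = 100L,
                           seed = NULL) {
  if (length(rho) != 1 || !is.finite(rho) || rho <= 0 || rho > 1)
    stop("rho must lie in (0, 1]", call. = FALSE)
  if (is.null(m) || is.null(s)) {
    ms <- profile_at(rho)
    if (is.null(m)) m <- ms[["m"]]
    if (is.null(s)) s <- ms[["s"]]
  }
  n_hvc <- as.integer(n_hvc)
  if (n_hvc < 1L) stop("n_hvc must be >= 1", call. = FALSE)
  n_active <- as.integer(round(rho * n_hvc))
  if (n_active == 0L)
    stop("round(rho * n_hvc) = 0: no active inputs", call. = FALSE)
  par <- params_from_moments(m, s)
  w <- numeric(n_hvc)
  with_opt_seed(seed, {
    idx <- sample.int(n_hvc, n_active)
    w[idx] <- rlnorm(n_active, meanlog = par$mu, sdlog = par$sigma)
  })
  structure(list(rho = rho, m = m, s = s, weights = w),
            class = "connectivity_profile")
}

#' @export
print.connectivity_profile <- function(x, ...) {
  cat(sprintf(paste0("connectivity profile: rho = %.2f (%d/%d active),",
                     " target mean %.1f pA, SD %.1f pA\n"),
              x$rho, sum(x$weights > 0), length(x$weights), x$m, x$s))
  invisible(x)
}
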