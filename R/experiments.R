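#' Simulate one parameter point of the network model
#'
#' A "realization" is one random draw of the HVC->RA weight vector, held
#' fixed while the model sings `n_renditions` renditions, each with fresh
#' LMAN noise; the HVC raster is identical across renditions.  The
#' rendition-to-rendition CC is computed per realization and averaged
#' across realizations.
#'
#' @param rho fraction of active HVC inputs.
#' @param m,s mean and SD of the active-weight distribution (pA); default
#'   from [profile_at()] at `rho`.
#' @param lman LMAN configuration: list with `type`
#'   (`"poisson"`/`"bursty"`/`"modulated"`) and the matching fields of
#'   [lman_input()]; `rate = 0` silences LMAN.
#' @param params an [ra_params()] object.
#' @param n_realizations number of weight-vector draws (desk-scale
#'   default 50; 5000 for publication-scale averages).
#' @param n_renditions renditions per realization (default 200), >= 2.
#' @param seed master seed; all child seeds derive from it.
#' @param sigma_ms CC smoothing width (ms).
#' @return list with `mean_cc`, `se_cc` (SE over realizations),
#'   `mean_rate` (Hz), `cc` and `rate` per-realization vectors.
#' @export
run_point <- function(rho, m = NULL, s = NULL,
                      lman = list(type = "poisson"),
                      params = ra_params(),
                      n_realizations = 50L, n_renditions = 200L,
                      seed = NULL, sigma_ms = 10) {
  if (n_renditions < 2L) stop("n_renditions must be >= 2", call. = FALSE)
  if (is.null(m) || is.null(s)) {
    ms <- profile_at(rho)
    if (is.null(m)) m <- ms[["m"]]
    if (is.null(s)) s <- ms[["s"]]
  }
  hvc <- hvc_song(params$n_hvc, params$song_dur)
  v_inh <- tonic_inhibition(m, rho, params)
  lman_type <- if (is.null(lman$type)) "poisson" else lman$type
  lman_rate <- lman$rate
  silent <- !is.null(lman_rate) && identical(lman_rate, 0)
  seeds <- derive_seeds(seed, n_realizations)
  cc <- rate <- numeric(n_realizations)
  for (k in seq_len(n_realizations)) {
    res <- withr::with_seed(seeds[k], {
      prof <- sample_weights(rho, m, s, params$n_hvc)
      rends <- lapply(seq_len(n_renditions), function(j) {
        ltr <- if (silent) NULL else
          lman_input(lman_type, duration = params$song_dur,
                     rate = lman_rate,
                     b = if (is.null(lman$b)) 0 else lman$b,
                     mod_depth = if (is.null(lman$mod_depth)) 0 else
                       lman$mod_depth)
        simulate_rendition(prof, hvc, ltr, params, v_inh = v_inh)
      })
      counts <- vapply(rends, function(tr) length(tr$times), integer(1))
      list(cc = cc_average(rends, sigma_ms = sigma_ms,
                           keep_matrix = FALSE)$mean_cc,
           rate = mean(counts) / (params$song_dur / 1000))
    })
    cc[k] <- res$cc
    rate[k] <- res$rate
  }
  list(mean_cc = mean(cc),
       se_cc = if (n_realizations > 1) sd(cc) / sqrt(n_realizations)
               else NA_real_,
       mean_rate = mean(rate), cc = cc, rate = rate)
}

.sweep_axes <- c("strengthen_and_prune", "strengthen_only", "prune_only",
                 "lman_strength", "nmda_ratio", "gain_tau_m",
                 "burstiness", "song_lock")

#' Sweep one manipulation axis of the network model
#'
#' Runs [run_point()] along a parameter grid.  The axes are the circuit
#' manipulations explored with the model:
#'
#' * `strengthen_and_prune`: grid of `rho`; `(m, s)` co-vary via
#'   [profile_at()] (the developmental axis).
#' * `strengthen_only`: `rho` fixed at 0.9 while `(m, s)` follow
#'   [profile_at()] of the grid value.
#' * `prune_only`: grid of `rho` with `(m, s)` fixed at (50, 35) pA.
#'   Both single axes are anchored at the plastic-song standard model.
#' * `lman_strength`: grid of scale factors on `W_LMAN` (paper range
#'   0.5-1.5) at standard connectivity.
#' * `nmda_ratio`: grid of AMPA fractions `r` (0-0.2, and 1 = pure AMPA).
#' * `gain_tau_m`: grid of membrane time constants (16-25 ms).
#' * `burstiness`: grid of burst fractions `b`; LMAN becomes two
#'   superposed independent 40 Hz bursty neurons.
#' * `song_lock`: grid of sine modulation depths of the 80 Hz LMAN rate.
#'
#' Tonic inhibition is recomputed from each grid point's `(m, rho)` on
#' every axis, since it is defined as proportional to the HVC drive.
#'
#' @param axis one of the axes above.
#' @param grid numeric vector of axis values.
#' @param n_realizations,n_renditions,seed,params see [run_point()].
#' @return An object of class `sweep_result`: data.frame with columns
#'   `axis_value`, `mean_cc`, `se_cc`, `mean_rate_hz`; attributes `axis`
#'   and `seed`.
#' @export
run_sweep <- function(axis, grid, n_realizations = 50L,
                      n_renditions = 200L, seed = NULL,
                      params = ra_params()) {
  axis <- match.arg(axis, .sweep_axes)
  seeds <- derive_seeds(seed, length(grid))
  base <- .profile_anchors$plastic
  rows <- lapply(seq_along(grid), function(i) {
    g <- grid[i]
    p <- params
    rho <- base[["rho"]]; m <- NULL; s <- NULL
    lman <- list(type = "poisson")
    switch(axis,
      strengthen_and_prune = { rho <- g },
      strengthen_only = { ms <- profile_at(g); m <- ms[["m"]]
                          s <- ms[["s"]] },
      prune_only = { rho <- g; m <- base[["m"]]; s <- base[["s"]] },
      lman_strength = { p$w_lman <- params$w_lman * g },
      nmda_ratio = { p$r_ampa <- g },
      gain_tau_m = { p$tau_m <- g },
      burstiness = { lman <- list(type = "bursty", b = g) },
      song_lock = { lman <- list(type = "modulated", mod_depth = g) })
    pt <- run_point(rho, m, s, lman = lman, params = p,
                    n_realizations = n_realizations,
                    n_renditions = n_renditions, seed = seeds[i])
    data.frame(axis_value = g, mean_cc = pt$mean_cc, se_cc = pt$se_cc,
               mean_rate_hz = pt$mean_rate)
  })
  out <- do.call(rbind, rows)
  attr(out, "axis") <- axis
  attr(out, "seed") <- seed
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Share of the developmental CC change explained by LMAN weakening
#'
#' Compares the CC gain obtained by halving the LMAN synaptic strength at
#' plastic-song connectivity (`rho = 0.9`) against the CC gain obtained by
#' moving from plastic-song to adult connectivity (`rho = 0.37`) at full
#' LMAN strength:
#' `100 * (CC[rho=0.9, W/2] - CC[rho=0.9, W]) /
#'        (CC[rho=0.37, W] - CC[rho=0.9, W])`.
#'
#' @param seed master seed.
#' @param n_realizations weight-vector draws per condition (default 50).
#' @param n_renditions renditions per realization (default 200).
#' @param params an [ra_params()] object.
#' @param paired reuse the same weight draws and LMAN spike trains for
#'   the standard and halved conditions (common random numbers; default
#'   TRUE).  The numerator CC difference is extremely noisy across
#'   independent weight draws because the halved condition sits near the
#'   firing threshold, and pairing removes the shared draw-to-draw
#'   variance without changing the estimand.
#' @return list with `share_pct` and the three condition CCs
#'   (`cc_standard`, `cc_halved`, `cc_adult`) plus their per-realization
#'   vectors.
#' @export
lman_weakening_share <- function(seed = NULL, n_realizations = 50L,
                                 n_renditions = 200L,
                                 params = ra_params(), paired = TRUE) {
  seeds <- derive_seeds(seed, 3L)
  half <- params
  half$w_lman <- params$w_lman / 2
  std <- run_point(0.9, lman = list(type = "poisson"), params = params,
                   n_realizations = n_realizations,
                   n_renditions = n_renditions, seed = seeds[1])
  halved <- run_point(0.9, lman = list(type = "poisson"), params = half,
                      n_realizations = n_realizations,
                      n_renditions = n_renditions,
                      seed = if (paired) seeds[1] else seeds[2])
  adult <- run_point(0.37, lman = list(type = "poisson"),
                     params = params,
                     n_realizations = n_realizations,
                     n_renditions = n_renditions, seed = seeds[3])
  denom <- adult$mean_cc - std$mean_cc
  if (!is.finite(denom) || denom <= 0)
    stop("developmental CC change is not positive; misconfigured model",
         call. = FALSE)
  list(share_pct = 100 * (halved$mean_cc - std$mean_cc) / denom,
       cc_standard = std$mean_cc, cc_halved = halved$mean_cc,
       cc_adult = adult$mean_cc,
       cc_standard_all = std$cc, cc_halved_all = halved$cc,
       cc_adult_all = adult$cc)
}
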