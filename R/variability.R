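#' Instantaneous firing rate of a spike train
#'
#' Between consecutive spikes the instantaneous rate is the reciprocal of
#' the inter-spike interval, `R(t) = 1 / (t_{k+1} - t_k)` for
#' `t_k < t < t_{k+1}`, converted to Hz.  Before the first and after the
#' last spike the rate is filled with 0 by default (`fill = "na"` marks
#' those epochs `NA` instead, used by the F-I analysis); a train with
#' fewer than two spikes yields an all-fill trace.
#'
#' @param train a `spike_train`.
#' @param grid regular time grid (ms); default 1 ms spacing over the train
#'   duration.
#' @param fill value outside the first..last spike span: `"zero"` or
#'   `"na"`.
#' @return An object of class `rate_trace`: list with `grid` (ms) and
#'   `values` (Hz).
#' @export
instantaneous_rate <- function(train,
                               grid = seq(0, train$duration, by = 1),
                               fill = c("zero", "na")) {
  fill <- match.arg(fill)
  fv <- if (fill == "zero") 0 else NA_real_
  values <- rep(fv, length(grid))
  tt <- train$times
  if (length(tt) >= 2L) {
    idx <- findInterval(grid, tt)
    inside <- idx >= 1L & idx < length(tt)
    values[inside] <- 1000 / (tt[idx[inside] + 1L] - tt[idx[inside]])
  }
  structure(list(grid = grid, values = values), class = "rate_trace")
}

#' Gaussian smoothing of a rate trace
#'
#' Convolves the trace with a unit-area Gaussian kernel (default
#' `sigma = 10` ms), truncated at 4 sigma.  Edges are handled by kernel
#' renormalization (dividing by the in-range kernel mass), which preserves
#' a constant trace exactly.
#'
#' @param trace a `rate_trace` on a regular grid.
#' @param sigma_ms kernel standard deviation (ms), > 0.
#' @return A smoothed `rate_trace`.
#' @export
smooth_rate <- function(trace, sigma_ms = 10) {
  if (!is.finite(sigma_ms) || sigma_ms <= 0)
    stop("sigma_ms must be positive", call. = FALSE)
  g <- trace$grid
  step <- diff(g)
  if (length(step) && max(abs(step - step[1])) > 1e-9 * step[1])
    stop("smooth_rate requires a regular grid", call. = FALSE)
  dt <- if (length(step)) step[1] else 1
  trace$values <- gauss_smooth(matrix(trace$values, ncol = 1),
                               sigma_ms / dt)[, 1]
  trace
}

# column-wise Gaussian smoothing of a matrix (rows = time), sigma in grid
# units, truncated at 4 sigma, edge-renormalized
gauss_smooth <- function(x, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  n <- nrow(x)
  pad <- matrix(0, half, ncol(x))
  num <- stats::filter(rbind(pad, x, pad), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k,
                       sides = 2)
  keep <- (half + 1):(half + n)
  sm <- as.matrix(num[keep, , drop = FALSE]) / den[keep]
  dimnames(sm) <- NULL
  sm
}

#' Rendition-to-rendition firing-rate correlation (CC)
#'
#' The variability measure of the model: each rendition's spike train is
#' converted to an instantaneous firing rate, smoothed with a 10 ms
#' Gaussian, and mean-subtracted; `CC_ij` is the Pearson correlation of
#' the resulting traces of renditions i and j over the song, and the
#' summary CC is the average over all off-diagonal pairs.  High CC means
#' reproducible, low-variability firing.  A rendition whose smoothed trace
#' has zero variance (e.g. no spikes) contributes 0 to its pairs and is
#' flagged.
#'
#' @param renditions list of `spike_train`s of equal duration (N >= 2).
#' @param grid regular time grid (ms); default 1 ms over the duration.
#' @param sigma_ms Gaussian smoothing width (ms, default 10).
#' @param keep_matrix return the full pairwise matrix (default TRUE).
#' @return An object of class `cc_result`: list with `mean_cc`,
#'   `n_renditions`, `matrix` (optional) and `degenerate` (indices of
#'   zero-variance renditions).
#' @export
cc_average <- function(renditions,
                       grid = seq(0, renditions[[1]]$duration, by = 1),
                       sigma_ms = 10, keep_matrix = TRUE) {
  n <- length(renditions)
  if (n < 2L) stop("need at least 2 renditions", call. = FALSE)
  durs <- vapply(renditions, `[[`, numeric(1), "duration")
  if (length(unique(durs)) != 1L)
    stop("renditions must have equal duration", call. = FALSE)
  raw <- vapply(renditions, function(tr)
    instantaneous_rate(tr, grid)$values, numeric(length(grid)))
  step <- if (length(grid) > 1) grid[2] - grid[1] else 1
  sm <- gauss_smooth(raw, sigma_ms / step)
  sm <- sweep(sm, 2, colMeans(sm))
  degenerate <- which(apply(sm, 2, function(v) all(abs(v) < 1e-12)))
  cc <- matrix(0, n, n)
  ok <- setdiff(seq_len(n), degenerate)
  if (length(ok) >= 2L) cc[ok, ok] <- cor(sm[, ok, drop = FALSE])
  diag(cc) <- 1
  structure(list(mean_cc = mean(cc[upper.tri(cc)]),
                 n_renditions = n,
                 matrix = if (keep_matrix) cc,
                 degenerate = degenerate),
            class = "cc_result")
}

#' @export
print.cc_result <- function(x, ...) {
  cat(sprintf("mean pairwise CC = %.4f over %d renditions", x$mean_cc,
              x$n_renditions))
  if (length(x$degenerate))
    cat(sprintf(" (%d degenerate)", length(x$degenerate)))
  cat("\n")
  invisible(x)
}
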