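#' Read and write spike trains as CSV
#'
#' Spike tables use two columns, `source` and `time_ms`; several trains
#' (e.g. a whole HVC raster) share one file.
#'
#' @param trains a `spike_train` or list of them.
#' @param path file path.
#' @return `write_spikes_csv` returns `path` invisibly;
#'   `read_spikes_csv` returns a list of `spike_train`s.
#' @export
write_spikes_csv <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr)
    data.frame(source = as.character(tr$source),
               time_ms = tr$times,
               duration_ms = tr$duration)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$source <- as.character(df$source)
  lapply(split(df, df$source), function(d)
    spike_train(d$time_ms, d$duration_ms[1], source = d$source[1]))
}

#' Read and write a realized connectivity profile as CSV
#'
#' Weight vectors are serialized with columns `hvc_index` and
#' `weight_pA`; the profile's `(rho, m, s)` travel as attributes encoded
#' in a comment-free extra row-less header convention is avoided - they
#' are re-derivable, so only the realized weights are stored and `rho` is
#' recovered from the zero pattern.
#'
#' @param profile a `connectivity_profile`.
#' @param path file path.
#' @return `write_weights_csv` returns `path` invisibly;
#'   `read_weights_csv` returns a `connectivity_profile` whose `(m, s)`
#'   are the realized moments of the nonzero weights.
#' @export
write_weights_csv <- function(profile, path) {
  write.csv(data.frame(hvc_index = seq_along(profile$weights),
                       weight_pA = profile$weights),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(path) {
  df <- read.csv(path)
  w <- df$weight_pA[order(df$hvc_index)]
  act <- w[w > 0]
  structure(list(rho = length(act) / length(w), m = mean(act),
                 s = if (length(act) > 1) sd(act) else 0, weights = w),
            class = "connectivity_profile")
}

#' Read and write a log-normal fit as JSON
#'
#' @param fit a `lognormal_fit`.
#' @param path file path.
#' @return `write_fit_json` returns `path` invisibly; `read_fit_json`
#'   returns a `lognormal_fit`.
#' @export
write_fit_json <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON export", call. = FALSE)
  jsonlite::write_json(list(mu = fit$mu, sigma = fit$sigma, n = fit$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON import", call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mu = x$mu, sigma = x$sigma, n = as.integer(x$n)),
            class = "lognormal_fit")
}
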