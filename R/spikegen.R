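#' Construct a spike train
#'
#' @param times numeric vector of event times (ms); will be sorted.
#' @param duration total duration (ms); all times must lie in
#'   `[0, duration]`.
#' @param source label for the emitting source (e.g. an HVC neuron index,
#'   `"LMAN"`, `"RA"`).
#' @return An object of class `spike_train`: list with `times`, `duration`,
#'   `source`.
#' @export
spike_train <- function(times, duration, source = NA_character_) {
  times <- sort(as.numeric(times))
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (length(times) && (times[1] < 0 || times[length(times)] > duration))
    stop("spike times must lie in [0, duration]", call. = FALSE)
  structure(list(times = times, duration = duration, source = source),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train [%s]: %d spikes in %g ms (%.1f Hz)\n",
              as.character(x$source), length(x$times), x$duration,
              1000 * length(x$times) / x$duration))
  invisible(x)
}

#' Superpose spike trains
#'
#' Merges the events of several spike trains of equal duration into one
#' train, e.g. to pool two LMAN neurons converging on the same RA neuron.
#'
#' @param ... `spike_train` objects, or a single list of them.
#' @param source label for the merged train.
#' @return A `spike_train`.
#' @export
merge_trains <- function(..., source = "merged") {
  trains <- list(...)
  if (length(trains) == 1L && !inherits(trains[[1]], "spike_train"))
    trains <- trains[[1]]
  durs <- vapply(trains, `[[`, numeric(1), "duration")
  if (length(unique(durs)) != 1L)
    stop("all trains must have the same duration", call. = FALSE)
  spike_train(unlist(lapply(trains, `[[`, "times")), durs[1], source)
}

#' HVC time-keeper raster
#'
#' Each of the `n_hvc` premotor time-keeper neurons fires a single
#' stereotyped burst per song rendition: five spikes 2 ms apart, with the
#' burst of neuron *i* (1-based) starting at `(i - 1) * 10` ms, so the
#' bursts tile the song regularly and without overlap.  The raster is
#' deterministic - identical on every rendition.
#'
#' @param n_hvc number of HVC neurons (default 100).
#' @param song_dur song duration (ms); must equal `n_hvc * 10`.
#' @return A list of `n_hvc` `spike_train` objects.
#' @export
hvc_song <- function(n_hvc = 100L, song_dur = n_hvc * 10) {
  n_hvc <- as.integer(n_hvc)
  if (n_hvc < 1L) stop("n_hvc must be >= 1", call. = FALSE)
  if (!isTRUE(all.equal(song_dur, n_hvc * 10)))
    stop("song_dur must equal n_hvc * 10 ms (regular tiling)",
         call. = FALSE)
  lapply(seq_len(n_hvc), function(i)
    spike_train((i - 1) * 10 + c(0, 2, 4, 6, 8), song_dur, source = i))
}

#' Homogeneous Poisson LMAN spike train
#'
#' The default model of LMAN input to RA: the two afferent LMAN neurons,
#' each firing near 40 Hz, are merged into a single homogeneous Poisson
#' process at 80 Hz.
#'
#' @param rate firing rate (Hz), >= 0.
#' @param duration train duration (ms).
#' @param seed optional integer seed.
#' @return A `spike_train` with source `"LMAN"`.
#' @export
lman_poisson <- function(rate = 80, duration = 1000, seed = NULL) {
  if (!is.finite(rate) || rate < 0)
    stop("rate must be non-negative", call. = FALSE)
  with_opt_seed(seed, {
    n <- rpois(1L, rate * duration / 1000)
    spike_train(runif(n, 0, duration), duration, source = "LMAN")
  })
}

#' Bursty LMAN spike train at a fixed mean rate
#'
#' Models burstiness in a single LMAN neuron while holding its mean rate
#' fixed: a tonic Poisson train at `rate * (1 - b)` Hz is superposed with
#' Poisson-timed burst events at `rate * b / spikes_per_burst` Hz (8b Hz at
#' the 40 Hz default), each burst a stereotyped run of `spikes_per_burst`
#' spikes `intra_isi` ms apart.  Spikes of a burst starting near the end of
#' the train that would fall beyond `duration` are dropped.
#'
#' @param rate per-neuron mean rate (Hz, default 40).
#' @param b fraction of spikes occurring within bursts, in \[0, 1\].
#' @param duration train duration (ms).
#' @param spikes_per_burst spikes per burst event (default 5).
#' @param intra_isi within-burst inter-spike interval (ms, default 2).
#' @param seed optional integer seed.
#' @return A `spike_train` with source `"LMAN"`.
#' @export
lman_bursty <- function(rate = 40, b = 0, duration = 1000,
                        spikes_per_burst = 5L, intra_isi = 2,
                        seed = NULL) {
  if (!is.finite(b) || b < 0 || b > 1)
    stop("b must lie in [0, 1]", call. = FALSE)
  if (!is.finite(rate) || rate < 0)
    stop("rate must be non-negative", call. = FALSE)
  with_opt_seed(seed, {
    n_tonic <- rpois(1L, rate * (1 - b) * duration / 1000)
    tonic <- runif(n_tonic, 0, duration)
    n_burst <- rpois(1L, rate * b / spikes_per_burst * duration / 1000)
    onsets <- runif(n_burst, 0, duration)
    burst <- rep(onsets, each = spikes_per_burst) +
      rep(intra_isi * (seq_len(spikes_per_burst) - 1), times = n_burst)
    spike_train(c(tonic, burst[burst <= duration]), duration,
                source = "LMAN")
  })
}

#' Sinusoidally rate-modulated (song-locked) LMAN spike train
#'
#' Inhomogeneous Poisson train with rate profile
#' `lambda(t) = rate * (1 + mod_depth * sin(2 pi t / duration))` - a single
#' sine period spanning the song, phase 0.  Because the sine integrates to
#' zero over one period, the expected spike count equals `rate * duration`
#' for every modulation depth.  Sampled by thinning.
#'
#' @param rate baseline rate (Hz).
#' @param mod_depth fractional modulation depth, in \[0, 1).
#' @param duration train duration (ms).
#' @param seed optional integer seed.
#' @return A `spike_train` with source `"LMAN"`.
#' @export
lman_modulated <- function(rate = 80, mod_depth = 0, duration = 1000,
                           seed = NULL) {
  if (!is.finite(mod_depth) || mod_depth < 0 || mod_depth >= 1)
    stop("mod_depth must lie in [0, 1)", call. = FALSE)
  if (!is.finite(rate) || rate < 0)
    stop("rate must be non-negative", call. = FALSE)
  with_opt_seed(seed, {
    lambda_max <- rate * (1 + mod_depth)
    n_cand <- rpois(1L, lambda_max * duration / 1000)
    cand <- runif(n_cand, 0, duration)
    lam <- rate * (1 + mod_depth * sin(2 * pi * cand / duration))
    keep <- runif(n_cand) * lambda_max < lam
    spike_train(cand[keep], duration, source = "LMAN")
  })
}

#' Generate one LMAN input per the standard or a modified firing pattern
#'
#' Convenience dispatcher used by the sweep machinery.  `type = "poisson"`
#' gives the standard merged 80 Hz process; `type = "bursty"` superposes
#' two independent bursty 40 Hz neurons (the per-neuron rate stays fixed
#' while burstiness varies); `type = "modulated"` gives the song-locked
#' 80 Hz process.
#'
#' @param type one of `"poisson"`, `"bursty"`, `"modulated"`.
#' @param duration train duration (ms).
#' @param rate total rate in Hz for `"poisson"`/`"modulated"` (default 80),
#'   per-neuron rate for `"bursty"` (default 40, two neurons).
#' @param b burst fraction (bursty only).
#' @param mod_depth sine modulation depth (modulated only).
#' @param seed optional integer seed.
#' @return A `spike_train`.
#' @export
lman_input <- function(type = c("poisson", "bursty", "modulated"),
                       duration = 1000, rate = NULL, b = 0,
                       mod_depth = 0, seed = NULL) {
  type <- match.arg(type)
  with_opt_seed(seed, switch(type,
    poisson = lman_poisson(if (is.null(rate)) 80 else rate, duration),
    bursty = merge_trains(
      lman_bursty(if (is.null(rate)) 40 else rate, b, duration),
      lman_bursty(if (is.null(rate)) 40 else rate, b, duration),
      source = "LMAN"),
    modulated = lman_modulated(if (is.null(rate)) 80 else rate,
                               mod_depth, duration)
  ))
}
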