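#' Hilbert-envelope HFO detector parameters
#'
#' Candidate events are maximal runs where the analytic-signal envelope of
#' the band-passed trace exceeds `mean + threshold_sd * SD` of the envelope
#' (or `median + threshold_sd * MAD_normalized` with `stat = "median"`).
#' Runs closer than `merge_gap` ms are merged; candidates shorter than
#' `min_duration` ms or with fewer than `min_oscillations` oscillations are
#' discarded. Oscillations are counted as rectified-signal peaks above half
#' the event's envelope maximum, over the event's half-maximum envelope
#' extent, minus one peak as an allowance for the roughly one cycle of
#' envelope widening the band-pass filter introduces. Envelope statistics
#' are computed on the whole analyzed segment.
#'
#' @param band `(low, high)` in Hz: `c(80, 250)` for ripples,
#'   `c(250, 500)` for fast ripples.
#' @param threshold_sd Envelope threshold in SD above the mean (default 5).
#' @param min_oscillations Minimum rectified-peak count (default 4).
#' @param min_duration Minimum event duration, ms (default 6).
#' @param merge_gap Runs closer than this are merged, ms (default 10).
#' @param stat `"mean"` (mean/SD, default) or `"median"` (median/MAD).
#' @return A list of class `sr_hfo_params`.
#' @export
hfo_params <- function(band = c(80, 250), threshold_sd = 5,
                       min_oscillations = 4, min_duration = 6,
                       merge_gap = 10, stat = c("mean", "median")) {
  if (band[1] <= 0 || band[1] >= band[2]) abort("invalid band.")
  if (min_oscillations < 1) abort("min_oscillations must be >= 1.")
  structure(list(band = band, threshold_sd = threshold_sd,
                 min_oscillations = min_oscillations,
                 min_duration = min_duration, merge_gap = merge_gap,
                 stat = match.arg(stat)),
            class = "sr_hfo_params")
}

#' Detect HFOs on a single channel
#'
#' @param x Numeric signal vector (raw, unfiltered).
#' @param sampling_rate Hz; must be at least `2 * band[2]`.
#' @param params An [hfo_params()] object.
#' @param channel_id Channel identifier stored on the events.
#' @param keep_rejected Keep candidates failing the duration/oscillation
#'   screens, marked `rejected_short` (default `FALSE`).
#' @return Event tibble (possibly empty) with `peak_time` at the envelope
#'   maximum, `peak_frequency` (maximal in-band spectral power) and
#'   `n_oscillations`.
#' @export
detect_hfo_channel <- function(x, sampling_rate, params = hfo_params(),
                               channel_id = "CH", keep_rejected = FALSE) {
  stopifnot(inherits(params, "sr_hfo_params"))
  if (sampling_rate < 2 * params$band[2]) {
    abort("sampling rate below twice the band's upper edge.")
  }
  if (length(x) < sampling_rate) {
    abort("segment shorter than 1 s: insufficient baseline for envelope statistics.")
  }
  xf <- bandpass(x, params$band, sampling_rate)
  env <- hilbert_envelope(xf)
  thr <- if (params$stat == "mean") {
    mean(env) + params$threshold_sd * stats::sd(env)
  } else {
    median(env) + params$threshold_sd * mad(env)
  }
  runs <- runs_above(env > thr)
  if (nrow(runs) == 0L) return(empty_events())
  gap <- params$merge_gap / 1000 * sampling_rate
  runs <- merge_runs(runs, gap)
  out <- purrr::map_dfr(seq_len(nrow(runs)), function(k) {
    i0 <- runs$start[k]; i1 <- runs$end[k]
    seg_env <- env[i0:i1]
    # oscillations are counted over the half-maximum envelope extent of the
    # event (capped at 200 ms), not just the supra-threshold run: the
    # counting region then spans the visible burst
    half <- max(seg_env) / 2
    cap <- round(0.2 * sampling_rate)
    e0 <- i0; while (e0 > 1L && env[e0 - 1L] > half && i0 - e0 < cap) e0 <- e0 - 1L
    e1 <- i1; while (e1 < length(env) && env[e1 + 1L] > half && e1 - i1 < cap) e1 <- e1 + 1L
    # band-pass filtering widens a burst's half-max envelope by about one
    # cycle, so one counted peak is a smearing artifact: subtract it
    n_osc <- max(0L, count_oscillations(xf[e0:e1], max(seg_env)) - 1L)
    dur_ms <- (i1 - i0 + 1L) / sampling_rate * 1000
    ok <- dur_ms >= params$min_duration && n_osc >= params$min_oscillations
    if (!ok && !keep_rejected) return(NULL)
    pk <- i0 + which.max(seg_env) - 1L
    tibble(
      channel_id = channel_id,
      onset = (i0 - 1L) / sampling_rate,
      offset = i1 / sampling_rate,
      peak_time = (pk - 1L) / sampling_rate,
      event_type = if (params$band[1] >= 250) "fast_ripple" else "ripple",
      peak_frequency = peak_frequency(xf[i0:i1], sampling_rate, params$band),
      n_oscillations = n_osc,
      qc_status = if (ok) NA_character_ else "rejected_short"
    )
  })
  if (nrow(out) == 0L) empty_events() else validate_events(out)
}

runs_above <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], end = ends[r$values])
}

merge_runs <- function(runs, gap_samples) {
  if (nrow(runs) <= 1L) return(runs)
  start <- runs$start[1]; end <- runs$end[1]
  out_s <- integer(); out_e <- integer()
  for (k in 2:nrow(runs)) {
    if (runs$start[k] - end <= gap_samples) {
      end <- runs$end[k]
    } else {
      out_s <- c(out_s, start); out_e <- c(out_e, end)
      start <- runs$start[k]; end <- runs$end[k]
    }
  }
  tibble(start = c(out_s, start), end = c(out_e, end))
}

# rectified-signal peaks above half the event's envelope maximum
count_oscillations <- function(seg, env_max) {
  a <- abs(seg)
  n <- length(a)
  if (n < 3L) return(0L)
  pk <- which(a[2:(n - 1L)] > a[1:(n - 2L)] & a[2:(n - 1L)] >= a[3:n]) + 1L
  sum(a[pk] > env_max / 2)
}

peak_frequency <- function(seg, fs, band) {
  n <- max(length(seg), 256L)
  spec <- Mod(fft(c(seg * signal::hanning(length(seg)),
                    rep(0, n - length(seg)))))^2
  freqs <- (seq_len(n) - 1L) * fs / n
  in_band <- freqs >= band[1] & freqs <= band[2]
  freqs[in_band][which.max(spec[in_band])]
}

#' Detect and QC HFOs over a whole recording
#'
#' Runs [detect_hfo_channel()] on every channel for the given band and
#' applies [qc_hfo()]; by default only accepted events are returned.
#'
#' @param recording An [new_recording()] object.
#' @param params An [hfo_params()] object.
#' @param qc Apply automated quality control (default `TRUE`).
#' @param keep_rejected Return rejected events too, with their
#'   `qc_status` reason (default `FALSE`).
#' @return Event tibble.
#' @export
detect_hfo <- function(recording, params = hfo_params(), qc = TRUE,
                       keep_rejected = FALSE) {
  stopifnot(inherits(recording, "sr_recording"))
  ev <- purrr::map_dfr(seq_along(recording$channel_ids), function(i) {
    detect_hfo_channel(recording$signal[i, ], recording$sampling_rate,
                       params, channel_id = recording$channel_ids[i])
  })
  if (nrow(ev) == 0L) return(empty_events())
  if (qc) {
    ev <- qc_hfo(ev, recording, params$band)
    if (!keep_rejected) ev <- ev[ev$qc_status == "accepted", ]
  } else {
    ev$qc_status <- "accepted"
  }
  validate_events(ev)
}
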