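#' Stand-in interictal spike detector
#'
#' A transparent amplitude/slope detector intended as a reproducible
#' stand-in for commercial spike-detection software; it is **not**
#' equivalent to such software and users with trusted external annotations
#' should import them with [read_event_table()] instead. On the preprocessed
#' signal ([preprocess_for_spikes()]) it computes per-channel robust z-scores
#' of the rectified amplitude and of the rectified first derivative; samples
#' where the average of the two exceeds `z_threshold` seed candidates,
#' candidates within `refractory` ms merge, and event extents are clamped to
#' 20-200 ms around the amplitude peak.
#'
#' @param z_threshold Composite robust z threshold (default 5, matching the
#'   5-SD convention of the HFO detector).
#' @param refractory Merge window in ms (default 200).
#' @return `spike_params()` returns a list of class `sr_spike_params`.
#' @export
spike_params <- function(z_threshold = 5, refractory = 200) {
  structure(list(z_threshold = z_threshold, refractory = refractory),
            class = "sr_spike_params")
}

#' @rdname spike_params
#' @param recording A preprocessed [new_recording()].
#' @param params A `spike_params()` object.
#' @return `detect_spikes_standin()` returns an event tibble of spikes.
#' @export
detect_spikes_standin <- function(recording, params = spike_params()) {
  stopifnot(inherits(recording, "sr_recording"))
  fs <- recording$sampling_rate
  refr <- params$refractory / 1000 * fs
  min_half <- round(0.010 * fs)   # half of the 20 ms floor
  max_half <- round(0.100 * fs)   # half of the 200 ms cap
  out <- purrr::map_dfr(seq_along(recording$channel_ids), function(i) {
    x <- recording$signal[i, ]
    za <- robust_z(abs(x))
    zs <- robust_z(c(abs(diff(x)), 0))
    comp <- (za + zs) / 2
    runs <- runs_above(comp > params$z_threshold)
    if (nrow(runs) == 0L) return(NULL)
    runs <- merge_runs(runs, refr)
    purrr::map_dfr(seq_len(nrow(runs)), function(k) {
      i0 <- runs$start[k]; i1 <- runs$end[k]
      pk <- i0 + which.max(abs(x[i0:i1])) - 1L
      half <- max(min_half, min(max_half, ceiling((i1 - i0 + 1L) / 2)))
      a <- max(1L, pk - half); b <- min(length(x), pk + half)
      tibble(channel_id = recording$channel_ids[i],
             onset = (a - 1L) / fs, offset = b / fs,
             peak_time = (pk - 1L) / fs, event_type = "spike",
             peak_frequency = NA_real_, n_oscillations = NA_integer_,
             qc_status = "accepted")
    })
  })
  if (nrow(out) == 0L) return(empty_events())
  validate_events(out)
}

robust_z <- function(v) {
  m <- median(v)
  s <- max(mad(v), 1e-12)
  (v - m) / s
}

#' Match detected events against reference annotations
#'
#' Greedy one-to-one matching by nearest `peak_time` on the same channel,
#' within `tolerance` ms. Sensitivity = matches / |reference|; precision =
#' matches / |detected|.
#'
#' @param detected,reference Event tibbles.
#' @param tolerance Matching tolerance in ms (default 100 for spikes; 50 is
#'   conventional for HFOs).
#' @return List with `sensitivity`, `precision`, `n_matched` and a `matches`
#'   tibble of paired peak times.
#' @export
match_events <- function(detected, reference, tolerance = 100) {
  if (tolerance < 0) abort("`tolerance` must be >= 0.")
  detected <- validate_events(empty_events_if_null(detected))
  reference <- validate_events(empty_events_if_null(reference))
  tol <- tolerance / 1000
  matches <- list()
  for (ch in unique(reference$channel_id)) {
    d <- detected[detected$channel_id == ch, ]
    r <- reference[reference$channel_id == ch, ]
    if (nrow(d) == 0L || nrow(r) == 0L) next
    pairs <- expand.grid(di = seq_len(nrow(d)), ri = seq_len(nrow(r)))
    pairs$dt <- abs(d$peak_time[pairs$di] - r$peak_time[pairs$ri])
    pairs <- pairs[pairs$dt <= tol, ]
    pairs <- pairs[order(pairs$dt), ]
    used_d <- logical(nrow(d)); used_r <- logical(nrow(r))
    for (j in seq_len(nrow(pairs))) {
      di <- pairs$di[j]; ri <- pairs$ri[j]
      if (!used_d[di] && !used_r[ri]) {
        used_d[di] <- TRUE; used_r[ri] <- TRUE
        matches[[length(matches) + 1L]] <-
          tibble(channel_id = ch, detected_peak = d$peak_time[di],
                 reference_peak = r$peak_time[ri], dt = pairs$dt[j])
      }
    }
  }
  matches <- if (length(matches)) bind_rows(matches) else
    tibble(channel_id = character(), detected_peak = double(),
           reference_peak = double(), dt = double())
  n_m <- nrow(matches)
  list(
    sensitivity = if (nrow(reference)) n_m / nrow(reference) else NA_real_,
    precision = if (nrow(detected)) n_m / nrow(detected) else NA_real_,
    n_matched = n_m,
    matches = matches
  )
}
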