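#' Automated quality control of detected HFOs
#'
#' Mirrors expert visual review of candidate HFOs. An event is accepted iff
#' it satisfies the island or oscillation criterion and is not a filtered
#' sharp transient:
#'
#' * island test: the event's in-band power spectrum has a local maximum
#'   strictly interior to the band whose power exceeds `island_ratio` times
#'   the power at the band edges (an isolated time-frequency peak);
#' * oscillation criterion: at least four oscillation peaks in the filtered
#'   signal;
#' * Gibbs test (rejection): the unfiltered segment contains a sharp
#'   transient (maximum absolute first difference more than `sharp_z` robust
#'   z-units above the channel's typical slope) while the filtered event has
#'   fewer than four oscillations -- the signature of filter ringing.
#'
#' Rejected events are labelled `rejected_gibbs` when a sharp transient is
#' present and the in-band spectrum is concentrated at the low band edge (the
#' signature of a filtered step/spike), and `rejected_blob` otherwise (an
#' "elongated blob" in the time-frequency plane).
#'
#' @param events Event tibble from [detect_hfo_channel()].
#' @param recording The raw (unfiltered) [new_recording()].
#' @param band The detection band `(low, high)` in Hz.
#' @param island_ratio Required interior-peak to band-edge power ratio
#'   (default 2).
#' @param sharp_z Robust z threshold on the first difference (default 8).
#' @param pad Context around the event used for the spectrum, seconds
#'   (default 0.05).
#' @return `events` with `qc_status` filled in
#'   (`accepted`/`rejected_blob`/`rejected_gibbs`).
#' @export
qc_hfo <- function(events, recording, band, island_ratio = 2, sharp_z = 8,
                   pad = 0.05) {
  stopifnot(inherits(recording, "sr_recording"))
  events <- validate_events(events)
  if (nrow(events) == 0L) return(events)
  fs <- recording$sampling_rate
  # channel-wide robust slope statistics for the sharp-transient test
  slope_stats <- lapply(seq_along(recording$channel_ids), function(i) {
    d <- abs(diff(recording$signal[i, ]))
    c(med = median(d), mad = max(mad(d), 1e-12))
  })
  names(slope_stats) <- recording$channel_ids
  status <- character(nrow(events))
  for (k in seq_len(nrow(events))) {
    ci <- match(events$channel_id[k], recording$channel_ids)
    x <- recording$signal[ci, ]
    i0 <- max(1L, round(events$onset[k] * fs) + 1L - round(pad * fs))
    i1 <- min(length(x), round(events$offset[k] * fs) + round(pad * fs))
    seg <- x[i0:i1]
    ss <- slope_stats[[events$channel_id[k]]]
    sharp <- max(abs(diff(seg))) > ss["med"] + sharp_z * 1.4826 * ss["mad"]
    sp <- band_spectrum(seg, fs, band)
    interior <- island_test(sp, island_ratio)
    n_osc <- events$n_oscillations[k]
    if (is.na(n_osc)) n_osc <- 0L
    gibbs <- sharp && n_osc < 4
    if (!gibbs && (interior || n_osc >= 4)) {
      status[k] <- "accepted"
    } else if (sharp && edge_tilt(sp) > 4) {
      # low-band-edge-concentrated spectrum + sharp transient: filter ringing
      status[k] <- "rejected_gibbs"
    } else {
      status[k] <- "rejected_blob"
    }
  }
  events$qc_status <- status
  events
}

band_spectrum <- function(seg, fs, band) {
  n <- max(2L * length(seg), 512L)
  w <- seg * signal::hanning(length(seg))
  p <- Mod(fft(c(w, rep(0, n - length(w)))))^2
  freqs <- (seq_len(n) - 1L) * fs / n
  keep <- freqs >= band[1] & freqs <= band[2]
  list(freq = freqs[keep], power = p[keep])
}

island_test <- function(sp, island_ratio) {
  p <- sp$power
  m <- length(p)
  if (m < 5L) return(FALSE)
  imax <- which.max(p)
  interior <- imax > 2L && imax < m - 1L
  edge <- max(p[1], p[m])
  interior && p[imax] > island_ratio * edge
}

spectral_flatness <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  exp(mean(log(p))) / mean(p)
}

# power in the lowest quarter of the band over the highest quarter; a
# filtered step/sharp transient tilts strongly toward the low edge, while a
# broadband click is near 1
edge_tilt <- function(sp) {
  m <- length(sp$power)
  lo <- sp$power[seq_len(max(1L, m %/% 4))]
  hi <- sp$power[(m - max(1L, m %/% 4) + 1L):m]
  mean(lo) / max(mean(hi), 1e-300)
}
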