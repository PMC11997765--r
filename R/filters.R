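#' Zero-phase band-pass filter
#'
#' Linear-phase FIR (Hamming-windowed, [signal::fir1()]) applied forward and
#' backward with [signal::filtfilt()], so the net response is zero-phase and
#' event times are not shifted.
#'
#' @param x Numeric vector (one channel).
#' @param band Length-2 numeric, `(low, high)` in Hz; must lie below Nyquist.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_taps FIR order (default 256; transition width about
#'   `3.3 * sampling_rate / n_taps` Hz).
#' @return Filtered vector, same length as `x`.
#' @export
bandpass <- function(x, band, sampling_rate, n_taps = 256) {
  nyq <- sampling_rate / 2
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    abort("`band` must be (low, high) with 0 < low < high.")
  }
  if (band[2] > nyq) abort("band extends to or beyond the Nyquist frequency.")
  w <- pmin(band / nyq, 0.999)
  # filtfilt needs ~3x the filter length of data; shrink the order for short
  # segments rather than refuse them
  n_taps <- min(n_taps, 2L * ((length(x) - 4L) %/% 6L))
  if (n_taps < 16L) abort("segment too short to band-pass filter.")
  b <- signal::fir1(n_taps, w, type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

# zero-phase Butterworth band-stop (used for the 60 Hz notch)
notch_filter <- function(x, freq, sampling_rate, width = 2, order = 4) {
  nyq <- sampling_rate / 2
  bf <- signal::butter(order, c(freq - width, freq + width) / nyq,
                       type = "stop")
  as.numeric(signal::filtfilt(bf, x))
}

# zero-phase Butterworth band-pass (wide bands with very low edges, where an
# FIR of practical order cannot realize the transition)
butter_bandpass <- function(x, band, sampling_rate, order = 4) {
  nyq <- sampling_rate / 2
  bf <- signal::butter(order, pmin(band / nyq, 0.999), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Preprocess a recording for spike detection
#'
#' Common average reference (per-sample mean across channels subtracted),
#' DC removal, zero-phase band-pass 1-70 Hz and a zero-phase 60 Hz notch.
#'
#' @param recording An [new_recording()] object with at least two channels
#'   (unless `car = FALSE`).
#' @param bandpass_band Pass band in Hz (default `c(1, 70)`).
#' @param notch Notch frequency in Hz (default 60; `NULL` disables).
#' @param car Apply the common average reference (default `TRUE`).
#' @return A preprocessed `sr_recording`.
#' @export
preprocess_for_spikes <- function(recording, bandpass_band = c(1, 70),
                                  notch = 60, car = TRUE) {
  stopifnot(inherits(recording, "sr_recording"))
  fs <- recording$sampling_rate
  if (fs <= 2 * bandpass_band[2]) {
    abort("sampling rate too low for the spike band.")
  }
  sig <- recording$signal
  if (car) {
    if (nrow(sig) < 2L) {
      abort("common average reference needs >= 2 channels (set car = FALSE).")
    }
    sig <- sweep(sig, 2L, colMeans(sig))
  }
  sig <- sig - rowMeans(sig)
  out <- t(apply(sig, 1L, function(ch) {
    y <- butter_bandpass(ch, bandpass_band, fs)
    if (!is.null(notch) && notch < fs / 2) y <- notch_filter(y, notch, fs)
    y
  }))
  out <- out - rowMeans(out)  # filter edge transients leave a tiny offset
  new_recording(out, fs, recording$channel_ids, recording$start_time)
}

# analytic-signal envelope via the FFT (Marple construction)
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}
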