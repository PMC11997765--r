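#' Synthetic interictal background
#'
#' Channels of independent 1/f^alpha noise, generated by shaping the spectrum
#' of white Gaussian noise in the frequency domain and rescaling each channel
#' to the target RMS. `alpha = 0` gives white noise; `alpha = 1` the pink
#' background typical of iEEG.
#'
#' @param n_channels Number of channels.
#' @param duration Duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param alpha Spectral exponent (>= 0).
#' @param rms Target per-channel RMS in microvolts.
#' @param seed Integer seed; identical seeds give identical signals.
#' @param channel_ids Optional channel identifiers.
#' @return An [new_recording()] object.
#' @export
synth_background <- function(n_channels, duration, sampling_rate,
                             alpha = 1, rms = 20, seed,
                             channel_ids = NULL) {
  if (alpha < 0) abort("`alpha` must be >= 0.")
  if (duration <= 0 || sampling_rate <= 0) {
    abort("duration and sampling_rate must be positive.")
  }
  n <- round(duration * sampling_rate)
  channel_ids <- channel_ids %||% sprintf("CH%02d", seq_len(n_channels))
  sig <- withr::with_seed(seed, {
    t(vapply(seq_len(n_channels), function(i) {
      one_over_f(n, sampling_rate, alpha, rms)
    }, numeric(n)))
  })
  new_recording(sig, sampling_rate, channel_ids)
}

one_over_f <- function(n, fs, alpha, rms) {
  white <- rnorm(n)
  if (alpha == 0) return(white * rms / stats::sd(white))
  X <- fft(white)
  freqs <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]
  # leave DC at zero; roll off above a 0.5 Hz knee to keep variance finite
  shape <- c(0, pmax(freqs[-1], 0.5)^(-alpha / 2))
  x <- Re(fft(X * shape, inverse = TRUE) / n)
  x <- x - mean(x)
  x * rms / sqrt(mean(x^2))
}

#' Synthetic event waveforms
#'
#' Ripples and fast ripples are Hann-windowed sinusoids of `n_cycles / f0`
#' seconds; spikes are biphasic sharp transients of about 60 ms. Waveforms
#' are normalized so the peak absolute amplitude equals `amplitude`. These
#' shapes concentrate their energy in the band of their class (ripple
#' 80-250 Hz, fast ripple 250-500 Hz, spike below 70 Hz) and show an
#' isolated peak in the time-frequency plane, as a detector expects.
#'
#' @param event_type One of `"spike"`, `"ripple"`, `"fast_ripple"`.
#' @param f0 Oscillation frequency in Hz (HFOs only; ripple 80-250, fast
#'   ripple 250-500).
#' @param n_cycles Number of oscillation cycles (>= 4; HFOs only).
#' @param amplitude Peak amplitude in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param spike_duration Spike width in seconds (0.05-0.07).
#' @return Numeric vector with the sampled waveform.
#' @export
synth_event_waveform <- function(event_type, f0 = NULL, n_cycles = 8,
                                 amplitude = 100, sampling_rate = 2000,
                                 spike_duration = 0.06) {
  event_type <- match.arg(event_type, event_types())
  if (event_type == "spike") {
    if (spike_duration < 0.05 || spike_duration > 0.07) {
      abort("`spike_duration` must be within 0.05-0.07 s.")
    }
    n <- round(spike_duration * sampling_rate)
    u <- seq(0, 1, length.out = n)
    # one biphasic cycle under a Hann window: sharp rise-fall-undershoot
    w <- sin(2 * pi * u) * 0.5 * (1 - cos(2 * pi * u))
  } else {
    lims <- if (event_type == "ripple") c(80, 250) else c(250, 500)
    if (is.null(f0) || f0 < lims[1] || f0 > lims[2] ||
        (event_type == "fast_ripple" && f0 <= 250)) {
      abort(sprintf("`f0` must be within (%g, %g] Hz for a %s.",
                    lims[1], lims[2], event_type))
    }
    if (f0 >= sampling_rate / 2) {
      abort("`f0` at or beyond Nyquist would alias.")
    }
    if (n_cycles < 4) abort("`n_cycles` must be >= 4.")
    n <- round(n_cycles / f0 * sampling_rate)
    u <- seq(0, 1, length.out = n)
    w <- sin(2 * pi * n_cycles * u) * 0.5 * (1 - cos(2 * pi * u))
  }
  w * amplitude / max(abs(w))
}
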