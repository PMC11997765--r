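#' Multichannel iEEG recording
#'
#' A recording bundles a channels-by-samples signal matrix (microvolts) with
#' its sampling rate and channel identifiers. Times throughout the package
#' are seconds from recording start (0-based); event intervals are half-open
#' `[onset, offset)`.
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_ids Character vector of unique channel identifiers, one per
#'   row of `signal`.
#' @param start_time Offset of the first sample in seconds (default 0).
#' @return An object of class `sr_recording`.
#' @export
#' @examples
#' rec <- new_recording(matrix(rnorm(2000), 2), 1000, c("A1", "A2"))
#' rec
new_recording <- function(signal, sampling_rate, channel_ids,
                          start_time = 0) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1L)
  storage.mode(signal) <- "double"
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number.")
  }
  if (ncol(signal) < 1L) abort("recording must contain at least one sample.")
  if (!all(is.finite(signal))) abort("signal contains non-finite samples.")
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != nrow(signal)) {
    abort("`channel_ids` must match the number of signal rows.")
  }
  if (anyDuplicated(channel_ids)) abort("`channel_ids` must be unique.")
  rownames(signal) <- channel_ids
  structure(
    list(signal = signal, sampling_rate = sampling_rate,
         channel_ids = channel_ids, start_time = start_time),
    class = "sr_recording"
  )
}

#' @export
print.sr_recording <- function(x, ...) {
  cat(sprintf("<sr_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              recording_duration(x)))
  invisible(x)
}

#' @rdname new_recording
#' @param recording An `sr_recording`.
#' @return `recording_duration()` returns the duration in seconds.
#' @export
recording_duration <- function(recording) {
  stopifnot(inherits(recording, "sr_recording"))
  ncol(recording$signal) / recording$sampling_rate
}
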