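#' Read and write European Data Format (EDF) files
#'
#' Minimal EDF support for continuous multichannel recordings: 16-bit
#' little-endian samples, one physical unit (microvolts assumed on read
#' whatever the stored dimension string), all signals sharing a single
#' sampling rate. Digital values are converted to physical units with the
#' per-signal linear scaling stored in the header. Annotation signals and
#' mixed sampling rates are not supported.
#'
#' @param path Path to an EDF file.
#' @return `read_recording()` returns an [new_recording()] object.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(paste0("EDF file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_chr <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  version <- hdr_chr(8)
  if (!identical(version, "0")) {
    abort("not an EDF file (unexpected version field).")
  }
  hdr_chr(80); hdr_chr(80)            # patient / recording id
  hdr_chr(8); hdr_chr(8)              # start date / time
  n_header <- as.integer(hdr_chr(8))
  hdr_chr(44)                         # reserved
  n_records <- as.integer(hdr_chr(8))
  record_dur <- as.numeric(hdr_chr(8))
  ns <- as.integer(hdr_chr(4))
  if (is.na(ns) || ns < 1L) abort("EDF file declares no signals.")
  field <- function(w) vapply(seq_len(ns), function(i) hdr_chr(w), "")
  labels <- field(16)
  field(80)                           # transducer
  field(8)                            # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                           # prefiltering
  spr <- as.integer(field(8))         # samples per record
  field(32)                           # reserved
  if (length(unique(spr)) != 1L) {
    abort("mixed sampling rates across signals are not supported.")
  }
  if (is.na(record_dur) || record_dur <= 0) {
    abort("invalid record duration in EDF header.")
  }
  fs <- spr[1L] / record_dur
  expected_header <- 256L + 256L * ns
  if (!is.na(n_header) && n_header != expected_header) {
    warn("EDF header length field inconsistent; proceeding by layout.")
  }
  total <- n_records * spr[1L]
  raw_data <- readBin(con, "integer", n = n_records * ns * spr[1L],
                      size = 2L, signed = TRUE, endian = "little")
  if (length(raw_data) < n_records * ns * spr[1L]) {
    abort("EDF data section truncated.")
  }
  # record-major layout: within each record the signals are sequential
  arr <- array(raw_data, dim = c(spr[1L], ns, n_records))
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- matrix(0, nrow = ns, ncol = total)
  for (i in seq_len(ns)) {
    sig[i, ] <- as.vector(arr[, i, ]) * gain[i] +
      (phys_min[i] - dig_min[i] * gain[i])
  }
  ids <- make.unique(labels)
  new_recording(sig, fs, ids)
}

#' @rdname read_recording
#' @param recording An [new_recording()] object.
#' @param record_duration Data-record length in seconds (default 1). The
#'   recording is zero-padded to a whole number of records on write; the pad
#'   is at most one record.
#' @return `write_recording()` invisibly returns `path`.
#' @export
write_recording <- function(recording, path, record_duration = 1) {
  stopifnot(inherits(recording, "sr_recording"))
  sig <- recording$signal
  fs <- recording$sampling_rate
  spr <- fs * record_duration
  if (abs(spr - round(spr)) > 1e-9) {
    abort("sampling_rate x record_duration must be an integer.")
  }
  spr <- as.integer(round(spr))
  ns <- nrow(sig)
  n_records <- ceiling(ncol(sig) / spr)
  pad <- n_records * spr - ncol(sig)
  if (pad > 0) sig <- cbind(sig, matrix(0, ns, pad))
  # symmetric physical range per signal, full 16-bit digital range
  amp <- pmax(apply(abs(sig), 1L, max), 1e-6)
  phys_max <- amp
  phys_min <- -amp
  dig_max <- 32767
  dig_min <- -32767
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w) {
    s <- sprintf("%-*s", w, substr(as.character(x), 1L, w))
    writeBin(charToRaw(s), con)
  }
  num <- function(x, w) put(formatC(x, width = -1, format = "g", digits = 7), w)
  put("0", 8)
  put("X X X X", 80)
  put("Startdate 01-JAN-2000", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(256L + 256L * ns, 8)
  put("", 44)
  put(n_records, 8)
  num(record_duration, 8)
  put(ns, 4)
  for (id in recording$channel_ids) put(id, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) num(phys_min[i], 8)
  for (i in seq_len(ns)) num(phys_max[i], 8)
  for (i in seq_len(ns)) put(dig_min, 8)
  for (i in seq_len(ns)) put(dig_max, 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(spr, 8)
  for (i in seq_len(ns)) put("", 32)
  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      dig <- round((sig[i, idx] - phys_min[i]) / gain[i] + dig_min)
      dig <- pmin(pmax(dig, dig_min), dig_max)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
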