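#' Read a channel metadata table
#'
#' Comma-separated UTF-8 with a mandatory header. Required columns:
#' `channel_id`, `lobe`, `is_soz`, `is_resected`, `electrode_kind`. Flags are
#' parsed from `0/1/true/false` (case-insensitive).
#'
#' @param path Path to a CSV file.
#' @return Tibble with one row per channel.
#' @export
read_channel_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("channel_id", "lobe", "is_soz", "is_resected",
                "electrode_kind")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    abort(paste0("channel table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble(
    channel_id = as.character(tab$channel_id),
    lobe = tolower(tab$lobe),
    is_soz = parse_flag(tab$is_soz, "is_soz"),
    is_resected = parse_flag(tab$is_resected, "is_resected"),
    electrode_kind = tolower(tab$electrode_kind)
  )
  validate_channels(out)
}

validate_channels <- function(channels) {
  channels <- as_tibble(channels)
  if (nrow(channels) == 0L) return(channels)
  if (anyDuplicated(channels$channel_id)) {
    abort("duplicate channel_id in channel table.")
  }
  bad_lobe <- setdiff(unique(channels$lobe), lobe_levels())
  if (length(bad_lobe)) {
    abort(paste0("unknown lobe: ", paste(bad_lobe, collapse = ", ")))
  }
  bad_kind <- setdiff(unique(channels$electrode_kind), electrode_kinds())
  if (length(bad_kind)) {
    abort(paste0("unknown electrode_kind: ",
                 paste(bad_kind, collapse = ", ")))
  }
  channels
}

parse_flag <- function(x, what) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t", "yes")] <- TRUE
  out[v %in% c("0", "false", "f", "no")] <- FALSE
  if (anyNA(out)) abort(paste0("unparseable ", what, " flag value."))
  out
}

#' Read and write event annotation tables
#'
#' Comma-separated with header. Required columns: `channel_id`, `onset`,
#' `offset` (seconds from recording start), `event_type` (one of `spike`,
#' `ripple`, `fast_ripple`). Optional: `peak_time` (defaults to the interval
#' midpoint), `peak_frequency`, `n_oscillations`, `qc_status`. This schema
#' also lets users import externally produced spike annotations in place of
#' the built-in stand-in detector.
#'
#' @param path Path to a CSV file.
#' @return `read_event_table()` returns an event tibble sorted by
#'   `(channel_id, onset)`.
#' @export
read_event_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("channel_id", "onset", "offset", "event_type")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    abort(paste0("event table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  ev <- tibble(
    channel_id = as.character(tab$channel_id),
    onset = as.numeric(tab$onset),
    offset = as.numeric(tab$offset),
    peak_time = if ("peak_time" %in% names(tab))
      as.numeric(tab$peak_time) else NA_real_,
    event_type = tolower(tab$event_type),
    peak_frequency = if ("peak_frequency" %in% names(tab))
      as.numeric(tab$peak_frequency) else NA_real_,
    n_oscillations = if ("n_oscillations" %in% names(tab))
      as.integer(tab$n_oscillations) else NA_integer_,
    qc_status = if ("qc_status" %in% names(tab))
      as.character(tab$qc_status) else NA_character_
  )
  validate_events(ev)
}

#' @rdname read_event_table
#' @param events Event tibble.
#' @export
validate_events <- function(events) {
  events <- as_tibble(events)
  need <- c("channel_id", "onset", "offset", "event_type")
  missing <- setdiff(need, names(events))
  if (length(missing)) {
    abort(paste0("events lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"peak_time" %in% names(events)) events$peak_time <- NA_real_
  events$peak_time <- ifelse(is.na(events$peak_time),
                             (events$onset + events$offset) / 2,
                             events$peak_time)
  if (nrow(events)) {
    bad_type <- setdiff(unique(events$event_type), event_types())
    if (length(bad_type)) {
      abort(paste0("unknown event_type: ", paste(bad_type, collapse = ", ")))
    }
    if (any(events$onset > events$offset)) {
      abort("event with onset > offset.")
    }
    if (any(events$peak_time < events$onset |
            events$peak_time > events$offset)) {
      abort("event with peak_time outside [onset, offset].")
    }
  }
  arrange(events, .data$channel_id, .data$onset)
}

#' @rdname read_event_table
#' @return `write_event_table()` invisibly returns `path`; rows are ordered
#'   by `(channel_id, onset)` so writes are stable, and
#'   `read_event_table(write_event_table(e))` reproduces `e` up to float
#'   formatting.
#' @export
write_event_table <- function(events, path) {
  events <- validate_events(empty_events_if_null(events))
  keep <- c("channel_id", "onset", "offset", "peak_time", "event_type",
            "peak_frequency", "n_oscillations", "qc_status")
  for (k in keep) if (!k %in% names(events)) events[[k]] <- NA
  readr::write_csv(events[keep], path)
  invisible(path)
}

empty_events <- function() {
  tibble(channel_id = character(), onset = double(), offset = double(),
         peak_time = double(), event_type = character(),
         peak_frequency = double(), n_oscillations = integer(),
         qc_status = character())
}

empty_events_if_null <- function(events) {
  if (is.null(events) || nrow(as_tibble(events)) == 0L) empty_events()
  else events
}

#' Read a patient cohort table
#'
#' Required columns: `patient_id`, `duration_min` (analyzed recording length,
#' minutes), `engel` (Engel class), `follow_up` (years). An `outcome` column
#' (`good`/`poor`) is derived from `engel` and checked against any provided
#' one.
#'
#' @param path Path to a CSV file.
#' @return Tibble with one row per patient.
#' @export
read_cohort_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("patient_id", "duration_min", "engel", "follow_up")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    abort(paste0("cohort table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble(
    patient_id = as.character(tab$patient_id),
    duration_min = as.numeric(tab$duration_min),
    engel = as.character(tab$engel),
    outcome = parse_engel(tab$engel),
    follow_up = as.numeric(tab$follow_up)
  )
  if ("outcome" %in% names(tab)) {
    given <- tolower(tab$outcome)
    if (!all(given == as.character(out$outcome))) {
      abort("outcome column contradicts Engel classes.")
    }
  }
  if (anyDuplicated(out$patient_id)) abort("duplicate patient_id.")
  if (any(out$duration_min <= 0)) abort("duration_min must be positive.")
  out
}
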