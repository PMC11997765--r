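#' Synthetic patient parameters
#'
#' Defaults emulate the structure this analysis assumes in clinical
#' interictal iEEG, at desk scale: pink (1/f) background; baseline channel
#' rates of about 1.3 spikes/min, 0.9 ripples/min and 0.15 fast ripples/min;
#' co-occurrence planned at generation time with the fractions of spikes
#' arriving on a ripple (11%), on a fast ripple (2%) and on both (2%), and of
#' ripples arriving on a fast ripple (5%); and a doubling of every category
#' rate on channels inside the seizure-onset zone / resected area
#' (`inside_multiplier = 2`). Companion events of a planned cluster are
#' jittered uniformly within +/- `cooccur_jitter` seconds of the anchor, so
#' planned co-occurrence survives a +/- 50 ms classification window by
#' construction.
#'
#' @param n_channels Number of channels (default 16).
#' @param duration Recording duration in seconds (default 600).
#' @param sampling_rate Hz (default 2000; must be >= 1000, and >= 1000 Hz
#'   band-limit support is required when `fr_rate > 0`).
#' @param background_exponent 1/f^alpha exponent (default 1).
#' @param background_rms Background RMS in microvolts (default 20).
#' @param spike_rate,ripple_rate,fr_rate Baseline per-channel rates
#'   (events/min) outside the SOZ/RA.
#' @param inside_multiplier Rate multiplier inside SOZ/RA (default 2).
#' @param p_cooccur Named list: `s_r`, `s_fr`, `s_r_fr` are fractions of
#'   spikes planned with a co-occurring ripple / fast ripple / both; `r_fr`
#'   the fraction of ripples planned with a co-occurring fast ripple.
#' @param cooccur_jitter Maximum |anchor - companion| peak latency, seconds
#'   (default 0.05).
#' @param snr Event peak amplitude divided by `sqrt(2)` times the background
#'   RMS in the event's band (default 5), i.e. the amplitude of an
#'   equal-power in-band sinusoid.
#' @param n_soz_channels,n_resected_channels SOZ and resected channel counts;
#'   the SOZ is a subset of the resection by default (good-outcome
#'   geometry); `soz_in_resection = FALSE` makes them disjoint.
#' @param soz_in_resection Logical (default `TRUE`).
#' @param seed Integer seed (mandatory for generation functions).
#' @return A list of class `sr_synth_params`.
#' @export
synth_params <- function(n_channels = 16, duration = 600,
                         sampling_rate = 2000, background_exponent = 1,
                         background_rms = 20, spike_rate = 1.3,
                         ripple_rate = 0.9, fr_rate = 0.15,
                         inside_multiplier = 2,
                         p_cooccur = list(s_r = 0.11, s_fr = 0.02,
                                          s_r_fr = 0.02, r_fr = 0.05),
                         cooccur_jitter = 0.05, snr = 5,
                         n_soz_channels = 4, n_resected_channels = 6,
                         soz_in_resection = TRUE, seed = 1L) {
  p <- as.list(environment())
  if (any(c(spike_rate, ripple_rate, fr_rate) < 0)) {
    abort("rates must be >= 0.")
  }
  pc <- unlist(p_cooccur)
  if (any(pc < 0 | pc > 1)) abort("co-occurrence probabilities must be in [0,1].")
  if (fr_rate > 0 && sampling_rate < 1000) {
    abort("fast ripples need sampling_rate >= 2 x 500 Hz.")
  }
  if (n_soz_channels + ifelse(soz_in_resection, 0, n_resected_channels) >
      n_channels || n_resected_channels > n_channels) {
    abort("SOZ/resected channel counts exceed n_channels.")
  }
  if (soz_in_resection && n_soz_channels > n_resected_channels) {
    abort("with soz_in_resection, n_soz_channels <= n_resected_channels.")
  }
  # derive planned per-category rates (events/min of cluster anchors)
  lam <- planned_category_rates(p)
  if (any(lam < -1e-9)) {
    abort(paste("co-occurrence fractions imply a negative isolated-event",
                "rate; lower p_cooccur or raise ripple/fast-ripple rates."))
  }
  p$planned_rates <- pmax(lam, 0)
  structure(p, class = "sr_synth_params")
}

planned_category_rates <- function(p) {
  pc <- p$p_cooccur
  s_r_fr <- pc$s_r_fr * p$spike_rate
  s_r <- pc$s_r * p$spike_rate
  s_fr <- pc$s_fr * p$spike_rate
  r_fr <- pc$r_fr * p$ripple_rate
  c(s_only = p$spike_rate - s_r - s_fr - s_r_fr,
    r_only = p$ripple_rate - s_r - s_r_fr - r_fr,
    fr_only = p$fr_rate - s_fr - s_r_fr - r_fr,
    s_r = s_r, s_fr = s_fr, r_fr = r_fr, s_r_fr = s_r_fr)
}

# channel metadata implied by the params (first channels are SOZ/resected)
synth_channels <- function(params) {
  n <- params$n_channels
  ids <- sprintf("CH%02d", seq_len(n))
  soz <- seq_len(params$n_soz_channels)
  res <- if (params$soz_in_resection) {
    seq_len(params$n_resected_channels)
  } else {
    params$n_soz_channels + seq_len(params$n_resected_channels)
  }
  tibble(
    channel_id = ids,
    lobe = rep_len(lobe_levels()[1:4], n),
    is_soz = seq_len(n) %in% soz,
    is_resected = seq_len(n) %in% res,
    electrode_kind = "grid"
  )
}

# events per cluster composition, with per-type member events
cluster_members <- function(category) {
  switch(category,
    s_only = "spike", r_only = "ripple", fr_only = "fast_ripple",
    s_r = c("spike", "ripple"), s_fr = c("spike", "fast_ripple"),
    r_fr = c("ripple", "fast_ripple"),
    s_r_fr = c("spike", "ripple", "fast_ripple"))
}

#' Generate ground-truth events for one synthetic patient
#'
#' Cluster anchors are drawn from homogeneous Poisson processes per channel
#' and planned category; channels inside the SOZ/RA receive
#' `inside_multiplier` times the baseline rate. Anchors closer than 0.25 s on
#' a channel are thinned (with a warning when the loss exceeds 2%) so planned
#' clusters cannot merge; companion events are placed within
#' `+/- cooccur_jitter` of the anchor peak. Events are kept at least 100 ms
#' from the segment edges.
#'
#' @param params An [synth_params()] object.
#' @param seed Integer seed; overrides `params$seed` when given.
#' @return Event tibble with a `planned_category` column.
#' @export
synth_events <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sr_synth_params"))
  channels <- synth_channels(params)
  dur_min <- params$duration / 60
  lam <- params$planned_rates
  withr::with_seed(seed, {
    per_channel <- purrr::map(seq_len(nrow(channels)), function(i) {
      mult <- if (channels$is_soz[i] || channels$is_resected[i])
        params$inside_multiplier else 1
      counts <- rpois(length(lam), lam * mult * dur_min)
      total <- sum(counts)
      if (total == 0L) return(NULL)
      anchors <- sort(runif(total, 0.1, params$duration - 0.1))
      cats <- sample(rep(names(lam), counts))
      keep <- thin_min_gap(anchors, 0.25)
      # single random collisions are expected; warn only when the dead time
      # is eating a systematic share of the planned events
      if (sum(!keep) >= 5L && sum(!keep) / total > 0.1) {
        warn(sprintf(
          "channel %s: %d of %d planned clusters thinned (rate near capacity)",
          channels$channel_id[i], sum(!keep), total))
      }
      anchors <- anchors[keep]
      cats <- cats[keep]
      purrr::map2_dfr(anchors, cats, function(a, cat) {
        make_cluster_events(a, cat, params, channels$channel_id[i])
      })
    })
    validate_events(dplyr::bind_rows(c(list(empty_events()), per_channel)))
  })
}

thin_min_gap <- function(sorted_times, gap) {
  keep <- logical(length(sorted_times))
  last <- -Inf
  for (j in seq_along(sorted_times)) {
    if (sorted_times[j] - last >= gap) {
      keep[j] <- TRUE
      last <- sorted_times[j]
    }
  }
  keep
}

make_cluster_events <- function(anchor, category, params, channel_id) {
  types <- cluster_members(category)
  peaks <- anchor +
    c(0, runif(length(types) - 1L, -params$cooccur_jitter,
               params$cooccur_jitter))
  rows <- purrr::map2_dfr(types, peaks, function(tp, pk) {
    if (tp == "spike") {
      half <- 0.03
      f0 <- NA_real_; nc <- NA_integer_
    } else if (tp == "ripple") {
      f0 <- runif(1, 90, 240); nc <- sample(6:12, 1)
      half <- nc / f0 / 2
    } else {
      f0 <- runif(1, 260, 450); nc <- sample(6:10, 1)
      half <- nc / f0 / 2
    }
    tibble(channel_id = channel_id, onset = pk - half, offset = pk + half,
           peak_time = pk, event_type = tp, peak_frequency = f0,
           n_oscillations = nc, qc_status = NA_character_)
  })
  rows$planned_category <- category
  rows
}

#' Synthesize a full patient: recording, ground truth and channel labels
#'
#' Draws ground-truth events with [synth_events()], builds a 1/f background
#' with [synth_background()] and injects each event's waveform at the
#' configured SNR (peak amplitude = `snr * sqrt(2) *` background RMS in the
#' event's band, measured per channel).
#'
#' @inheritParams synth_events
#' @return List with elements `recording` ([new_recording()]), `events`
#'   (ground-truth tibble) and `channels` (channel tibble).
#' @export
synth_patient <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sr_synth_params"))
  events <- synth_events(params, seed = seed)
  channels <- synth_channels(params)
  rec <- synth_background(params$n_channels, params$duration,
                          params$sampling_rate,
                          alpha = params$background_exponent,
                          rms = params$background_rms,
                          seed = seed + 104729L,
                          channel_ids = channels$channel_id)
  fs <- params$sampling_rate
  bands <- list(spike = c(1, 70), ripple = c(80, 250),
                fast_ripple = c(250, min(500, fs / 2 * 0.999)))
  withr::with_seed(seed + 224737L, {
    for (ci in seq_len(nrow(channels))) {
      id <- channels$channel_id[ci]
      ev <- events[events$channel_id == id, ]
      if (nrow(ev) == 0L) next
      x <- rec$signal[ci, ]
      band_rms <- purrr::map_dbl(bands, function(b) {
        sqrt(mean(bandpass(x, b, fs)^2))
      })
      for (k in seq_len(nrow(ev))) {
        tp <- ev$event_type[k]
        amp <- params$snr * sqrt(2) * band_rms[[tp]]
        w <- if (tp == "spike") {
          synth_event_waveform("spike", amplitude = amp, sampling_rate = fs)
        } else {
          synth_event_waveform(tp, f0 = ev$peak_frequency[k],
                               n_cycles = ev$n_oscillations[k],
                               amplitude = amp, sampling_rate = fs)
        }
        start <- round(ev$onset[k] * fs) + 1L
        idx <- start:(start + length(w) - 1L)
        ok <- idx >= 1L & idx <= length(x)
        x[idx[ok]] <- x[idx[ok]] + w[ok]
      }
      rec$signal[ci, ] <- x
    }
  })
  list(recording = rec, events = events, channels = channels)
}
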