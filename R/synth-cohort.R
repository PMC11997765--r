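#' Synthetic cohort parameters
#'
#' Cohort defaults mirror a typical pediatric epilepsy-surgery series: 40
#' patients of whom 26 achieve a good (Engel I) outcome. Outcome is tied to
#' the ground truth by a resection-ratio rule: for designed-good patients the
#' resected channel set is chosen so the realized resection ratio of
#' `outcome_rule_biomarker` exceeds `outcome_threshold`, and stays below it
#' for designed-poor patients; labels are then flipped independently with
#' probability `label_noise` to emulate prognostic ambiguity.
#'
#' @param n_patients Number of patients (default 40).
#' @param n_good Designed good outcomes before label noise (default 26).
#' @param outcome_rule_biomarker Category driving the outcome rule
#'   (default `"s_r"`).
#' @param outcome_threshold Resection-ratio cut-off (default 0.5).
#' @param label_noise Probability a label contradicts the rule (default 0.1,
#'   must be <= 0.5).
#' @param base [synth_params()] shared by all patients.
#' @param rate_scale_range Per-patient multiplicative jitter on all event
#'   rates, drawn uniformly (default `c(0.5, 2)`).
#' @param design_outcome When `TRUE` (default) the resected set is adjusted
#'   until the realized rule ratio lands on the designed side of the
#'   threshold. Set `FALSE` for localization analyses: resection labels then
#'   stay at the a-priori geometry of [synth_params()], independent of the
#'   realized event counts.
#' @param seed Integer seed.
#' @return A list of class `sr_cohort_params`.
#' @export
cohort_params <- function(n_patients = 40, n_good = 26,
                          outcome_rule_biomarker = "s_r",
                          outcome_threshold = 0.5, label_noise = 0.1,
                          base = synth_params(),
                          rate_scale_range = c(0.5, 2),
                          design_outcome = TRUE, seed = 1L) {
  if (n_good > n_patients) abort("n_good must be <= n_patients.")
  if (label_noise < 0 || label_noise > 0.5) {
    abort("label_noise must be in [0, 0.5].")
  }
  outcome_rule_biomarker <- match_category(outcome_rule_biomarker)
  structure(as.list(environment()), class = "sr_cohort_params")
}

# planned-category counts per channel (rows) without waveform synthesis
gen_patient_counts <- function(params, seed) {
  channels <- synth_channels(params)
  lam <- params$planned_rates
  dur_min <- params$duration / 60
  hot <- channels$is_soz | channels$is_resected
  withr::with_seed(seed, {
    mult <- ifelse(hot, params$inside_multiplier, 1)
    counts <- matrix(rpois(length(lam) * nrow(channels),
                           rep(lam * dur_min, each = nrow(channels)) *
                             rep(mult, length(lam))),
                     nrow = nrow(channels),
                     dimnames = list(channels$channel_id, names(lam)))
    counts
  })
}

# long 11-category rate tibble from a channels x 7 planned-count matrix
rates_from_planned_counts <- function(counts, duration_min) {
  stopifnot(duration_min > 0)
  full <- cbind(
    all_s = rowSums(counts[, c("s_only", "s_r", "s_fr", "s_r_fr"),
                           drop = FALSE]),
    all_r = rowSums(counts[, c("r_only", "s_r", "r_fr", "s_r_fr"),
                           drop = FALSE]),
    all_fr = rowSums(counts[, c("fr_only", "s_fr", "r_fr", "s_r_fr"),
                            drop = FALSE]),
    counts[, bm_cluster_categories(), drop = FALSE],
    s_hfo = rowSums(counts[, c("s_r", "s_fr", "s_r_fr"), drop = FALSE])
  )
  tibble(
    channel_id = rep(rownames(counts), times = ncol(full)),
    category = rep(colnames(full), each = nrow(full)),
    count = as.vector(full),
    rate = as.vector(full) / duration_min,
    duration_min = duration_min
  )
}

#' Generate a synthetic patient cohort
#'
#' Each patient receives per-channel, per-category event counts from the
#' planned-category Poisson model of [synth_params()] (identical in law to
#' counting the events of [synth_events()]); the resected channel set is then
#' adjusted so the ground-truth resection ratio of the rule biomarker lands
#' on the designed side of the threshold, and outcome labels are flipped with
#' probability `label_noise`.
#'
#' @param cp A [cohort_params()] object.
#' @param events Also generate event-level ground truth per patient (slower;
#'   default `FALSE`).
#' @return Tibble with one row per patient: `patient_id`, `engel`, `outcome`,
#'   `designed_outcome`, `rule_ratio` (realized ground-truth resection
#'   ratio), `follow_up`, `duration_min`, and list-columns `rates`,
#'   `channels` (and `events` when requested).
#' @export
synth_cohort <- function(cp, events = FALSE) {
  stopifnot(inherits(cp, "sr_cohort_params"))
  designed <- rep(c("good", "poor"),
                  c(cp$n_good, cp$n_patients - cp$n_good))
  meta <- withr::with_seed(cp$seed, {
    tibble(
      patient_id = sprintf("P%02d", seq_len(cp$n_patients)),
      designed_outcome = designed,
      rate_scale = runif(cp$n_patients, cp$rate_scale_range[1],
                         cp$rate_scale_range[2]),
      follow_up = sample(1:8, cp$n_patients, replace = TRUE),
      flip = runif(cp$n_patients) < cp$label_noise,
      sub_seed = sample.int(2^20, cp$n_patients) + cp$seed,
      engel_draw = runif(cp$n_patients)
    )
  })
  out <- purrr::map_dfr(seq_len(cp$n_patients), function(i) {
    p <- cp$base
    p$spike_rate <- p$spike_rate * meta$rate_scale[i]
    p$ripple_rate <- p$ripple_rate * meta$rate_scale[i]
    p$fr_rate <- p$fr_rate * meta$rate_scale[i]
    p$planned_rates <- p$planned_rates * meta$rate_scale[i]
    dur_min <- p$duration / 60
    ev <- NULL
    if (events) {
      ev <- synth_events(p, seed = meta$sub_seed[i])
      counts <- planned_counts_from_events(ev, synth_channels(p)$channel_id)
    } else {
      counts <- gen_patient_counts(p, seed = meta$sub_seed[i])
    }
    channels <- synth_channels(p)
    rule_counts <- rule_category_counts(counts, cp$outcome_rule_biomarker)
    if (cp$design_outcome) {
      res <- design_resection(rule_counts, channels,
                              good = meta$designed_outcome[i] == "good",
                              threshold = cp$outcome_threshold)
      channels$is_resected <- res$is_resected
      ratio <- res$ratio
    } else {
      ratio <- if (sum(rule_counts) > 0) {
        sum(rule_counts[channels$is_resected]) / sum(rule_counts)
      } else NA_real_
    }
    rates <- rates_from_planned_counts(counts, dur_min)
    outcome <- meta$designed_outcome[i]
    if (meta$flip[i]) outcome <- ifelse(outcome == "good", "poor", "good")
    engel <- assign_engel(outcome, meta$engel_draw[i])
    row <- tibble(
      patient_id = meta$patient_id[i], engel = engel, outcome = outcome,
      designed_outcome = meta$designed_outcome[i],
      rule_ratio = ratio, follow_up = meta$follow_up[i],
      duration_min = dur_min, rates = list(rates), channels = list(channels)
    )
    if (events) row$events <- list(ev)
    row
  })
  out$outcome <- factor(out$outcome, levels = c("good", "poor"))
  out
}

planned_counts_from_events <- function(ev, channel_ids) {
  # one planned cluster = one count; spikes anchor multi-type clusters, so
  # count distinct (channel, planned_category, anchor) via the first member
  anchors <- ev |>
    group_by(.data$channel_id, .data$planned_category) |>
    summarise(n = sum(.data$event_type ==
                        cluster_members(.data$planned_category[1])[1]),
              .groups = "drop")
  counts <- matrix(0L, nrow = length(channel_ids),
                   ncol = length(bm_cluster_categories()),
                   dimnames = list(channel_ids, bm_cluster_categories()))
  counts[cbind(match(anchors$channel_id, channel_ids),
               match(anchors$planned_category,
                     bm_cluster_categories()))] <- anchors$n
  counts
}

rule_category_counts <- function(counts, category) {
  contrib <- switch(category,
    all_s = c("s_only", "s_r", "s_fr", "s_r_fr"),
    all_r = c("r_only", "s_r", "r_fr", "s_r_fr"),
    all_fr = c("fr_only", "s_fr", "r_fr", "s_r_fr"),
    s_hfo = c("s_r", "s_fr", "s_r_fr"),
    category)
  rowSums(counts[, contrib, drop = FALSE])
}

# choose the resected set so the realized rule ratio lands on the designed
# side of the threshold; greedy adjustment from the hot/cold baseline
design_resection <- function(rule_counts, channels, good, threshold) {
  total <- sum(rule_counts)
  if (total == 0) {
    abort(paste("cannot design outcome: the rule biomarker has no events;",
                "raise its rate or the recording duration."))
  }
  n <- length(rule_counts)
  if (good) {
    res <- channels$is_resected
    ratio <- sum(rule_counts[res]) / total
    order_hot <- order(rule_counts, decreasing = TRUE)
    for (j in order_hot) {
      if (ratio > threshold) break
      if (!res[j]) {
        res[j] <- TRUE
        ratio <- sum(rule_counts[res]) / total
      }
    }
    if (ratio <= threshold) {
      abort("cannot design a good outcome above the ratio threshold.")
    }
  } else {
    # resect the coldest non-SOZ channels, shrinking if still too hot
    k <- sum(channels$is_resected)
    cold <- order(rule_counts + ifelse(channels$is_soz, max(rule_counts) *
                                         n, 0))
    res <- rep(FALSE, n)
    res[cold[seq_len(k)]] <- TRUE
    ratio <- sum(rule_counts[res]) / total
    while (ratio >= threshold && any(res)) {
      drop <- which(res)[which.max(rule_counts[res])]
      res[drop] <- FALSE
      ratio <- sum(rule_counts[res]) / total
    }
    if (ratio >= threshold) {
      abort("cannot design a poor outcome below the ratio threshold.")
    }
  }
  list(is_resected = res, ratio = ratio)
}

assign_engel <- function(outcome, u) {
  if (outcome == "good") {
    c("1a", "1a", "1b", "1c", "1d")[ceiling(u * 5)]
  } else {
    c("2b", "3", "3a", "3a", "4b")[ceiling(u * 5)]
  }
}
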