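#' Cluster events by temporal co-occurrence
#'
#' Two events on the same channel co-occur when their peak times differ by
#' at most `window` ms (closed interval: a latency of exactly 50 ms still
#' counts). Clusters are the connected components of this relation (single
#' linkage), so transitive chains merge: a spike at 0 ms, a ripple at 40 ms
#' and a fast ripple at 80 ms form one `s_r_fr` cluster. Events never
#' cluster across channels.
#'
#' @param events Event tibble (needs `channel_id`, `peak_time`,
#'   `event_type`).
#' @param window Co-occurrence half-window in ms (default 50).
#' @return Tibble with one row per event: its `cluster_id`, the cluster's
#'   `category` (one of the seven exclusive compositions) and `cluster_size`.
#' @export
build_clusters <- function(events, window = 50) {
  if (window < 0) abort("`window` must be >= 0.")
  events <- validate_events(empty_events_if_null(events))
  if (nrow(events) == 0L) {
    return(mutate(events, cluster_id = character(), category = character(),
                  cluster_size = integer()))
  }
  w <- window / 1000
  events <- arrange(events, .data$channel_id, .data$peak_time)
  # single linkage on a sorted line: a new component starts where the gap to
  # the previous peak exceeds the window
  events <- events |>
    group_by(.data$channel_id) |>
    mutate(.gap = c(Inf, diff(.data$peak_time)),
           .comp = cumsum(.data$.gap > w + 1e-12)) |>
    ungroup() |>
    mutate(cluster_id = paste0(.data$channel_id, "#", .data$.comp)) |>
    select(-".gap", -".comp")
  events |>
    group_by(.data$cluster_id) |>
    mutate(category = category_from_types(unique(.data$event_type)),
           cluster_size = dplyr::n()) |>
    ungroup()
}

#' Count events and clusters in the eleven biomarker categories
#'
#' `all_s`/`all_r`/`all_fr` count individual events of each type;
#' `s_only` ... `s_r_fr` count clusters with exactly that composition;
#' `s_hfo` counts clusters containing a spike and at least one HFO. Both
#' per-cluster (`n_clusters`) and per-event (`n_events`) tallies are
#' reported; the `count` column carries the headline convention (events for
#' the `all_*` categories, clusters otherwise).
#'
#' @param clustered Output of [build_clusters()].
#' @param channel_ids Channels to report (default: those present). Channels
#'   without events get zero counts, so they participate in downstream rate
#'   comparisons.
#' @return Tibble `(channel_id, category, count, n_events, n_clusters)`,
#'   complete over `channel_ids` x categories.
#' @export
categorize_events <- function(clustered, channel_ids = NULL) {
  channel_ids <- channel_ids %||% unique(clustered$channel_id)
  grid <- tidyr::expand_grid(channel_id = as.character(channel_ids),
                             category = bm_categories())
  if (nrow(clustered) == 0L) {
    return(mutate(grid, count = 0L, n_events = 0L, n_clusters = 0L))
  }
  type_cat <- c(spike = "all_s", ripple = "all_r", fast_ripple = "all_fr")
  ev_all <- clustered |>
    count(.data$channel_id, category = type_cat[.data$event_type],
          name = "n_events") |>
    mutate(n_clusters = NA_integer_)
  # clusters counted once; events within them also tallied
  clus <- clustered |>
    group_by(.data$channel_id, .data$cluster_id, .data$category) |>
    summarise(size = dplyr::n(), .groups = "drop")
  clus_tab <- clus |>
    group_by(.data$channel_id, .data$category) |>
    summarise(n_clusters = dplyr::n(), n_events = sum(.data$size),
              .groups = "drop")
  s_hfo <- clus |>
    filter(.data$category %in% c("s_r", "s_fr", "s_r_fr")) |>
    group_by(.data$channel_id) |>
    summarise(n_clusters = dplyr::n(), n_events = sum(.data$size),
              .groups = "drop") |>
    mutate(category = "s_hfo")
  # all_* cluster tallies: clusters containing the type
  all_clus <- clustered |>
    distinct(.data$channel_id, .data$cluster_id, .data$event_type) |>
    count(.data$channel_id, category = type_cat[.data$event_type],
          name = "n_clusters")
  counts <- bind_rows(
    left_join(ev_all |> select(-"n_clusters"), all_clus,
              by = c("channel_id", "category")),
    clus_tab, s_hfo
  )
  grid |>
    left_join(counts, by = c("channel_id", "category")) |>
    mutate(
      n_events = ifelse(is.na(.data$n_events), 0L, .data$n_events),
      n_clusters = ifelse(is.na(.data$n_clusters), 0L, .data$n_clusters),
      count = ifelse(.data$category %in% c("all_s", "all_r", "all_fr"),
                     .data$n_events, .data$n_clusters)
    ) |>
    select("channel_id", "category", "count", "n_events", "n_clusters")
}

#' Per-channel biomarker occurrence rates
#'
#' Rates are event (or cluster) counts divided by the analyzed recording
#' length in minutes.
#'
#' @param counts Output of [categorize_events()].
#' @param duration_min Recording duration in minutes (> 0).
#' @return `counts` with `rate` (events/min) and `duration_min` columns.
#' @export
compute_rates <- function(counts, duration_min) {
  if (!is.numeric(duration_min) || duration_min <= 0) {
    abort("`duration_min` must be positive.")
  }
  mutate(counts, rate = .data$count / duration_min,
         duration_min = duration_min)
}

#' Area percentage of a biomarker
#'
#' The proportion (in percent) of implanted channels on which a biomarker
#' occurs, alongside the resected-area and SOZ percentages from the channel
#' flags.
#'
#' @param rates Rate tibble from [compute_rates()].
#' @param channels Channel tibble (needs `channel_id`, `is_soz`,
#'   `is_resected`).
#' @param category Biomarker category code.
#' @return Tibble with `biomarker_pct`, `resected_pct`, `soz_pct`.
#' @export
area_percentage <- function(rates, channels, category) {
  category <- match_category(category, several.ok = FALSE)
  if (nrow(channels) == 0L) abort("need at least one channel.")
  r <- rates |>
    filter(.data$category == !!category) |>
    select("channel_id", "rate")
  ch <- left_join(channels, r, by = "channel_id") |>
    mutate(rate = ifelse(is.na(.data$rate), 0, .data$rate))
  tibble(
    category = category,
    biomarker_pct = 100 * mean(ch$rate > 0),
    resected_pct = 100 * mean(ch$is_resected),
    soz_pct = 100 * mean(ch$is_soz)
  )
}
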