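#' Resection ratio of a biomarker
#'
#' The fraction of a biomarker's total rate carried by resected contacts:
#' sum of the category's rates over resected channels divided by the sum
#' over all channels. A value near 1 means essentially all of the
#' biomarker's events were removed; near 0, essentially none. When the
#' patient shows no events of the category the ratio is undefined (`NA`) and
#' the patient is excluded from that biomarker's outcome analysis.
#'
#' @param rates Rate tibble from [compute_rates()].
#' @param channels Channel tibble with `is_resected`.
#' @param category Biomarker category code.
#' @return A single number in `[0, 1]`, or `NA` when undefined.
#' @export
#' @examples
#' rates <- tibble::tibble(channel_id = c("a", "b", "c"), category = "s_r",
#'                         count = c(2, 3, 5), rate = c(2, 3, 5) / 10,
#'                         duration_min = 10)
#' ch <- tibble::tibble(channel_id = c("a", "b", "c"),
#'                      is_resected = c(TRUE, TRUE, FALSE))
#' resection_ratio(rates, ch, "s_r")  # 0.5
resection_ratio <- function(rates, channels, category) {
  category <- match_category(category, several.ok = FALSE)
  r <- rates |> filter(.data$category == !!category)
  ch <- left_join(channels, select(r, "channel_id", "rate"),
                  by = "channel_id") |>
    mutate(rate = ifelse(is.na(.data$rate), 0, .data$rate))
  total <- sum(ch$rate)
  if (total <= 0) return(NA_real_)
  sum(ch$rate[ch$is_resected]) / total
}

#' SOZ ratio
#'
#' The fraction of seizure-onset-zone contacts that were resected.
#'
#' @param channels Channel tibble with `is_soz` and `is_resected`.
#' @return Number in `[0, 1]`, or `NA` when the patient has no SOZ contacts.
#' @export
soz_ratio <- function(channels) {
  n_soz <- sum(channels$is_soz)
  if (n_soz == 0L) return(NA_real_)
  sum(channels$is_soz & channels$is_resected) / n_soz
}

#' Per-patient outcome predictors
#'
#' @param cohort Cohort tibble with list-columns `rates` and `channels`.
#' @param category Biomarker category, or `"soz"` for the SOZ ratio.
#' @return Tibble `(patient_id, outcome, predictor)`; `predictor` is `NA`
#'   for patients lacking the biomarker.
#' @export
cohort_predictors <- function(cohort, category) {
  pred <- purrr::map_dbl(seq_len(nrow(cohort)), function(i) {
    if (identical(category, "soz")) {
      soz_ratio(cohort$channels[[i]])
    } else {
      resection_ratio(cohort$rates[[i]], cohort$channels[[i]], category)
    }
  })
  tibble(patient_id = cohort$patient_id,
         outcome = factor(cohort$outcome, levels = c("good", "poor")),
         predictor = pred)
}

#' Outcome prediction metrics at the Youden point
#'
#' ROC of a per-patient predictor (e.g. resection ratio) against surgical
#' outcome, with the positive class = good outcome and a positive prediction
#' = predictor strictly above the threshold. The operating threshold
#' maximizes Youden's J = sensitivity + specificity - 1 (ties broken toward
#' the higher-specificity point); the full metric suite -- sensitivity,
#' specificity, PPV, NPV, markedness (PPV + NPV - 1), FPR, accuracy -- is
#' evaluated there. Patients with an undefined predictor are excluded and
#' counted.
#'
#' @param predictor Numeric vector (NA = undefined, excluded).
#' @param outcomes Factor/character with levels `good`/`poor`.
#' @param threshold Optional fixed threshold; when supplied the Youden
#'   search is skipped (used for pseudo-prospective prediction).
#' @return Object of class `sr_outcome`: metrics, confusion counts,
#'   `threshold`, `auc`, `n_excluded`.
#' @export
outcome_roc_metrics <- function(predictor, outcomes, threshold = NULL) {
  keep <- !is.na(predictor)
  n_excluded <- sum(!keep)
  predictor <- predictor[keep]
  outcomes <- as.character(outcomes)[keep]
  good <- outcomes == "good"
  if (!any(good) || all(good)) {
    abort("degenerate labels: both outcomes must be present.")
  }
  roc <- build_roc(predictor, good)
  if (is.null(threshold)) {
    j <- roc$sensitivity + roc$specificity - 1
    best <- which(abs(j - max(j)) < 1e-12)
    best <- best[which.max(roc$specificity[best])]
    threshold <- roc$threshold[best]
  }
  pred_pos <- predictor > threshold
  tp <- sum(pred_pos & good); fp <- sum(pred_pos & !good)
  tn <- sum(!pred_pos & !good); fn <- sum(!pred_pos & good)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  structure(list(
    metrics = tibble(
      auc = attr(roc, "auc"), sensitivity = sens, specificity = spec,
      ppv = ppv, npv = npv, markedness = ppv + npv - 1, fpr = 1 - spec,
      accuracy = (tp + tn) / (tp + tn + fp + fn),
      youden_j = sens + spec - 1, threshold = threshold
    ),
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    roc = roc, threshold = threshold, n_excluded = n_excluded,
    n = length(predictor)
  ), class = "sr_outcome")
}

#' @export
print.sr_outcome <- function(x, ...) {
  cat(sprintf("<sr_outcome> n = %d (excluded %d), threshold = %.3g\n",
              x$n, x$n_excluded, x$threshold))
  m <- x$metrics
  cat(sprintf(
    "  AUC %.3f | sens %.2f spec %.2f | PPV %.2f NPV %.2f | acc %.2f\n",
    m$auc, m$sensitivity, m$specificity, m$ppv, m$npv, m$accuracy))
  cat(sprintf("  confusion TP %d FP %d TN %d FN %d\n", x$confusion["TP"],
              x$confusion["FP"], x$confusion["TN"], x$confusion["FN"]))
  invisible(x)
}

#' @export
tidy.sr_outcome <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.sr_outcome <- function(x, ...) {
  bind_cols(x$metrics, tibble(n = x$n, n_excluded = x$n_excluded))
}

#' Leave-one-out cross-validated outcome metrics
#'
#' For each fold one patient is dropped and [outcome_roc_metrics()] is
#' recomputed on the remainder (threshold refitted per fold unless `cutoff`
#' is given); metrics are summarized as median and IQR across folds. This
#' characterizes the stability of the operating point rather than held-out
#' prediction. Folds left with a single outcome class are skipped with a
#' message.
#'
#' @param cohort Cohort tibble.
#' @param category Biomarker category, or `"soz"`.
#' @param cutoff Optional fixed threshold (pseudo-prospective mode).
#' @return List of class `sr_loocv`: `summary` tibble
#'   (`metric`, `median`, `q25`, `q75`), per-fold tibble, counts.
#' @export
loocv_outcome <- function(cohort, category, cutoff = NULL) {
  preds <- cohort_predictors(cohort, category)
  usable <- which(!is.na(preds$predictor))
  if (length(usable) < 3L) abort("need >= 3 patients with a defined predictor.")
  folds <- purrr::map_dfr(usable, function(i) {
    rest <- setdiff(usable, i)
    out <- preds$outcome[rest]
    if (length(unique(out)) < 2L) {
      inform(sprintf("fold %s skipped: single outcome class.",
                     preds$patient_id[i]))
      return(NULL)
    }
    m <- outcome_roc_metrics(preds$predictor[rest], out,
                             threshold = cutoff)
    bind_cols(tibble(fold = preds$patient_id[i]), m$metrics)
  })
  if (nrow(folds) == 0L) abort("no evaluable folds.")
  summary <- folds |>
    tidyr::pivot_longer(-"fold", names_to = "metric",
                        values_to = "value") |>
    group_by(.data$metric) |>
    summarise(median = median(.data$value, na.rm = TRUE),
              q25 = quantile(.data$value, 0.25, na.rm = TRUE),
              q75 = quantile(.data$value, 0.75, na.rm = TRUE),
              .groups = "drop")
  structure(list(summary = summary, folds = folds,
                 n_folds = nrow(folds), n_patients = length(usable),
                 cutoff = cutoff, category = category),
            class = "sr_loocv")
}

#' @export
print.sr_loocv <- function(x, ...) {
  cat(sprintf("<sr_loocv> %s, %d folds over %d patients%s\n",
              if (identical(x$category, "soz")) "SOZ ratio"
              else bm_label(x$category),
              x$n_folds, x$n_patients,
              if (is.null(x$cutoff)) " (Youden refit per fold)"
              else sprintf(" (fixed cut-off %.2f)", x$cutoff)))
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.sr_loocv <- function(x, ...) x$summary

#' Pseudo-prospective outcome prediction at a fixed cut-off
#'
#' Predicts a good outcome when the resection ratio exceeds `cutoff`
#' (strictly; a ratio of exactly 0.5 predicts poor) without any threshold
#' fitting, evaluated per leave-one-out fold and summarized as median (IQR).
#'
#' @inheritParams loocv_outcome
#' @param cutoff Resection-ratio cut-off (default 0.5).
#' @return An `sr_loocv` object.
#' @export
pseudo_prospective <- function(cohort, category, cutoff = 0.5) {
  loocv_outcome(cohort, category, cutoff = cutoff)
}

#' Clinically motivated patient subgroups
#'
#' `frequent_spikes`: patients whose median channel spike (`all_s`) rate is
#' strictly above the cut-point (default: the cohort's median of these
#' per-patient medians, recomputed). `no_fr_rare_spikes`: patients with zero
#' fast-ripple events and a median spike rate strictly below the cut-point.
#'
#' @param cohort Cohort tibble.
#' @param rule `"frequent_spikes"` or `"no_fr_rare_spikes"`.
#' @param cut Spikes/min cut-point; default the cohort median.
#' @return The filtered cohort tibble, with attribute `"cut"`.
#' @export
subgroup_filter <- function(cohort, rule = c("frequent_spikes",
                                             "no_fr_rare_spikes"),
                            cut = NULL) {
  rule <- match.arg(rule)
  med_spike <- purrr::map_dbl(cohort$rates, function(r) {
    median(r$rate[r$category == "all_s"])
  })
  n_fr <- purrr::map_dbl(cohort$rates, function(r) {
    sum(r$count[r$category == "all_fr"])
  })
  cut <- cut %||% median(med_spike)
  keep <- if (rule == "frequent_spikes") {
    med_spike > cut
  } else {
    n_fr == 0 & med_spike < cut
  }
  structure(cohort[keep, ], cut = cut)
}

#' Compare good and poor outcome groups
#'
#' Two-sided Wilcoxon rank-sum test on a per-patient summary: the mean
#' channel rate of a category, or its resection ratio.
#'
#' @param cohort Cohort tibble.
#' @param category Biomarker category code.
#' @param value `"mean_rate"` or `"resection_ratio"`.
#' @return List with group medians (IQR), `statistic`, `p_value`, sizes.
#' @export
compare_outcome_groups <- function(cohort, category,
                                   value = c("mean_rate",
                                             "resection_ratio")) {
  value <- match.arg(value)
  category <- match_category(category, several.ok = FALSE)
  v <- if (value == "mean_rate") {
    purrr::map_dbl(cohort$rates, function(r) {
      mean(r$rate[r$category == category])
    })
  } else {
    cohort_predictors(cohort, category)$predictor
  }
  good <- v[cohort$outcome == "good" & !is.na(v)]
  poor <- v[cohort$outcome == "poor" & !is.na(v)]
  if (length(good) < 2L || length(poor) < 2L) {
    abort("both outcome groups need >= 2 patients with defined values.")
  }
  wt <- suppressWarnings(wilcox.test(good, poor, exact = FALSE))
  if (length(unique(c(good, poor))) == 1L) wt$p.value <- 1
  list(category = category, value = value,
       good_median = median(good), good_iqr = quantile(good, c(0.25, 0.75)),
       poor_median = median(poor), poor_iqr = quantile(poor, c(0.25, 0.75)),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       n_good = length(good), n_poor = length(poor))
}
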