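#' Per-patient localization performance
#'
#' For each patient, builds the ROC of one biomarker's channel rates against
#' the SOZ or resected-area labels and computes the restricted-specificity
#' pAUC and sensitivity at fixed specificity levels. Channels without events
#' participate with rate 0. Patients whose channel labels are single-class
#' (e.g. nothing resected) are skipped with a message.
#'
#' @param cohort Cohort tibble ([synth_cohort()] layout: list-columns
#'   `rates` and `channels`).
#' @param category Biomarker category code.
#' @param region `"ra"` (resected area) or `"soz"`.
#' @param outcome_group Restrict to `"good"`, `"poor"` or `"all"` patients
#'   (default `"good"`, the convention for localization analyses).
#' @param spec_range,levels Forwarded to [partial_auc()].
#' @return Tibble with one row per evaluable patient: `patient_id`, `auc`,
#'   `pauc_raw`, `pauc_norm`, `sens_at_*`, and `median_spike_rate` (the
#'   patient's median `all_s` channel rate).
#' @export
localize_patients <- function(cohort, category, region = c("ra", "soz"),
                              outcome_group = c("good", "poor", "all"),
                              spec_range = c(0.85, 1),
                              levels = c(0.85, 0.90, 0.95)) {
  region <- match.arg(region)
  outcome_group <- match.arg(outcome_group)
  category <- match_category(category, several.ok = FALSE)
  keep <- if (outcome_group == "all") rep(TRUE, nrow(cohort)) else
    cohort$outcome == outcome_group
  purrr::map_dfr(which(keep), function(i) {
    sc <- channel_scores(cohort$rates[[i]], cohort$channels[[i]], category,
                         region)
    spikes <- channel_scores(cohort$rates[[i]], cohort$channels[[i]],
                             "all_s", region)
    if (length(unique(sc$label)) < 2L) {
      inform(paste0(cohort$patient_id[i],
                    ": single-class channel labels; skipped."))
      return(NULL)
    }
    roc <- build_roc(sc$score, sc$label)
    pa <- partial_auc(roc, spec_range, levels)
    bind_cols(tibble(patient_id = cohort$patient_id[i],
                     auc = attr(roc, "auc")),
              as_tibble(pa),
              tibble(median_spike_rate = median(spikes$score)))
  })
}

channel_scores <- function(rates, channels, category, region) {
  r <- rates |>
    filter(.data$category == !!category) |>
    select("channel_id", "rate")
  ch <- left_join(channels, r, by = "channel_id")
  tibble(
    channel_id = ch$channel_id,
    score = ifelse(is.na(ch$rate), 0, ch$rate),
    label = if (region == "ra") ch$is_resected else ch$is_soz
  )
}

#' Pooled group-level ROC across patients
#'
#' Pools every contact of the selected patients into one point set (rates as
#' scores, region membership as labels) and returns the [build_roc()] curve.
#'
#' @inheritParams localize_patients
#' @return An `sr_roc` object.
#' @export
localize_group_roc <- function(cohort, category, region = c("ra", "soz"),
                               outcome_group = c("good", "poor", "all")) {
  region <- match.arg(region)
  outcome_group <- match.arg(outcome_group)
  category <- match_category(category, several.ok = FALSE)
  keep <- if (outcome_group == "all") rep(TRUE, nrow(cohort)) else
    cohort$outcome == outcome_group
  pooled <- purrr::map_dfr(which(keep), function(i) {
    channel_scores(cohort$rates[[i]], cohort$channels[[i]], category, region)
  })
  build_roc(pooled$score, pooled$label)
}

#' Paired inside/outside rate comparison
#'
#' Per patient, the median channel rate inside and outside the region is
#' computed (channels without the biomarker contribute rate 0); the pairs
#' are compared with a two-sided Wilcoxon signed-rank test.
#'
#' @inheritParams localize_patients
#' @return List of class `sr_paired_test`: per-patient `pairs` tibble,
#'   group medians with IQR, the test `statistic` and `p_value`.
#' @export
compare_rates_in_out <- function(cohort, category, region = c("ra", "soz"),
                                 outcome_group = c("good", "poor", "all")) {
  region <- match.arg(region)
  outcome_group <- match.arg(outcome_group)
  category <- match_category(category, several.ok = FALSE)
  keep <- if (outcome_group == "all") rep(TRUE, nrow(cohort)) else
    cohort$outcome == outcome_group
  pairs <- purrr::map_dfr(which(keep), function(i) {
    sc <- channel_scores(cohort$rates[[i]], cohort$channels[[i]], category,
                         region)
    if (!any(sc$label) || all(sc$label)) return(NULL)
    tibble(patient_id = cohort$patient_id[i],
           inside = median(sc$score[sc$label]),
           outside = median(sc$score[!sc$label]))
  })
  if (nrow(pairs) < 2L) {
    abort("insufficient data: need >= 2 patients with both regions.")
  }
  wt <- suppressWarnings(
    wilcox.test(pairs$inside, pairs$outside, paired = TRUE,
                exact = FALSE, correct = TRUE)
  )
  if (all(pairs$inside == pairs$outside)) wt$p.value <- 1
  structure(list(
    category = category, region = region, outcome_group = outcome_group,
    pairs = pairs,
    inside_median = median(pairs$inside),
    inside_iqr = unname(quantile(pairs$inside, c(0.25, 0.75))),
    outside_median = median(pairs$outside),
    outside_iqr = unname(quantile(pairs$outside, c(0.25, 0.75))),
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n = nrow(pairs)
  ), class = "sr_paired_test")
}

#' @export
print.sr_paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired in/out %s comparison, %s (%s outcome, n = %d)\n",
    toupper(x$region), bm_label(x$category), x$outcome_group, x$n))
  cat(sprintf("  inside  %.3f (%.3f-%.3f) events/min\n", x$inside_median,
              x$inside_iqr[1], x$inside_iqr[2]))
  cat(sprintf("  outside %.3f (%.3f-%.3f) events/min\n", x$outside_median,
              x$outside_iqr[1], x$outside_iqr[2]))
  cat(sprintf("  Wilcoxon signed-rank V = %g, p = %.4g\n", x$statistic,
              x$p_value))
  invisible(x)
}

#' @export
tidy.sr_paired_test <- function(x, ...) {
  tibble(category = x$category, region = x$region,
         outcome_group = x$outcome_group, n = x$n,
         inside_median = x$inside_median, outside_median = x$outside_median,
         statistic = x$statistic, p_value = x$p_value)
}

#' Correlation between localization performance and spike rate
#'
#' Spearman rank correlation between each patient's normalized pAUC for a
#' category and their median spike (`all_s`) channel rate.
#'
#' @inheritParams localize_patients
#' @return List with `rho`, `p_value`, `n` and the per-patient tibble.
#' @export
correlate_pauc_spikerate <- function(cohort, category = "s_r",
                                     region = c("ra", "soz"),
                                     outcome_group = c("good", "poor",
                                                       "all")) {
  tab <- localize_patients(cohort, category, region, outcome_group)
  if (nrow(tab) < 5L) abort("need >= 5 patients with a defined pAUC.")
  if (length(unique(tab$pauc_norm)) < 2L ||
      length(unique(tab$median_spike_rate)) < 2L) {
    abort("constant input: correlation undefined.")
  }
  ct <- suppressWarnings(
    cor.test(tab$median_spike_rate, tab$pauc_norm, method = "spearman")
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(tab),
       data = tab)
}

#' Kruskal-Wallis test with Tukey-Kramer post hoc on rank means
#'
#' Omnibus Kruskal-Wallis test followed by all pairwise comparisons of mean
#' ranks using the studentized-range distribution with Tukey-Kramer
#' adjustment for unequal group sizes (the convention of MATLAB's
#' `multcompare` after `kruskalwallis`).
#'
#' @param values Numeric vector.
#' @param group Grouping vector (same length).
#' @return List with `statistic` (H), `p_value`, `df` and a `pairwise`
#'   tibble of corrected p-values.
#' @export
compare_groups_kw <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) abort("need >= 2 groups.")
  sizes <- table(group)
  if (any(sizes < 2L)) abort("every group needs >= 2 values.")
  if (length(unique(values)) == 1L) {
    lv <- levels(group)
    pw <- purrr::map_dfr(utils::combn(length(lv), 2, simplify = FALSE),
                         function(ij) tibble(group1 = lv[ij[1]],
                                             group2 = lv[ij[2]],
                                             mean_rank_diff = 0, p_adj = 1))
    return(list(statistic = 0, p_value = 1, df = length(lv) - 1L,
                pairwise = pw))
  }
  kw <- kruskal.test(values, group)
  N <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, group, mean)
  # ties-corrected rank variance
  ties <- table(rk)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  s2 <- N * (N + 1) / 12 * tie_corr
  lv <- levels(group)
  pw <- purrr::map_dfr(utils::combn(length(lv), 2, simplify = FALSE),
                       function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(s2 * (1 / sizes[i] + 1 / sizes[j]))
    q <- abs(mean_rank[i] - mean_rank[j]) / (se / sqrt(2))
    tibble(group1 = lv[i], group2 = lv[j],
           mean_rank_diff = unname(mean_rank[i] - mean_rank[j]),
           p_adj = stats::ptukey(q, nmeans = length(lv), df = Inf,
                                 lower.tail = FALSE))
  })
  list(statistic = unname(kw$statistic), p_value = kw$p.value,
       df = unname(kw$parameter), pairwise = pw)
}
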