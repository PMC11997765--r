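#' Plot biomarker rates inside versus outside a region
#'
#' Paired per-patient medians (one line per patient) inside and outside the
#' SOZ or resected area.
#'
#' @inheritParams compare_rates_in_out
#' @return A ggplot object.
#' @export
plot_rates_in_out <- function(cohort, category, region = c("ra", "soz"),
                              outcome_group = c("good", "poor", "all")) {
  res <- compare_rates_in_out(cohort, category, region, outcome_group)
  df <- tidyr::pivot_longer(res$pairs, c("inside", "outside"),
                            names_to = "where", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$where, y = .data$rate)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = NULL, y = "median channel rate (events/min)",
      title = sprintf("%s rates %s %s (p = %.3g)", bm_label(res$category),
                      "in/out", toupper(res$region), res$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot resection ratios by surgical outcome
#'
#' @param cohort Cohort tibble.
#' @param categories Biomarker categories to show (default the four
#'   headline ones).
#' @param cutoff Reference cut-off line (default 0.5).
#' @return A ggplot object.
#' @export
plot_resection_ratio <- function(cohort,
                                 categories = c("all_s", "all_r", "all_fr",
                                                "s_r"),
                                 cutoff = 0.5) {
  df <- purrr::map_dfr(categories, function(cat) {
    mutate(cohort_predictors(cohort, cat), category = bm_label(cat))
  }) |>
    filter(!is.na(.data$predictor))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$predictor)) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7) +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = "surgical outcome", y = "resection ratio") +
    ggplot2::theme_minimal()
}

#' Plot per-patient localization performance
#'
#' Normalized restricted-specificity pAUC per biomarker, with both chance
#' conventions drawn as reference lines.
#'
#' @param cohort Cohort tibble.
#' @param categories Categories to show (default all eleven).
#' @inheritParams localize_patients
#' @return A ggplot object.
#' @export
plot_pauc <- function(cohort, categories = bm_categories(),
                      region = c("ra", "soz")) {
  region <- match.arg(region)
  df <- purrr::map_dfr(categories, function(cat) {
    tab <- localize_patients(cohort, cat, region = region)
    if (nrow(tab)) mutate(tab, category = bm_label(cat)) else NULL
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$pauc_norm)) +
    ggplot2::geom_hline(yintercept = pauc_chance("half_max")$pauc_norm,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = pauc_chance("diagonal")$pauc_norm,
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "normalized pAUC",
                  title = sprintf("Localization of the %s, per patient",
                                  toupper(region)),
                  subtitle = "dashed: half-max chance; dotted: diagonal-ROC chance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
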