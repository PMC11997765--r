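#' Receiver operating characteristic over rate thresholds
#'
#' A unit (typically an iEEG contact) is predicted positive when its score
#' (typically a biomarker rate) is strictly greater than the threshold;
#' condition positives are the units inside the region of interest (RA or
#' SOZ). Thresholds scan every unique score plus the two extremes, so the
#' curve always contains the endpoints (sensitivity, specificity) = (0, 1)
#' and (1, 0).
#'
#' @param scores Numeric vector of per-unit scores.
#' @param labels Logical (or coercible) vector: `TRUE` = condition positive.
#' @return An object of class `sr_roc`: a tibble of operating points
#'   (`threshold`, `sensitivity`, `specificity`, `fpr`) with the full `auc`
#'   as attribute.
#' @export
#' @examples
#' roc <- build_roc(c(0, 1, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
#' glance(roc)
build_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    abort("`scores` and `labels` must be equal-length and NA-free.")
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort("degenerate labels: both classes must be present.")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) sum(scores > t & labels) / n_pos, 0)
  spec <- vapply(thr, function(t) sum(scores <= t & !labels) / n_neg, 0)
  out <- tibble(threshold = thr, sensitivity = sens, specificity = spec,
                fpr = 1 - spec)
  auc <- trapezoid(out$fpr, out$sensitivity)
  structure(out, class = c("sr_roc", class(out)),
            auc = auc, n_pos = n_pos, n_neg = n_neg)
}

trapezoid <- function(x, y) {
  o <- order(x)
  sum(diff(x[o]) * (head(y[o], -1) + tail(y[o], -1)) / 2)
}

#' @export
tidy.sr_roc <- function(x, ...) as_tibble(unclass(x)[c("threshold",
  "sensitivity", "specificity", "fpr")])

#' @export
glance.sr_roc <- function(x, ...) {
  tibble(auc = attr(x, "auc"), n_pos = attr(x, "n_pos"),
         n_neg = attr(x, "n_neg"), n_thresholds = nrow(x))
}

#' Sensitivity at fixed specificity levels
#'
#' For each level, returns the sensitivity of the achievable operating point
#' with the smallest specificity at or above the level (no interpolation);
#' among ties the more sensitive point is taken.
#'
#' @param roc An [build_roc()] object.
#' @param levels Specificity levels (default `c(0.85, 0.90, 0.95)`).
#' @return Tibble `(specificity_level, sensitivity, specificity)`.
#' @export
sens_at_spec <- function(roc, levels = c(0.85, 0.90, 0.95)) {
  stopifnot(inherits(roc, "sr_roc"))
  purrr::map_dfr(levels, function(lv) {
    ok <- roc$specificity >= lv - 1e-12
    sp_min <- min(roc$specificity[ok])
    at <- ok & abs(roc$specificity - sp_min) < 1e-12
    tibble(specificity_level = lv,
           sensitivity = max(roc$sensitivity[at]),
           specificity = sp_min)
  })
}

#' Restricted-specificity partial AUC
#'
#' Trapezoidal integral of sensitivity over the false-positive rate on
#' `[0, 1 - spec_range[1]]` (default specificity 85-100%, i.e. FPR 0-0.15),
#' with linear interpolation of the curve at the boundary. The normalized
#' value divides by the maximum possible area (the FPR width, 0.15 by
#' default) and ranges from 0 to 1.
#'
#' @param roc An [build_roc()] object.
#' @param spec_range Specificity range (default `c(0.85, 1)`).
#' @param levels Specificity levels forwarded to [sens_at_spec()].
#' @return Tibble of class `sr_pauc`: `pauc_raw`, `pauc_norm`, and
#'   `sens_at_0.85` etc.
#' @export
partial_auc <- function(roc, spec_range = c(0.85, 1),
                        levels = c(0.85, 0.90, 0.95)) {
  stopifnot(inherits(roc, "sr_roc"))
  fmax <- round(1 - spec_range[1], 12)
  pts <- tibble(fpr = roc$fpr, sens = roc$sensitivity) |>
    arrange(.data$fpr, .data$sens)
  inside <- pts[pts$fpr <= fmax + 1e-12, ]
  if (max(pts$fpr) > fmax) {
    # interpolate the ROC polyline at the FPR boundary
    above <- pts[pts$fpr > fmax, ][1, ]
    below <- inside[nrow(inside), ]
    s_b <- if (above$fpr > below$fpr) {
      below$sens + (above$sens - below$sens) *
        (fmax - below$fpr) / (above$fpr - below$fpr)
    } else below$sens
    inside <- bind_rows(inside, tibble(fpr = fmax, sens = s_b))
  }
  raw <- trapezoid(inside$fpr, inside$sens)
  raw <- min(max(raw, 0), fmax)  # guard floating-point overshoot
  sas <- sens_at_spec(roc, levels)
  out <- tibble(pauc_raw = raw, pauc_norm = raw / fmax)
  for (j in seq_len(nrow(sas))) {
    out[[paste0("sens_at_", format(sas$specificity_level[j]))]] <-
      sas$sensitivity[j]
  }
  structure(out, class = c("sr_pauc", class(out)))
}

#' Chance level of the restricted-specificity pAUC
#'
#' Two conventions are in circulation. `"half_max"` takes half of the
#' maximum possible area (0.075 raw / 0.5 normalized for specificity
#' 85-100%). `"diagonal"` integrates a true diagonal ROC
#' (sensitivity = FPR) over the restricted range, giving
#' `(1 - spec_range[1])^2 / 2` = 0.01125 raw / 0.075 normalized -- the value
#' an uninformative classifier actually attains. The two differ because half
#' the maximum is not the diagonal's area on a restricted range; both are
#' reported so either reference line can be drawn.
#'
#' @param convention `"half_max"` or `"diagonal"`.
#' @param spec_range Specificity range (default `c(0.85, 1)`).
#' @return Tibble `(convention, pauc_raw, pauc_norm)`.
#' @export
pauc_chance <- function(convention = c("half_max", "diagonal"),
                        spec_range = c(0.85, 1)) {
  convention <- match.arg(convention)
  fmax <- round(1 - spec_range[1], 12)
  raw <- if (convention == "half_max") {
    fmax * 1 / 2
  } else {
    # trapezoidal integral of the diagonal polyline on [0, fmax]
    trapezoid(c(0, fmax), c(0, fmax))
  }
  tibble(convention = convention, pauc_raw = raw, pauc_norm = raw / fmax)
}

#' @export
autoplot.sr_roc <- function(object, spec_range = c(0.85, 1), ...) {
  df <- tidy(object) |> arrange(.data$fpr, .data$sensitivity)
  fmax <- 1 - spec_range[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::annotate("rect", xmin = 0, xmax = fmax, ymin = 0, ymax = 1,
                      alpha = 0.08, fill = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-positive rate (1 - specificity)",
                  y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", attr(object, "auc")),
                  subtitle = "shaded: restricted-specificity pAUC region") +
    ggplot2::theme_minimal()
}
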