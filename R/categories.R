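#' Biomarker categories
#'
#' Interictal events are classified by their temporal co-occurrence (within a
#' +/- 50 ms window, same channel) into eleven categories: the three raw
#' tallies (`all_s`, `all_r`, `all_fr` -- every spike, ripple and fast ripple
#' regardless of company), the seven mutually exclusive cluster compositions
#' (`s_only`, `r_only`, `fr_only`, `s_r`, `s_fr`, `r_fr`, `s_r_fr`), and the
#' derived `s_hfo` (clusters containing a spike and at least one HFO).
#'
#' @return Character vector of the eleven canonical category codes.
#' @export
#' @examples
#' bm_categories()
bm_categories <- function() {
  c("all_s", "all_r", "all_fr",
    "s_only", "r_only", "fr_only",
    "s_r", "s_fr", "r_fr", "s_r_fr",
    "s_hfo")
}

# the seven exclusive cluster compositions, keyed by sorted type set
bm_cluster_categories <- function() {
  c("s_only", "r_only", "fr_only", "s_r", "s_fr", "r_fr", "s_r_fr")
}

#' @rdname bm_categories
#' @param category Category code(s), e.g. `"s_r"`.
#' @return `bm_label()` returns display labels (e.g. `"S + R"`).
#' @export
bm_label <- function(category) {
  labels <- c(
    all_s = "All S", all_r = "All R", all_fr = "All FR",
    s_only = "S only", r_only = "R only", fr_only = "FR only",
    s_r = "S + R", s_fr = "S + FR", r_fr = "R + FR",
    s_r_fr = "S + R + FR", s_hfo = "S + HFO"
  )
  unname(labels[match_category(category)])
}

match_category <- function(category, several.ok = TRUE) {
  out <- match.arg(tolower(category), bm_categories(), several.ok = several.ok)
  if (!several.ok && length(out) != 1L) {
    abort("`category` must be a single biomarker category code.")
  }
  out
}

event_types <- function() c("spike", "ripple", "fast_ripple")

# category code for a cluster's set of event types
category_from_types <- function(types) {
  has_s <- "spike" %in% types
  has_r <- "ripple" %in% types
  has_f <- "fast_ripple" %in% types
  key <- paste0(ifelse(has_s, "s", ""), ifelse(has_r, "r", ""),
                ifelse(has_f, "f", ""))
  switch(key,
    s = "s_only", r = "r_only", f = "fr_only",
    sr = "s_r", sf = "s_fr", rf = "r_fr", srf = "s_r_fr",
    abort("cluster with empty type set"))
}

#' Parse Engel outcome classes
#'
#' Engel class I (subclasses A-D) is a good surgical outcome; class II or
#' worse is poor. Parsing is case-insensitive and accepts Arabic ("1a", "3")
#' or Roman ("IA", "III") numerals.
#'
#' @param engel Character vector of Engel class labels.
#' @return Factor with levels `good`, `poor`.
#' @export
#' @examples
#' parse_engel(c("1a", "IB", "2", "IVb"))
parse_engel <- function(engel) {
  x <- tolower(gsub("[[:space:]]", "", as.character(engel)))
  roman <- c(iv = "4", iii = "3", ii = "2", i = "1")
  for (r in names(roman)) x <- sub(paste0("^", r), roman[[r]], x)
  ok <- grepl("^[1-4][a-d]?$", x)
  if (any(!ok)) {
    abort(paste0("unparseable Engel class: ",
                 paste(unique(engel[!ok]), collapse = ", ")))
  }
  factor(ifelse(startsWith(x, "1"), "good", "poor"),
         levels = c("good", "poor"))
}

lobe_levels <- function() c("temporal", "frontal", "parietal", "occipital", "other")
electrode_kinds <- function() c("grid", "strip", "depth")
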