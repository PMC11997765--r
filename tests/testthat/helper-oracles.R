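# Independent brute-force oracles used across the suite. These deliberately
# use the most literal O(n^2)/enumeration formulation so they share no code
# with the implementation they check.

# random event set over a few channels with mixed types
random_events <- function(n, n_channels = 3, t_max = 10) {
  ch <- sample(sprintf("E%d", seq_len(n_channels)), n, replace = TRUE)
  peak <- runif(n, 0, t_max)
  half <- runif(n, 0.005, 0.03)
  tibble::tibble(
    channel_id = ch,
    onset = peak - half, offset = peak + half, peak_time = peak,
    event_type = sample(c("spike", "ripple", "fast_ripple"), n,
                        replace = TRUE),
    peak_frequency = NA_real_, n_oscillations = NA_integer_,
    qc_status = NA_character_
  )
}

# connected components of the |dt| <= w relation by explicit pairwise scan
oracle_clusters <- function(events, window_ms = 50) {
  w <- window_ms / 1000
  events$oracle_comp <- NA_integer_
  comp <- 0L
  for (ch in unique(events$channel_id)) {
    idx <- which(events$channel_id == ch)
    n <- length(idx)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      adj[i, j] <- abs(events$peak_time[idx[i]] -
                         events$peak_time[idx[j]]) <= w + 1e-12
    }
    assigned <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (!is.na(assigned[i])) next
      comp <- comp + 1L
      frontier <- i
      while (length(frontier)) {
        assigned[frontier] <- comp
        nxt <- unique(unlist(lapply(frontier, function(k) which(adj[k, ]))))
        frontier <- setdiff(nxt, which(!is.na(assigned)))
      }
    }
    events$oracle_comp[idx] <- assigned
  }
  events
}

# 11-category counts from oracle components, channel x category
oracle_category_counts <- function(events_with_comp) {
  ev <- events_with_comp
  out <- list()
  for (ch in unique(ev$channel_id)) {
    e <- ev[ev$channel_id == ch, ]
    cnt <- c(all_s = sum(e$event_type == "spike"),
             all_r = sum(e$event_type == "ripple"),
             all_fr = sum(e$event_type == "fast_ripple"),
             s_only = 0, r_only = 0, fr_only = 0, s_r = 0, s_fr = 0,
             r_fr = 0, s_r_fr = 0, s_hfo = 0)
    for (cc in unique(e$oracle_comp)) {
      types <- sort(unique(e$event_type[e$oracle_comp == cc]))
      key <- paste(types, collapse = "+")
      cat_name <- switch(key,
        "spike" = "s_only", "ripple" = "r_only",
        "fast_ripple" = "fr_only",
        "ripple+spike" = "s_r", "fast_ripple+spike" = "s_fr",
        "fast_ripple+ripple" = "r_fr",
        "fast_ripple+ripple+spike" = "s_r_fr")
      cnt[cat_name] <- cnt[cat_name] + 1
      if ("spike" %in% types && any(c("ripple", "fast_ripple") %in% types)) {
        cnt["s_hfo"] <- cnt["s_hfo"] + 1
      }
    }
    out[[ch]] <- tibble::tibble(channel_id = ch, category = names(cnt),
                                count = unname(cnt))
  }
  dplyr::bind_rows(out)
}

# exhaustive-threshold ROC: every candidate threshold evaluated literally
oracle_roc_points <- function(scores, labels, thresholds) {
  t(vapply(thresholds, function(t) {
    pred <- scores > t
    c(sens = sum(pred & labels) / sum(labels),
      spec = sum(!pred & !labels) / sum(!labels))
  }, c(sens = 0, spec = 0)))
}

# AUC by Mann-Whitney concordant-pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# best Youden threshold by literal scan over all thresholds
oracle_youden <- function(scores, labels) {
  thr <- c(-Inf, sort(unique(scores)), Inf)
  pts <- oracle_roc_points(scores, labels, thr)
  j <- pts[, "sens"] + pts[, "spec"] - 1
  max(j)
}

# Barnard p by direct enumeration loops (row totals fixed, pooled z)
oracle_barnard <- function(x, grid = seq(0.001, 0.999, by = 0.001)) {
  n1 <- sum(x[1, ]); n2 <- sum(x[2, ])
  zfun <- function(k1, k2) {
    p1 <- k1 / n1; p2 <- k2 / n2; pp <- (k1 + k2) / (n1 + n2)
    v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
    if (v == 0) 0 else (p1 - p2) / sqrt(v)
  }
  z0 <- abs(zfun(x[1, 1], x[2, 1]))
  best <- 0
  for (p in grid) {
    tot <- 0
    for (k1 in 0:n1) for (k2 in 0:n2) {
      if (abs(zfun(k1, k2)) >= z0 - 1e-9) {
        tot <- tot + dbinom(k1, n1, p) * dbinom(k2, n2, p)
      }
    }
    best <- max(best, tot)
  }
  best
}

# exact paired signed-rank p by enumerating all sign assignments
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  ev <- n * (n + 1) / 4
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
}

# spearman rho by the rank formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

small_cohort <- function(seed = 42, n_patients = 12, n_good = 8, ...) {
  synth_cohort(cohort_params(n_patients = n_patients, n_good = n_good,
                             seed = seed, ...))
}
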