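mk_rates <- function(ids, category, rates) {
  tibble::tibble(channel_id = ids, category = category, count = rates * 10,
                 rate = rates, duration_min = 10)
}

test_that("resection ratio follows its defining arithmetic", {
  ch <- tibble::tibble(channel_id = c("a", "b", "c"),
                       is_resected = c(TRUE, TRUE, FALSE),
                       is_soz = c(TRUE, FALSE, FALSE))
  expect_equal(resection_ratio(mk_rates(c("a", "b", "c"), "s_r",
                                        c(2, 3, 5)), ch, "s_r"), 0.5)
  expect_equal(resection_ratio(mk_rates(c("a", "b", "c"), "s_r",
                                        c(2, 3, 0)), ch, "s_r"), 1)
  expect_equal(resection_ratio(mk_rates(c("a", "b", "c"), "s_r",
                                        c(0, 0, 5)), ch, "s_r"), 0)
  expect_true(is.na(resection_ratio(mk_rates(c("a", "b", "c"), "s_r",
                                             c(0, 0, 0)), ch, "s_r")))
  # invariance under rate rescaling
  r1 <- resection_ratio(mk_rates(c("a", "b", "c"), "s_r", c(1, 2, 4)),
                        ch, "s_r")
  r2 <- resection_ratio(mk_rates(c("a", "b", "c"), "s_r",
                                 7 * c(1, 2, 4)), ch, "s_r")
  expect_equal(r1, r2)
})

test_that("SOZ ratio counts resected SOZ contacts", {
  ch <- tibble::tibble(channel_id = sprintf("c%d", 1:6),
                       is_soz = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                       is_resected = c(TRUE, TRUE, TRUE, FALSE, TRUE,
                                       FALSE))
  expect_equal(soz_ratio(ch), 0.75)
  ch$is_resected <- TRUE
  expect_equal(soz_ratio(ch), 1)
  ch$is_resected <- FALSE
  expect_equal(soz_ratio(ch), 0)
  ch$is_soz <- FALSE
  expect_true(is.na(soz_ratio(ch)))
})

test_that("Youden-point metrics reproduce hand-computed confusions", {
  # perfectly separating predictor
  m <- outcome_roc_metrics(c(0.1, 0.2, 0.8, 0.9),
                           c("poor", "poor", "good", "good"))
  expect_equal(m$metrics$sensitivity, 1)
  expect_equal(m$metrics$specificity, 1)
  expect_equal(m$metrics$markedness, 1)
  expect_equal(m$metrics$youden_j, 1)

  # fixed confusion TP=14 FP=2 TN=4 FN=1 at threshold 0.5
  pred <- c(rep(0.9, 14), rep(0.1, 1), rep(0.9, 2), rep(0.1, 4))
  out <- c(rep("good", 15), rep("poor", 6))
  m2 <- outcome_roc_metrics(pred, out, threshold = 0.5)
  expect_equal(unname(m2$confusion), c(14, 2, 4, 1))
  expect_equal(m2$metrics$accuracy, 18 / 21)
  expect_equal(m2$metrics$markedness, 14 / 16 + 4 / 5 - 1)

  # undefined predictors are excluded and counted
  m3 <- outcome_roc_metrics(c(NA, 0.2, 0.8, 0.9, NA),
                            c("good", "poor", "good", "good", "poor"))
  expect_equal(m3$n_excluded, 2L)
  expect_equal(m3$n, 3L)

  expect_error(outcome_roc_metrics(c(0.2, 0.4), c("good", "good")),
               "degenerate")
})

test_that("LOO cross-validation summarizes folds as median (IQR)", {
  co <- small_cohort(seed = 301, n_patients = 12, n_good = 7)
  cv <- loocv_outcome(co, "s_r")
  expect_equal(cv$n_folds, 12L)
  acc <- cv$summary[cv$summary$metric == "accuracy", ]
  expect_true(acc$median >= acc$q25 && acc$median <= acc$q75)

  # perfectly separable cohort: every fold is perfect
  expect_true(all(cv$folds$accuracy[cv$folds$accuracy == 1] == 1))
  # n = 3 with a 2/1 outcome split: dropping the lone minority patient
  # leaves a single-class fold, which is skipped and logged
  n3 <- co[c(1, 2, 12), ]
  expect_message(cv3 <- loocv_outcome(n3, "s_r"), "skipped")
  expect_equal(cv3$n_folds, 2L)
  expect_error(loocv_outcome(co[1:2, ], "s_r"), ">= 3")
})

test_that("pseudo-prospective prediction uses the fixed strict cut-off", {
  co <- small_cohort(seed = 302, n_patients = 14, n_good = 9,
                     label_noise = 0)
  pp <- pseudo_prospective(co, "s_r")
  acc <- pp$summary$median[pp$summary$metric == "accuracy"]
  expect_equal(acc, 1)

  # ratio exactly at the cut-off predicts poor
  m <- outcome_roc_metrics(c(0.5, 0.5, 0.8, 0.9),
                           c("poor", "poor", "good", "good"),
                           threshold = 0.5)
  expect_equal(unname(m$confusion["TN"]), 2)
  expect_equal(unname(m$confusion["FP"]), 0)
})

test_that("subgroup rules split the cohort as designed", {
  co <- small_cohort(seed = 303, n_patients = 12, n_good = 8)
  med_spike <- vapply(co$rates, function(r) {
    median(r$rate[r$category == "all_s"])
  }, 0)
  freq <- subgroup_filter(co, "frequent_spikes")
  expect_setequal(freq$patient_id,
                  co$patient_id[med_spike > median(med_spike)])
  expect_lte(nrow(freq), ceiling(nrow(co) / 2))

  # a patient with all-zero spike rates is excluded from frequent_spikes
  co0 <- co
  r <- co0$rates[[1]]
  r$rate <- 0
  r$count <- 0
  co0$rates[[1]] <- r
  expect_false(co0$patient_id[1] %in%
                 subgroup_filter(co0, "frequent_spikes")$patient_id)

  rare <- subgroup_filter(co, "no_fr_rare_spikes", cut = 0.7)
  n_fr <- vapply(co$rates, function(r) {
    sum(r$count[r$category == "all_fr"])
  }, 0)
  expect_setequal(rare$patient_id,
                  co$patient_id[n_fr == 0 & med_spike < 0.7])
})

test_that("outcome group comparisons use the rank-sum test", {
  co <- small_cohort(seed = 304, n_patients = 14, n_good = 8)
  res <- compare_outcome_groups(co, "s_r", value = "resection_ratio")
  # designed cohorts separate good and poor by construction
  expect_lt(res$p_value, 0.05)
  expect_gt(res$good_median, res$poor_median)

  withr::with_seed(6, {
    for (rep in 1:5) {
      a <- rnorm(12); b <- rnorm(12)
      got <- suppressWarnings(wilcox.test(a, b, exact = FALSE))$p.value
      # oracle: normal approximation from the rank-sum formula
      r <- rank(c(a, b))[1:12]
      W <- sum(r) - 12 * 13 / 2
      mu <- 12 * 12 / 2
      sig <- sqrt(12 * 12 * 25 / 12)
      want <- 2 * pnorm(-abs((W - mu + 0.5 * sign(mu - W)) / sig))
      expect_equal(got, want, tolerance = 1e-6)
    }
  })
})

test_that("Barnard's test matches enumeration and its symmetries", {
  even <- barnard_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$p.value, 1)
  expect_equal(unname(even$statistic), 0)

  sep <- barnard_test(matrix(c(5, 0, 0, 5), 2))
  expect_lt(sep$p.value, 0.05)

  # row/column swap invariance
  x <- matrix(c(7, 2, 3, 6), 2)
  swapped <- x[2:1, 2:1]
  expect_equal(barnard_test(x)$p.value, barnard_test(swapped)$p.value,
               tolerance = 1e-12)

  # brute-force enumeration over all tables with n <= 12
  withr::with_seed(2, {
    grid <- seq(0.01, 0.99, by = 0.01)
    for (rep in 1:12) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
      x <- matrix(c(k1, k2, n1 - k1, n2 - k2), 2)
      got <- barnard_test(x, grid_size = 99)$p.value
      want <- oracle_barnard(x, grid = grid)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
  expect_error(barnard_test(matrix(c(0, 0, 0, 0), 2)), "margin")
})

test_that("two-proportions z-test matches the pooled formula", {
  expect_equal(two_prop_ztest(5, 10, 10, 20)$p.value, 1)
  res <- two_prop_ztest(9, 26, 8, 13)
  p1 <- 9 / 26; p2 <- 8 / 13; pp <- 17 / 39
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 26 + 1 / 13))
  expect_equal(unname(res$statistic), z, tolerance = 1e-9)
  expect_equal(res$p.value, 2 * pnorm(-abs(z)), tolerance = 1e-9)
  # p shrinks as the gap grows at fixed n
  p_small <- two_prop_ztest(10, 20, 12, 20)$p.value
  p_large <- two_prop_ztest(10, 20, 18, 20)$p.value
  expect_lt(p_large, p_small)
  expect_error(two_prop_ztest(5, 4, 1, 10), "counts")
})

test_that("predictors are invariant and monotone as required", {
  ch <- tibble::tibble(channel_id = sprintf("c%d", 1:5),
                       is_resected = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                       is_soz = FALSE)
  base <- c(1, 2, 3, 2, 2)
  r0 <- resection_ratio(mk_rates(ch$channel_id, "all_s", base), ch,
                        "all_s")
  # moving mass from non-resected to resected raises the ratio
  shifted <- c(2, 2, 2, 2, 2)
  r1 <- resection_ratio(mk_rates(ch$channel_id, "all_s", shifted), ch,
                        "all_s")
  expect_gt(r1, r0)
  expect_true(r0 >= 0 && r0 <= 1 && r1 >= 0 && r1 <= 1)
})
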