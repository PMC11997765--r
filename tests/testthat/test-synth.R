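test_that("background noise hits its target RMS and spectral slope", {
  rec <- synth_background(2, 60, 2000, alpha = 0, rms = 10, seed = 1)
  rms <- apply(rec$signal, 1, function(v) sqrt(mean(v^2)))
  expect_true(all(rms > 9.5 & rms < 10.5))

  pink <- synth_background(1, 60, 2000, alpha = 1, rms = 10, seed = 2)
  sp <- stats::spec.pgram(stats::ts(pink$signal[1, ], frequency = 2000),
                          plot = FALSE, taper = 0.1)
  keep <- sp$freq >= 1 & sp$freq <= 200
  slope <- stats::coef(stats::lm(log10(sp$spec[keep]) ~
                                   log10(sp$freq[keep])))[2]
  expect_lt(abs(slope - (-1)), 0.2)

  expect_error(synth_background(1, 10, 1000, alpha = -1, seed = 1),
               "alpha")
})

test_that("generation is deterministic given the seed", {
  a <- synth_background(2, 5, 1000, seed = 9)
  b <- synth_background(2, 5, 1000, seed = 9)
  expect_identical(a$signal, b$signal)

  p <- synth_params(n_channels = 8, duration = 120)
  expect_identical(synth_events(p, seed = 3), synth_events(p, seed = 3))

  cp <- cohort_params(n_patients = 6, n_good = 4, seed = 5)
  expect_identical(synth_cohort(cp), synth_cohort(cp))
})

test_that("event waveforms concentrate energy in their class band", {
  fs <- 2000
  in_band_energy <- function(w, band) {
    pad <- c(rep(0, fs), w, rep(0, fs))
    sum(bandpass(pad, band, fs)^2) / sum(pad^2)
  }
  r <- synth_event_waveform("ripple", f0 = 120, n_cycles = 8,
                            amplitude = 50, sampling_rate = fs)
  expect_equal(length(r), round(8 / 120 * fs))
  expect_equal(max(abs(r)), 50, tolerance = 0.01)
  expect_gt(in_band_energy(r, c(80, 250)), 0.9)
  expect_lt(in_band_energy(r, c(250, 500)), 0.05)

  f <- synth_event_waveform("fast_ripple", f0 = 300, n_cycles = 6,
                            amplitude = 50, sampling_rate = fs)
  expect_gt(in_band_energy(f, c(250, 500)), 0.9)
  expect_lt(in_band_energy(f, c(80, 250)), 0.2)

  s <- synth_event_waveform("spike", amplitude = 80, sampling_rate = fs)
  pad <- c(rep(0, fs), s, rep(0, fs))
  low <- spikeripples:::butter_bandpass(pad, c(0.5, 70), fs)
  expect_gt(sum(low^2) / sum(pad^2), 0.9)

  expect_error(synth_event_waveform("ripple", f0 = 60), "f0")
  expect_error(synth_event_waveform("fast_ripple", f0 = 1200,
                                    sampling_rate = 2000), "f0|Nyquist")
  expect_error(synth_event_waveform("ripple", f0 = 120, n_cycles = 3),
               "n_cycles")
})

test_that("injected event counts follow the planned Poisson rates", {
  p <- synth_params(n_channels = 1, duration = 600, spike_rate = 2,
                    ripple_rate = 0, fr_rate = 0,
                    p_cooccur = list(s_r = 0, s_fr = 0, s_r_fr = 0,
                                     r_fr = 0),
                    n_soz_channels = 0, n_resected_channels = 0)
  counts <- vapply(1:200, function(s) nrow(synth_events(p, seed = s)), 0)
  expect_gt(mean(counts), 18)
  expect_lt(mean(counts), 22)

  zero <- synth_params(n_channels = 2, duration = 60, spike_rate = 0,
                       ripple_rate = 0, fr_rate = 0,
                       p_cooccur = list(s_r = 0, s_fr = 0, s_r_fr = 0,
                                        r_fr = 0),
                       n_soz_channels = 1, n_resected_channels = 1)
  expect_equal(nrow(synth_events(zero, seed = 1)), 0L)
})

test_that("the inside multiplier doubles rates in the SOZ/RA", {
  p <- synth_params(n_channels = 8, duration = 1800, n_soz_channels = 4,
                    n_resected_channels = 4)
  ch <- spikeripples:::synth_channels(p)
  ratios <- vapply(1:50, function(s) {
    ev <- suppressWarnings(synth_events(p, seed = s))
    sp <- ev[ev$event_type == "spike", ]
    n_in <- sum(sp$channel_id %in% ch$channel_id[ch$is_soz])
    n_in / (nrow(sp) - n_in)
  }, 0)
  expect_gt(mean(ratios), 1.6)
  expect_lt(mean(ratios), 2.4)
})

test_that("events stay clear of segment edges and keep planned co-occurrence", {
  p <- synth_params(n_channels = 8, duration = 300)
  ev <- synth_events(p, seed = 13)
  expect_true(all(ev$peak_time > 0.05))
  expect_true(all(ev$peak_time < 300 - 0.05))
  # companions sit within +/- 50 ms of their cluster anchor: successive
  # events on a channel either belong to one planned cluster (gap <= 0.1 s,
  # the width of a +/- 50 ms jitter window) or are separated by the 0.25 s
  # anchor dead time
  gaps <- ev |>
    dplyr::arrange(channel_id, peak_time) |>
    dplyr::group_by(channel_id) |>
    dplyr::mutate(gap = c(Inf, diff(peak_time))) |>
    dplyr::pull(gap)
  expect_true(all(gaps <= 0.1 + 1e-9 | gaps >= 0.15))
})

test_that("cohort design enforces the outcome rule and label noise", {
  cp0 <- cohort_params(n_patients = 10, n_good = 6, label_noise = 0,
                       seed = 3)
  co0 <- synth_cohort(cp0)
  expect_equal(sum(co0$designed_outcome == "good"), 6L)
  agree <- (co0$rule_ratio > 0.5) == (co0$outcome == "good")
  expect_true(all(agree))
  # realized ratios always on the designed side
  expect_true(all(co0$rule_ratio[co0$designed_outcome == "good"] > 0.5))
  expect_true(all(co0$rule_ratio[co0$designed_outcome == "poor"] < 0.5))

  flips <- vapply(1:100, function(s) {
    co <- synth_cohort(cohort_params(n_patients = 40, n_good = 26,
                                     label_noise = 0.1, seed = s))
    sum(co$outcome != co$designed_outcome)
  }, 0)
  expect_gt(mean(flips), 2.8)
  expect_lt(mean(flips), 5.2)
})

test_that("direct count generation matches the event-level pipeline", {
  cp <- cohort_params(n_patients = 3, n_good = 2, seed = 11)
  co_ev <- synth_cohort(cp, events = TRUE)
  for (i in seq_len(nrow(co_ev))) {
    clustered <- build_clusters(co_ev$events[[i]])
    counts <- categorize_events(clustered,
                                co_ev$channels[[i]]$channel_id)
    rates <- compute_rates(counts, co_ev$duration_min[i])
    stored <- co_ev$rates[[i]]
    merged <- dplyr::inner_join(
      rates, stored, by = c("channel_id", "category"),
      suffix = c("_pipe", "_direct"))
    expect_equal(merged$count_pipe, merged$count_direct)
  }
})

test_that("infeasible designs raise a diagnostic", {
  cp <- cohort_params(
    n_patients = 2, n_good = 1, seed = 1,
    base = synth_params(duration = 60, spike_rate = 0, ripple_rate = 0,
                        fr_rate = 0,
                        p_cooccur = list(s_r = 0, s_fr = 0, s_r_fr = 0,
                                         r_fr = 0)))
  expect_error(synth_cohort(cp), "no events")
  expect_error(synth_params(spike_rate = -1), ">= 0")
  expect_error(cohort_params(n_patients = 5, n_good = 9), "n_good")
  expect_error(cohort_params(label_noise = 0.7), "label_noise")
})
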