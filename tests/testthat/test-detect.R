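# shared fixture: 1/f background with bursts injected at known times
inject_bursts <- function(type, f0, n_cycles, band, seed, duration = 300,
                          fs = 2000, snr = 5, period = 15) {
  rec <- synth_background(1, duration, fs, alpha = 1, rms = 20, seed = seed)
  x <- rec$signal[1, ]
  band_rms <- sqrt(mean(bandpass(x, band, fs)^2))
  truth_t <- seq(5, duration - 5, by = period)
  amp <- snr * sqrt(2) * band_rms
  for (t0 in truth_t) {
    w <- synth_event_waveform(type, f0 = f0, n_cycles = n_cycles,
                              amplitude = amp, sampling_rate = fs)
    i0 <- round(t0 * fs)
    x[i0:(i0 + length(w) - 1)] <- x[i0:(i0 + length(w) - 1)] + w
  }
  ref <- tibble::tibble(channel_id = "CH", onset = truth_t,
                        offset = truth_t + n_cycles / f0,
                        peak_time = truth_t + n_cycles / f0 / 2,
                        event_type = type)
  list(x = x, ref = validate_events(ref), fs = fs)
}

test_that("injected ripple bursts are detected with accurate peak times", {
  fx <- inject_bursts("ripple", 120, 8, c(80, 250), seed = 21)
  ev <- detect_hfo_channel(fx$x, fx$fs, hfo_params(band = c(80, 250)))
  mm <- match_events(ev, fx$ref, tolerance = 50)
  expect_gte(mm$sensitivity, 0.9)
  expect_gte(mm$precision, 0.9)
  expect_lt(max(mm$matches$dt), 0.010)
  expect_true(all(ev$peak_frequency > 80 & ev$peak_frequency < 250))
})

test_that("injected fast-ripple bursts are detected in their own band", {
  fx <- inject_bursts("fast_ripple", 300, 8, c(250, 500), seed = 22)
  ev <- detect_hfo_channel(fx$x, fx$fs, hfo_params(band = c(250, 500)))
  mm <- match_events(ev, fx$ref, tolerance = 50)
  expect_gte(mm$sensitivity, 0.9)
  expect_gte(mm$precision, 0.9)
  expect_true(all(ev$peak_frequency > 250))
})

test_that("3-cycle bursts fail the oscillation screen", {
  fs <- 2000
  x <- synth_background(1, 60, fs, alpha = 1, rms = 20,
                        seed = 23)$signal[1, ]
  band_rms <- sqrt(mean(bandpass(x, c(80, 250), fs)^2))
  # n_cycles >= 4 is enforced by the waveform generator; build 3 cycles
  # directly with the same Hann-windowed shape
  n <- round(3 / 120 * fs)
  u <- seq(0, 1, length.out = n)
  w <- sin(2 * pi * 3 * u) * 0.5 * (1 - cos(2 * pi * u))
  w <- w * (8 * sqrt(2) * band_rms) / max(abs(w))
  for (t0 in seq(5, 55, by = 5)) {
    i0 <- round(t0 * fs)
    x[i0:(i0 + n - 1)] <- x[i0:(i0 + n - 1)] + w
  }
  ev <- detect_hfo_channel(x, fs, hfo_params(band = c(80, 250)),
                           keep_rejected = TRUE)
  hits <- ev[ev$onset > 4, ]  # candidates at the injection sites
  expect_true(all(hits$qc_status == "rejected_short"))
  expect_equal(nrow(detect_hfo_channel(x, fs,
                                       hfo_params(band = c(80, 250)))), 0L)
})

test_that("raising the threshold never increases detections and shifts are tracked", {
  fx <- inject_bursts("ripple", 140, 8, c(80, 250), seed = 24,
                      duration = 120)
  n_prev <- Inf
  for (th in c(3, 5, 7, 9)) {
    n_th <- nrow(detect_hfo_channel(fx$x, fx$fs,
                                    hfo_params(band = c(80, 250),
                                               threshold_sd = th)))
    expect_lte(n_th, n_prev)
    n_prev <- n_th
  }
  # translation equivariance
  k <- 4321
  ev0 <- detect_hfo_channel(fx$x, fx$fs, hfo_params(band = c(80, 250)))
  ev1 <- detect_hfo_channel(c(rep(0, k), fx$x), fx$fs,
                            hfo_params(band = c(80, 250)))
  shifted <- ev1$peak_time - k / fx$fs
  matched <- outer(ev0$peak_time, shifted,
                   function(a, b) abs(a - b) < 2e-3)
  expect_true(all(rowSums(matched) >= 1))
})

test_that("pure noise rarely produces detections", {
  fs <- 2000
  n_fp <- vapply(1:25, function(s) {
    x <- withr::with_seed(s, rnorm(60 * fs) * 10)
    nrow(detect_hfo_channel(x, fs, hfo_params(band = c(80, 250))))
  }, 0)
  expect_gte(mean(n_fp == 0), 0.95)
})

test_that("QC accepts genuine bursts and rejects steps and clicks", {
  fs <- 2000
  # genuine windowed 300 Hz sinusoid
  x <- synth_background(1, 10, fs, alpha = 1, rms = 10,
                        seed = 31)$signal[1, ]
  w <- synth_event_waveform("fast_ripple", f0 = 300, n_cycles = 8,
                            amplitude = 40, sampling_rate = fs)
  x[8000:(8000 + length(w) - 1)] <- x[8000:(8000 + length(w) - 1)] + w
  ev <- detect_hfo_channel(x, fs, hfo_params(band = c(250, 500)))
  q <- qc_hfo(ev, new_recording(matrix(x, 1), fs, "CH"), c(250, 500))
  expect_true(all(q$qc_status == "accepted"))
  expect_gte(nrow(q), 1)

  # step discontinuity: Gibbs ringing after filtering
  xs <- synth_background(1, 10, fs, alpha = 1, rms = 10,
                         seed = 32)$signal[1, ]
  xs[10000:length(xs)] <- xs[10000:length(xs)] + 150
  cand <- detect_hfo_channel(xs, fs, hfo_params(band = c(80, 250)),
                             keep_rejected = TRUE)
  at_step <- cand[abs(cand$peak_time - 5) < 0.1, ]
  expect_gte(nrow(at_step), 1)
  qs <- qc_hfo(at_step, new_recording(matrix(xs, 1), fs, "CH"), c(80, 250))
  expect_true(all(qs$qc_status == "rejected_gibbs"))

  # broadband click
  xc <- synth_background(1, 10, fs, alpha = 1, rms = 10,
                         seed = 33)$signal[1, ]
  xc[10000] <- xc[10000] + 400
  cand_c <- detect_hfo_channel(xc, fs, hfo_params(band = c(80, 250)),
                               keep_rejected = TRUE)
  at_click <- cand_c[abs(cand_c$peak_time - 5) < 0.1, ]
  expect_gte(nrow(at_click), 1)
  qc <- qc_hfo(at_click, new_recording(matrix(xc, 1), fs, "CH"),
               c(80, 250))
  expect_true(all(qc$qc_status == "rejected_blob"))
})

test_that("the spike stand-in recovers injected spikes", {
  fs <- 2000
  rec <- synth_background(4, 600, fs, alpha = 1, rms = 20, seed = 31)
  truth <- list()
  withr::with_seed(5, {
    for (ci in 1:4) {
      x <- rec$signal[ci, ]
      lf_rms <- sqrt(mean(spikeripples:::butter_bandpass(x, c(1, 70),
                                                         fs)^2))
      tt <- seq(10, 590, by = 30) + runif(20, -5, 5)
      amp <- 5 * sqrt(2) * lf_rms
      for (t0 in tt) {
        w <- synth_event_waveform("spike", amplitude = amp,
                                  sampling_rate = fs)
        i0 <- round(t0 * fs)
        rec$signal[ci, i0:(i0 + length(w) - 1)] <-
          rec$signal[ci, i0:(i0 + length(w) - 1)] + w
      }
      truth[[ci]] <- tibble::tibble(
        channel_id = rec$channel_ids[ci], onset = tt, offset = tt + 0.06,
        peak_time = tt + 0.03, event_type = "spike")
    }
  })
  pre <- preprocess_for_spikes(rec)
  ev <- detect_spikes_standin(pre)
  mm <- match_events(ev, dplyr::bind_rows(truth), tolerance = 100)
  expect_gte(mm$sensitivity, 0.9)
  expect_gte(mm$precision, 0.9)

  # flat signal: nothing to detect
  flat <- new_recording(matrix(0, 2, 2 * fs), fs, c("A", "B"))
  expect_equal(nrow(detect_spikes_standin(flat)), 0L)
  # infinite threshold endpoint
  expect_equal(nrow(detect_spikes_standin(pre,
                                          spike_params(z_threshold = Inf))),
               0L)
})

test_that("event matching arithmetic is exact", {
  ref <- validate_events(tibble::tibble(
    channel_id = "A", onset = 1:5 - 0.01, offset = 1:5 + 0.01,
    peak_time = as.numeric(1:5), event_type = "spike"))
  same <- match_events(ref, ref, tolerance = 50)
  expect_equal(same$sensitivity, 1)
  expect_equal(same$precision, 1)

  extra <- 7:11 + 0.4
  spurious <- validate_events(tibble::tibble(
    channel_id = "A", onset = c(1:5, extra) - 0.01,
    offset = c(1:5, extra) + 0.01,
    peak_time = c(1:5, extra), event_type = "spike"))
  res <- match_events(spurious, ref, tolerance = 50)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$precision, 5 / 10)

  shifted <- dplyr::mutate(ref, peak_time = peak_time + 0.2,
                           onset = onset + 0.2, offset = offset + 0.2)
  expect_equal(match_events(shifted, ref, tolerance = 100)$sensitivity, 0)
  expect_error(match_events(ref, ref, tolerance = -1), "tolerance")
})
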