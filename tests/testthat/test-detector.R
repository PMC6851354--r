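test_that("band-pass filter has unit passband and steep stopband", {
  fs <- 2000
  t <- (1:(4 * fs)) / fs
  pass <- bandpass_filter(sin(2 * pi * 150 * t), "ripple", fs)
  mid <- (fs):(3 * fs)
  expect_gt(max(abs(pass[mid])), 0.95)
  expect_lt(max(abs(pass[mid])), 1.05)

  stopb <- bandpass_filter(sin(2 * pi * 50 * t), "ripple", fs)
  expect_lt(20 * log10(max(abs(stopb[mid]))), -40)

  expect_identical(bandpass_filter(rep(0, 1000), "ripple", fs),
                   rep(0, 1000))
  expect_error(bandpass_filter(rnorm(100), "fast_ripple", 900),
               "invalid-argument")
})

test_that("Th_amp scales with the signal and matches the Rayleigh law", {
  fs <- 2000
  cfg <- detector_config()
  set.seed(5)
  x <- rnorm(40 * fs)
  th1 <- estimate_baseline_threshold(x, fs, cfg)
  th2 <- estimate_baseline_threshold(2.5 * x, fs, cfg)
  expect_equal(th2, 2.5 * th1, tolerance = 1e-10)

  # closed-form Rayleigh envelope oracle for white Gaussian noise
  sigma <- 1.7
  set.seed(6)
  wn <- rnorm(60 * fs) * sigma
  th <- estimate_baseline_threshold(wn, fs, cfg)
  th_true <- sigma * (sqrt(pi / 2) + 3 * sqrt(2 - pi / 2))
  expect_equal(th, th_true, tolerance = 0.05)

  expect_error(estimate_baseline_threshold(rnorm(fs), fs, cfg),
               "insufficient-data")
})

test_that("Th_amp is lower for LNA-like than CD-like noise in every run", {
  fs <- 2000
  cfg <- detector_config()
  for (s in 1:5) {
    bg <- make_background(20, fs, 20, 3, seed = 600 + s)
    lna <- bandpass_filter(bg + make_amplifier_noise(20, fs, 2.3,
                                                     seed = 700 + s),
                           "ripple", fs)
    cd <- bandpass_filter(bg + make_amplifier_noise(20, fs, 21,
                                                    seed = 700 + s),
                          "ripple", fs)
    expect_lt(estimate_baseline_threshold(lna, fs, cfg),
              estimate_baseline_threshold(cd, fs, cfg))
  }
})

test_that("candidate detection finds bursts and applies the cycle rule", {
  fs <- 2000
  cfg <- detector_config()
  x <- lna_channel(30, fs, seed = 21)
  bs0 <- bandpass_filter(x, "ripple", fs)
  th <- estimate_baseline_threshold(bs0, fs, cfg)

  expect_identical(nrow(detect_candidates(rep(0.001, fs * 12), fs,
                                          1, cfg)), 0L)

  # injected 8-cycle 120 Hz 4 uV burst: exactly one candidate, J >= 0.5
  wav <- make_hfo_waveform(120, 8, 4, fs)
  i0 <- 15 * fs
  x1 <- x
  x1[i0:(i0 + length(wav) - 1)] <- x1[i0:(i0 + length(wav) - 1)] + wav
  bs1 <- bandpass_filter(x1, "ripple", fs)
  cand <- detect_candidates(bs1, fs, th, cfg)
  hits <- which(vapply(seq_len(nrow(cand)), function(k)
    jaccard(cand$start_s[k], cand$end_s[k], 15, 15 + 8 / 120),
    0) >= 0.5)
  expect_length(hits, 1L)

  # a 2-cycle burst fails the min-cycles rule
  w2 <- make_hfo_waveform(120, 2, 6, fs)
  x2 <- x
  x2[i0:(i0 + length(w2) - 1)] <- x2[i0:(i0 + length(w2) - 1)] + w2
  cand2 <- detect_candidates(bandpass_filter(x2, "ripple", fs), fs, th, cfg)
  expect_false(any(abs(cand2$start_s - 15) < 0.05))

  # raising the threshold never increases the candidate count
  counts <- vapply(c(0.5, 1, 2, 4) * th, function(t)
    nrow(detect_candidates(bs1, fs, t, cfg)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("time-frequency validation accepts tones and rejects leakage", {
  fs <- 2000
  cfg <- detector_config()
  bg <- lna_channel(20, fs, seed = 41)

  run_val <- function(f0, amp = 4, cycles = 10) {
    wav <- make_hfo_waveform(f0, cycles, amp, fs)
    x <- bg
    i0 <- 10 * fs
    x[i0:(i0 + length(wav) - 1)] <- x[i0:(i0 + length(wav) - 1)] + wav
    j0 <- floor((10 - 0.25) * fs)
    j1 <- j0 + nextn(floor(0.6 * fs), c(2, 3, 5)) - 1
    tf <- st_transform(x[j0:j1], fs, 40, 270, freq_step_hz = 5)
    validate_time_frequency(
      list(start_s = 10 - (j0 - 1) / fs,
           end_s = 10 + cycles / f0 - (j0 - 1) / fs), tf, cfg)
  }
  v140 <- run_val(140)
  expect_identical(v140$status, "accepted")
  expect_lt(abs(v140$peak_freq_hz - 140), 10)   # within ~one map step

  # 60 Hz burst leaking through the filter skirt: peak below band edge
  expect_identical(run_val(60, amp = 8)$status, "rejected_tf")
})

test_that("cross-channel rejection matches a brute-force overlap oracle", {
  cfg <- detector_config(cross_channel_fraction = 0.8)
  ev1 <- data.frame(channel = "A", start_s = 1, end_s = 1.1,
                    status = "accepted")
  expect_identical(reject_cross_channel(ev1, 1, cfg)$status, "accepted")

  # synchronous event on all 8 channels -> all flagged
  ev8 <- data.frame(channel = LETTERS[1:8], start_s = 2, end_s = 2.05,
                    status = "accepted")
  expect_true(all(reject_cross_channel(ev8, 8, cfg)$status ==
                    "rejected_cross_channel"))

  # random event sets vs O(n^2) oracle
  set.seed(13)
  for (rep in 1:5) {
    n <- 40
    ev <- data.frame(channel = sample(LETTERS[1:6], n, replace = TRUE),
                     start_s = runif(n, 0, 30), status = "accepted")
    ev$end_s <- ev$start_s + runif(n, 0.02, 0.2)
    got <- reject_cross_channel(ev, 6, cfg)$status
    want <- vapply(seq_len(n), function(i) {
      ch <- unique(ev$channel[ev$start_s < ev$end_s[i] &
                                ev$start_s[i] < ev$end_s])
      if (length(ch) / 6 > 0.8) "rejected_cross_channel" else "accepted"
    }, "")
    expect_identical(got, want)
  }
})

test_that("detection is deterministic and accepted peaks stay in band", {
  spec <- recording_spec(duration_s = 60,
                         channel_labels = c("C4-P4", "C3-P3"),
                         event_rate_per_min = 4, seed = 3)
  sim <- make_recording(spec)
  ev1 <- detect_hfo(sim$recording, "ripple")
  ev2 <- detect_hfo(sim$recording, "ripple")
  expect_identical(ev1, ev2)
  acc <- ev1[ev1$status == "accepted", ]
  expect_gt(nrow(acc), 0)
  expect_true(all(acc$peak_freq_hz >= 80 & acc$peak_freq_hz <= 250))
})

test_that("sensitivity never drops as injected amplitude grows", {
  amps <- c(1.5, 3, 6)
  sens <- vapply(amps, function(a) {
    hits <- 0; total <- 0
    for (s in 1:6) {
      spec <- recording_spec(duration_s = 60, channel_labels = "C4-P4",
                             event_amp_mean_uv = a, event_amp_sd_uv = 0,
                             event_amp_min_uv = min(a, 0.5),
                             spike_rate_per_min = 0,
                             event_rate_per_min = 4, seed = 400 + s)
      sim <- make_recording(spec)
      sc <- score_detection(detect_hfo(sim$recording, "ripple"), sim$truth)
      hits <- hits + sc$n_matched; total <- total + sc$n_truth
    }
    hits / total
  }, 0)
  expect_true(all(diff(sens) >= -0.02))   # monotone up to counting noise
  expect_gt(sens[3], 0.95)
})

test_that("review decisions only ever reject", {
  ev <- data.frame(event_id = 1:3, channel = "A", band = "ripple",
                   start_s = 1:3, end_s = 1:3 + 0.05, peak_freq_hz = 120,
                   peak_amp_uv = 3, status = c("accepted", "accepted",
                                               "rejected_tf"),
                   review_note = "")
  rv <- list(`1` = list(decision = "reject", note = "muscle"),
             `3` = list(decision = "keep"))
  out <- apply_review(ev, rv)
  expect_identical(out$status,
                   c("rejected_review", "accepted", "rejected_tf"))
  expect_identical(out$review_note[1], "muscle")
})
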