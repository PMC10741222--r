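# synthetic_data: generators are pure functions of (params, seed) and emit
# ground truth that downstream tests rely on.

test_that("attention trace: fixed point, determinism, stationary mean", {
  # zero noise, start == target 0.7 -> constant trace
  tr <- simulate_attention_trace(10, 2, attention_params(target = 0.7,
                                                         volatility = 0),
                                 seed = 1)
  expect_true(all(abs(tr$values - 0.7) < 1e-12))
  # same seed -> identical
  a <- simulate_attention_trace(50, 4, attention_params(), seed = 9)
  b <- simulate_attention_trace(50, 4, attention_params(), seed = 9)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, simulate_attention_trace(50, 4, attention_params(),
                                       seed = 10)$values))
  # law of large numbers: long trace mean within 0.05 of target
  long <- simulate_attention_trace(10000, 1, attention_params(target = 0.5),
                                   seed = 3)
  expect_lt(abs(mean(long$values) - 0.5), 0.05)
  expect_true(all(long$values >= 0 & long$values <= 1))
})

test_that("synthesized EEG couples theta/beta power to attention", {
  p <- synth_eeg_params()
  pw <- function(target) {
    tr <- simulate_attention_trace(12, 1,
                                   attention_params(target = target,
                                                    volatility = 0), seed = 4)
    rec <- synthesize_eeg(tr, small_montage(), 500, p, seed = 4)
    i <- match("Fz", rec$ch_names)
    c(theta = oracle_band_power(rec$data[i, 1:1500], 500, c(4, 7.5)),
      beta = oracle_band_power(rec$data[i, 1:1500], 500, c(13, 19)))
  }
  lo <- pw(0); hi <- pw(1)
  expect_gt(lo["theta"], hi["theta"])   # inattentive -> more theta
  expect_lt(lo["beta"], hi["beta"])
})

test_that("single-component tone mode gives a pure AM 6 Hz tone at Fz", {
  tr <- simulate_attention_trace(4, 1, attention_params(volatility = 0),
                                 seed = 1)
  p <- synth_eeg_params(theta_band = c(4, 8), alpha_amp = 0, beta_amp = 0,
                        pink_amp = 0, blink_rate = 0, osc_type = "tone")
  rec <- synthesize_eeg(tr, small_montage(), 500, p, seed = 1)
  x <- rec$data[match("Fz", rec$ch_names), ]
  n <- length(x)
  spec <- Mod(stats::fft(x))[2:(n / 2)]
  f <- (1:(n / 2 - 1)) * 500 / n
  in6 <- abs(f - 6) < 0.5
  expect_gt(sum(spec[in6]^2) / sum(spec^2), 0.999)
})

test_that("ECG channel carries ~heart_rate R-peaks and truth matches", {
  tr <- simulate_attention_trace(60, 1, attention_params(), seed = 2)
  rec <- synthesize_eeg(tr, small_montage(), 500,
                        synth_eeg_params(heart_rate_bpm = 90), seed = 2)
  peaks <- rec$meta$r_peaks
  expect_true(abs(length(peaks) - 90) <= 1)
  # peaks really are in the signal: amplitude at peak samples is large
  ecg <- rec$data[match("ECG", rec$ch_names), ]
  at_pk <- ecg[round(peaks * 500) + 1]
  expect_gt(min(at_pk), 0.8 * max(ecg))
})

test_that("muscle bursts are local in channel and annotated", {
  rec <- make_recording(10, seed = 5)
  rec_b <- inject_muscle_bursts(rec, times = 4, channels = "T7",
                                amplitude = 60, seed = 5)
  expect_identical(rec_b$annotations$label, "muscle")
  # burst only on T7: all other channels identical
  others <- setdiff(seq_along(rec$ch_names), match("T7", rec$ch_names))
  expect_identical(rec_b$data[others, ], rec$data[others, ])
  # empty times -> unchanged
  expect_identical(inject_muscle_bursts(rec, numeric(0))$data, rec$data)
  # burst on Oz leaves T7 beta power unchanged
  rec_oz <- inject_muscle_bursts(rec, times = 4, channels = "Oz",
                                 amplitude = 60, seed = 5)
  i_t7 <- match("T7", rec$ch_names)
  win <- round(3.5 * 500):round(6.5 * 500)
  expect_equal(band_power(rec_oz$data[i_t7, win], 500, c(13, 19)),
               band_power(rec$data[i_t7, win], 500, c(13, 19)))
  expect_error(inject_muscle_bursts(rec, 4, channels = "Nope"), "not found")
})

test_that("MR contamination: null case, RMS ratio, determinism", {
  clean <- make_recording(10, seed = 6)
  # null contamination equals upsampled clean within resampling tolerance
  mr0 <- contaminate_mr(clean, mr_contamination_params(gradient_amp = 0,
                                                       bcg_amp = 0), seed = 1)
  back <- lowpass_downsample(mr0$contaminated, 70, 500)
  # compare below the 70 Hz lowpass (the clean signal has pink noise above
  # it by construction, which the chain removes by design)
  h70 <- nfbloop:::fir_lowpass(85, 500, 30)
  n <- min(ncol(back$data), ncol(clean$data))
  for (ch in 1:2) {
    a <- nfbloop:::fir_apply(back$data[ch, 1:n], h70)
    b <- nfbloop:::fir_apply(clean$data[ch, 1:n], h70)
    expect_gt(stats::cor(a, b), 0.999)
  }
  # 10 mV gradient on ~EEG-scale signal: RMS ratio > 50
  mr <- contaminate_mr(clean, mr_contamination_params(), seed = 1)
  r <- sqrt(mean(mr$contaminated$data[1, ]^2)) / sqrt(mean(clean$data[1, ]^2))
  expect_gt(r, 50)
  # determinism
  mr2 <- contaminate_mr(clean, mr_contamination_params(), seed = 1)
  expect_identical(mr$contaminated$data, mr2$contaminated$data)
  # TR markers + R-peaks in the event table
  expect_true(all(c("tr", "r_peak") %in% mr$events$trial_type))
})

test_that("gradient-only contamination is confined outside the silent tail", {
  clean <- make_recording(10, seed = 8)
  prm <- mr_contamination_params(bcg_amp = 0, gradient_tail_frac = 0.2)
  mr <- contaminate_mr(clean, prm, seed = 2)
  up0 <- contaminate_mr(clean, mr_contamination_params(gradient_amp = 0,
                                                       bcg_amp = 0),
                        seed = 2)$contaminated
  sf <- prm$target_sfreq
  diffs <- abs(mr$contaminated$data[1, ] - up0$data[1, ])
  # samples in the silent last 20% of each TR are untouched
  tr_on <- mr$contaminated$meta$tr_onsets
  for (k in seq_along(tr_on)) {
    i1 <- round((tr_on[k] + 0.85 * prm$tr) * sf) + 1
    i2 <- min(length(diffs), round((tr_on[k] + 0.99 * prm$tr) * sf))
    if (i2 > i1) expect_lt(max(diffs[i1:i2]), 1e-6)
  }
})

test_that("simulated responses follow the behavioral model", {
  tr1 <- simulate_attention_trace(100, 1, attention_params(target = 1,
                                                           volatility = 0),
                                  seed = 1)
  trials <- data.frame(onset = seq(1, 99, by = 2), is_nogo = FALSE)
  # deterministic limit: full attention, zero noise -> all answered at base RT
  r <- simulate_responses(tr1, trials, list(rt_sd_ms = 0), seed = 3)
  expect_true(all(r$responded))
  expect_true(all(abs(r$rt_ms - 450) < 1e-9))
  # distraction offset shifts mean RT by exactly the offset when noise 0
  trials_d <- trials; trials_d$distracted <- TRUE
  rd <- simulate_responses(tr1, trials_d, list(rt_sd_ms = 0), seed = 3)
  expect_true(all(abs(rd$rt_ms - r$rt_ms - 50) < 1e-9))
  # binomial oracle: omission rate ~ configured probability
  tr0 <- simulate_attention_trace(100, 1, attention_params(target = 0,
                                                           volatility = 0),
                                  seed = 1)
  big <- data.frame(onset = runif(10000, 0, 99), is_nogo = FALSE)
  rb <- simulate_responses(tr0, big, list(omission_max = 0.1), seed = 4)
  expect_lt(abs(mean(!rb$responded) - 0.1), 0.01)
})
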