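# realtime_engine: the sliding-window TBR computation, gating, calibration
# and normalization.

test_that("average reference zeroes the scalp mean and spares ECG", {
  # already zero-mean pair unchanged
  w <- rbind(rep(1, 10), rep(-1, 10))
  expect_equal(average_reference(w), w)
  # common mode removed
  w2 <- matrix(3.7, 4, 5)
  expect_true(all(abs(average_reference(w2)) < 1e-12))
  # random matrix: column means of eeg rows ~ 0
  set.seed(1)
  m <- matrix(rnorm(31 * 1500), 31)
  ref <- average_reference(m)
  expect_lt(max(abs(colMeans(ref))), 1e-10)
  # ecg row passes through
  roles <- c(rep("eeg", 30), "ecg")
  ref2 <- average_reference(m, roles)
  expect_identical(ref2[31, ], m[31, ])
  expect_lt(max(abs(colMeans(ref2[1:30, ]))), 1e-10)
  expect_error(average_reference(m[1, , drop = FALSE]), ">= 2")
})

test_that("band_power matches the brute-force DFT oracle and separates bands", {
  t <- (0:1499) / 500
  s6 <- sin(2 * pi * 6 * t)
  expect_gt(band_power(s6, 500, c(4, 7.5)) / band_power(s6, 500, c(13, 19)),
            100)
  expect_equal(band_power(rep(0, 1500), 500, c(4, 7.5)), 0)
  # equal-amplitude 6 + 16 Hz: theta and beta powers equal within 5%
  s <- s6 + sin(2 * pi * 16 * t + 0.3)
  th <- band_power(s, 500, c(4, 7.5)); be <- band_power(s, 500, c(13, 19))
  expect_lt(abs(th - be) / be, 0.05)
  # oracle equivalence on noise
  set.seed(2)
  x <- rnorm(750)
  expect_rel_equal(band_power(x, 250, c(4, 7.5)),
                   oracle_band_power(x, 250, c(4, 7.5)), 1e-9)
  expect_error(band_power(x, 250, c(100, 130)), "Nyquist")
})

test_that("muscle gate applies the strict 3x rule", {
  expect_true(gate_muscle(4, 1))
  expect_false(gate_muscle(3, 1))           # boundary: strict inequality
  expect_false(gate_muscle(0, 0))
})

test_that("stream_tbr emits the right schedule and matches the oracle", {
  rec <- make_recording(10, seed = 3)
  out <- stream_tbr(rec)
  expect_equal(out$t, 3:10)                 # 8 samples at t = 3..10 s
  expect_false(any(is.na(out$tbr_raw)))
  # oracle: recompute window 5 (t = 7 s) by hand
  cfg <- engine_config()
  i2 <- 7 * 500; i1 <- i2 - 1500 + 1
  win <- average_reference(rec$data[, i1:i2], rec$ch_roles)
  i_fz <- match("Fz", rec$ch_names)
  th <- oracle_band_power(win[i_fz, ], 500, cfg$theta_band)
  be <- oracle_band_power(win[i_fz, ], 500, cfg$beta_band)
  expect_rel_equal(out$theta_power[out$t == 7], th, 1e-6)
  expect_rel_equal(out$beta_power[out$t == 7], be, 1e-6)
  expect_rel_equal(out$tbr_raw[out$t == 7], th / be, 1e-6)
  expect_error(stream_tbr(make_recording(10, ch_names = c("Cz", "Pz", "ECG"))),
               "Fz")
})

test_that("stationary signal gives a stable tbr_raw sequence", {
  tr <- simulate_attention_trace(20, 1, attention_params(volatility = 0),
                                 seed = 5)
  rec <- synthesize_eeg(tr, small_montage(), 500,
                        synth_eeg_params(pink_amp = 0, blink_rate = 0,
                                         osc_type = "tone"), seed = 5)
  out <- stream_tbr(rec)
  expect_lt(max(abs(out$tbr_raw - mean(out$tbr_raw))) / mean(out$tbr_raw),
            0.10)
})

test_that("chunked streaming equals the whole-recording call", {
  rec <- make_recording(9, seed = 6)
  whole <- stream_tbr(rec)
  for (chunk in c(1L, 7L, 500L, 1234L)) {
    st <- tbr_streamer(engine_config(), rec$sfreq, rec$ch_names,
                       rec$ch_roles)
    i <- 1L
    while (i <= ncol(rec$data)) {
      j <- min(ncol(rec$data), i + chunk - 1L)
      st$feed(rec$data[, i:j, drop = FALSE])
      i <- j + 1L
    }
    got <- st$collect()
    expect_equal(got, whole, tolerance = 1e-12)
  }
})

test_that("muscle burst on T7 gates exactly the overlapping windows", {
  rec <- make_recording(14, seed = 7)
  # a strong jaw clench: ~350 uV broadband EMG at the temporal electrode
  rec_b <- inject_muscle_bursts(rec, times = 7, channels = "T7",
                                amplitude = 350, duration_s = 1, seed = 7)
  out <- stream_tbr(rec_b)
  # windows fully covering the burst ((t-3, t] for t = 8, 9) must gate;
  # windows that end before the burst starts must not
  expect_true(all(out$gated[out$t %in% 8:9]))
  expect_false(any(out$gated[out$t <= 6]))
})

test_that("calibrate reproduces the printed min / top-quarter-mean rule", {
  # hand-evaluated example: ceiling(8/4) = 2 top values
  s <- data.frame(tbr_raw = c(5, 1, 8, 2, 7, 3, 6, 4),
                  gated = rep(FALSE, 8))
  b <- calibrate(s)
  expect_equal(b$tbr_min, 1)
  expect_equal(b$tbr_max, 7.5)
  # permutation invariance
  set.seed(4)
  for (r in 1:5) {
    p <- s[sample(nrow(s)), ]
    bp <- calibrate(p)
    expect_equal(bp$tbr_min, b$tbr_min)
    expect_equal(bp$tbr_max, b$tbr_max)
  }
  # gated samples removed; too few ungated -> error
  expect_error(calibrate(data.frame(tbr_raw = c(5, rep(2, 10)),
                                    gated = c(FALSE, rep(TRUE, 10)))),
               "calibration failed")
  # random arrays against the independent oracle (with ties and gating)
  set.seed(5)
  for (r in 1:50) {
    n <- sample(4:60, 1)
    tbr <- round(rexp(n, 1 / 3) + 0.1, 1)   # ties likely
    gated <- runif(n) < 0.2
    if (sum(!gated) < 4) gated[] <- FALSE
    got <- calibrate(tbr, gated)
    want <- oracle_calibrate(tbr, gated)
    expect_equal(got$tbr_min, want$tbr_min)
    expect_equal(got$tbr_max, want$tbr_max)
  }
})

test_that("normalization is the inverted clipped linear map", {
  b <- calibration_bounds(2, 6)
  expect_equal(normalize_tbr(2, b), 1)      # most focused end
  expect_equal(normalize_tbr(6, b), 0)
  expect_equal(normalize_tbr(4, b), 0.5)
  expect_equal(normalize_tbr(c(0, 10), b), c(1, 0))   # clipping
  expect_warning(v <- normalize_tbr(3, calibration_bounds(3, 3)),
                 "degenerate")
  expect_equal(v, 0.5)
  # bounds JSON round-trip
  p <- file.path(tempdir(), "b.json")
  write_bounds(b, p)
  b2 <- read_bounds(p)
  expect_equal(b2$tbr_min, 2); expect_equal(b2$tbr_max, 6)
})

test_that("monotone chain: attention down -> raw TBR up -> nfb down", {
  levels <- seq(0.05, 0.95, length.out = 10)
  mean_tbr <- vapply(levels, function(a) {
    tr <- simulate_attention_trace(14, 1, attention_params(target = a,
                                                           volatility = 0),
                                   seed = 11)
    rec <- synthesize_eeg(tr, small_montage(), 500, seed = 11)
    s <- stream_tbr(rec)
    mean(s$tbr_raw[!s$gated])
  }, 0)
  expect_lt(stats::cor(levels, mean_tbr, method = "spearman"), -0.9)
  b <- calibration_bounds(min(mean_tbr), max(mean_tbr))
  expect_gt(stats::cor(levels, normalize_tbr(mean_tbr, b),
                       method = "spearman"), 0.9)
})
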