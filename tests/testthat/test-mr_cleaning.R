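# mr_cleaning: trimmed templates, FIR lowpass/downsample, QRS detection and
# the full chain (the heavy injection-recovery run lives in
# test-acceptance.R).

test_that("build_template implements the printed trimmed mean", {
  # L=5, K=1, one time point [10, 0, 3, 100, 5] -> mean(3, 5, 10) = 6
  E <- matrix(c(10, 0, 3, 100, 5), 5, 1)
  expect_equal(build_template(E, 1), 6)
  # K = 0 reduces to the plain mean
  set.seed(1)
  E2 <- matrix(rnorm(40), 8, 5)
  expect_equal(build_template(E2, 0), colMeans(E2))
  # identical epochs -> template equals any epoch
  E3 <- matrix(rep(sin(1:7), each = 6), 6, 7)
  expect_equal(build_template(E3, 2), sin(1:7))
  expect_error(build_template(E2, 4), "L > 2K")
})

test_that("trimmed template is robust to up to K outlier epochs", {
  set.seed(2)
  base <- matrix(rnorm(30 * 20), 30, 20)
  t0 <- build_template(base, 6)
  spoiled <- base
  spoiled[1:6, ] <- 1e6          # K arbitrary outliers
  t1 <- build_template(spoiled, 6)
  # breakdown property: change bounded by replacing them with the max of
  # the remaining values instead
  capped <- base
  capped[1:6, ] <- matrix(apply(base[7:30, ], 2, max), 6, 20, byrow = TRUE)
  t2 <- build_template(capped, 6)
  expect_true(all(abs(t1 - t0) <= abs(t2 - t0) + 1e-12))
})

test_that("exactly repeating artifact is fully captured", {
  sf <- 1000
  art <- sin(2 * pi * 17 * (0:199) / sf) * 500
  x <- rep(art, 40)
  rec <- eeg_recording(rbind(x, x), sf, c("Fz", "ECG"))
  occ <- artifact_occurrences(seq(0, by = 0.2, length.out = 40), 200)
  cleaned <- subtract_artifact(rec, occ, template_params(30, 6))
  expect_lt(sqrt(mean(cleaned$data[1, ]^2)) / sqrt(mean(x^2)), 0.01)
})

test_that("one 50x outlier epoch does not disturb its neighbours", {
  set.seed(3)
  sf <- 500
  art <- 300 * sin(2 * pi * 25 * (0:99) / sf)
  n_ep <- 40
  eeg <- rnorm(n_ep * 100, sd = 10)
  x <- eeg + rep(art, n_ep)
  out_ep <- 20
  spike <- (out_ep * 100 + 1):(out_ep * 100 + 100)
  # head-movement-like excursions: extreme at every template time point;
  # with K >= 1 the trimming makes the template invariant to WHICH extreme
  # value the outlier epoch carries
  x1 <- x; x1[spike] <- x1[spike] + 50 * max(abs(art))
  x2 <- x; x2[spike] <- x2[spike] + 500 * max(abs(art))
  mk <- function(sig) eeg_recording(rbind(sig, 0), sf, c("Fz", "ECG"))
  occ <- artifact_occurrences(seq(0, by = 0.2, length.out = n_ep), 100)
  c1 <- subtract_artifact(mk(x1), occ, template_params(30, 6))
  c2 <- subtract_artifact(mk(x2), occ, template_params(30, 6))
  # every non-outlier epoch is cleaned identically in both runs
  keep <- setdiff(seq_len(n_ep * 100), spike)
  expect_lt(max(abs(c1$data[1, keep] - c2$data[1, keep])), 1e-9)
  expect_error(subtract_artifact(mk(x), artifact_occurrences(c(0, 0.2), 100),
                                 template_params(30, 6)), "need >= L")
})

test_that("lowpass_downsample meets pass/stop specs and contract", {
  sf <- 5000
  t <- (0:(2 * sf - 1)) / sf
  rec <- eeg_recording(rbind(sin(2 * pi * 30 * t), sin(2 * pi * 120 * t)),
                       sf, c("Fz", "Cz"))
  out <- lowpass_downsample(rec)
  expect_equal(out$sfreq, 500)
  mid <- 200:800
  # 30 Hz amplitude preserved within 2%
  expect_lt(abs(sqrt(2) * sd(out$data[1, mid]) - 1), 0.02)
  # 120 Hz attenuated below 1%
  expect_lt(sqrt(mean(out$data[2, mid]^2)) / sqrt(0.5), 0.01)
  expect_error(lowpass_downsample(rec, cutoff_hz = 300), "Nyquist")
  # annotations in seconds survive untouched
  rec$annotations <- data.frame(onset = 0.5, duration = 0.1, label = "a")
  expect_equal(lowpass_downsample(rec)$annotations$onset, 0.5)
})

test_that("QRS detection recovers synthetic ground truth", {
  tr <- simulate_attention_trace(60, 1, attention_params(), seed = 9)
  rec <- synthesize_eeg(tr, small_montage(), 500,
                        synth_eeg_params(heart_rate_bpm = 60), seed = 9)
  ecg <- rec$data[match("ECG", rec$ch_names), ]
  truth <- rec$meta$r_peaks
  det <- detect_qrs(ecg, 500)
  expect_true(abs(length(det) - 60) <= 1)
  # sensitivity and precision at +/- 20 ms
  hits <- vapply(det, function(d) min(abs(truth - d)) <= 0.02, TRUE)
  found <- vapply(truth, function(p) min(abs(det - p)) <= 0.02, TRUE)
  expect_gte(mean(hits), 0.99)
  expect_gte(mean(found), 0.99)
  # polarity robustness
  det_inv <- detect_qrs(-ecg, 500)
  expect_equal(length(det_inv), length(det))
  expect_lt(max(abs(det_inv - det)), 0.02)
  expect_error(detect_qrs(rep(0, 5000), 500), "flat")
})

test_that("pipeline with zero contamination reduces to lowpass_downsample", {
  # 1 kHz target keeps this fast while allowing the full L = 30 / 40
  clean <- make_recording(70, seed = 10)
  mr0 <- contaminate_mr(clean,
                        mr_contamination_params(gradient_amp = 0,
                                                bcg_amp = 0,
                                                target_sfreq = 1000),
                        seed = 1)
  ref <- lowpass_downsample(mr0$contaminated)
  out <- clean_mr_pipeline(mr0$contaminated, mr0$contaminated$meta$tr_onsets)
  # only residual differences: template subtraction of near-zero templates.
  # The trimmed-mean EEG leakage bounds the correlation near
  # 1/sqrt(1 + 1/18 + 1/30) ~ 0.957 for the two stages combined.
  n <- ncol(ref$data)
  expect_gt(stats::cor(out$data[1, 1:n], ref$data[1, 1:n]), 0.94)
  # QC provenance lists both (L, K) pairs
  expect_equal(out$meta$qc$gradient_L, 30L)
  expect_equal(out$meta$qc$pulse_K, 5L)
  expect_true(all(c("pre_rms", "post_rms", "tr_harmonic_power") %in%
                    names(out$meta$qc)))
  expect_error(clean_mr_pipeline(mr0$contaminated, numeric(0)), "TR markers")
})

test_that("ECG channel is never altered by pulse subtraction", {
  clean <- make_recording(20, seed = 12)
  mr <- contaminate_mr(clean,
                       mr_contamination_params(target_sfreq = 1000),
                       seed = 3)
  out <- clean_mr_pipeline(mr$contaminated, mr$contaminated$meta$tr_onsets,
                           params_grad = template_params(8, 2),
                           params_pulse = template_params(10, 2))
  # reference: gradient + lowpass only
  occ <- artifact_occurrences(mr$contaminated$meta$tr_onsets,
                              round(1.76 * 1000))
  ref <- lowpass_downsample(subtract_artifact(mr$contaminated, occ,
                                              template_params(8, 2)))
  i_ecg <- match("ECG", clean$ch_names)
  expect_equal(out$data[i_ecg, ], ref$data[i_ecg, ])
})
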