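# analysis: VR preprocessing, session/period TBR statistics, transfer TBR.

test_that("preprocess_vr filter responses meet spec", {
  sf <- 500
  t <- (0:(8 * sf - 1)) / sf
  drift <- 20 * sin(2 * pi * 0.2 * t)
  sig6 <- 10 * sin(2 * pi * 6 * t)
  line50 <- 10 * sin(2 * pi * 50 * t)
  rec <- eeg_recording(rbind(drift + sig6, line50, sig6, -sig6), sf,
                       c("Fz", "Cz", "Pz", "Oz"))
  out <- preprocess_vr(rec)
  mid <- (2 * sf):(6 * sf)
  # 50 Hz band content after the chain vs before (spectral measure is
  # immune to the average-reference mixing of other channels)
  p50_out <- band_power(out$data[2, mid], sf, c(48, 52))
  p50_in <- band_power(rec$data[2, mid], sf, c(48, 52))
  expect_lt(p50_out / p50_in, 10^(-30 / 10))               # >= 30 dB down
  # drift >= 20 dB down, 6 Hz within 5%: isolate via channel 1 minus ref
  rec_d <- eeg_recording(rbind(drift, drift * 0, drift * 0, drift * 0), sf,
                         c("Fz", "Cz", "Pz", "Oz"))
  out_d <- preprocess_vr(rec_d)
  expect_lt(sqrt(mean(out_d$data[1, mid]^2)) / sqrt(mean(drift^2)) /
              0.75,                       # average reference scales by 3/4
            10^(-20 / 20))
  rec_6 <- eeg_recording(rbind(sig6, sig6 * 0, sig6 * 0, sig6 * 0), sf,
                         c("Fz", "Cz", "Pz", "Oz"))
  out_6 <- preprocess_vr(rec_6, notch_hz = 0)
  expect_lt(abs(sqrt(mean(out_6$data[1, mid]^2)) /
                  (0.75 * sqrt(mean(sig6^2))) - 1), 0.05)
  expect_error(preprocess_vr(rec, bad_channels = rec$ch_names), "all channels")
})

test_that("preprocess_vr masks bad segments and interpolates bad channels", {
  rec <- make_recording(8, seed = 14, ch_names = c("Fp1", "Fp2", "F3", "Fz",
                                                   "F4", "C3", "Cz", "C4",
                                                   "P3", "Pz", "P4", "Oz",
                                                   "ECG"))
  bads <- data.frame(onset = 2, duration = 1)
  out <- preprocess_vr(rec, bad_annotations = bads, bad_channels = "Cz")
  expect_equal(sum(out$meta$bad_mask), 500L)
  expect_identical(out$meta$bad_channels, "Cz")
  # deterministic / idempotent masking metadata
  out2 <- preprocess_vr(rec, bad_annotations = bads, bad_channels = "Cz")
  expect_identical(out$data, out2$data)
  expect_identical(out$meta$bad_mask, out2$meta$bad_mask)
  # ICA hook runs between filtering and interpolation
  called <- FALSE
  hook <- function(r) { called <<- TRUE; r }
  invisible(preprocess_vr(rec, ica_excluder = hook))
  expect_true(called)
})

test_that("spherical-spline interpolation recovers a smooth scalp field", {
  labs <- c("Fp1", "Fp2", "F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz",
            "P4", "Oz")
  pos <- standard_positions(labs)
  # time-varying low-order field: linear combination of position coords
  t <- seq(0, 2, length.out = 200)
  V <- outer(5 * pos["z", ], sin(2 * pi * 3 * t)) +
    outer(3 * pos["y", ], cos(2 * pi * 5 * t))
  rec <- eeg_recording(V, 100, labs)
  out <- interpolate_channels(rec, c("Cz", "P3"))
  for (ch in c("Cz", "P3")) {
    i <- match(ch, labs)
    expect_gt(stats::cor(out$data[i, ], V[i, ]), 0.99)
    expect_lt(sqrt(mean((out$data[i, ] - V[i, ])^2)) / sd(V[i, ]), 0.2)
  }
  expect_error(standard_positions("NotAChannel"), "no montage position")
})

test_that("session_tbr implements the baseline-difference statistic", {
  ev <- data.frame(onset = c(0, 100, 200), duration = c(60, 40, 60),
                   trial_type = c("helicopter_run", "calc_task",
                                  "helicopter_run"))
  # piecewise-constant fixture: helicopter 1.5, baseline 2.0
  smp <- data.frame(
    t = c(seq(3, 59), seq(101, 119), seq(203, 259)),
    tbr_raw = c(rep(1.5, 57), rep(2, 19), rep(1.5, 57)),
    gated = FALSE)
  st <- session_tbr(smp, ev)
  expect_equal(st$mean_tbr_helicopter, 1.5)
  expect_equal(st$mean_tbr_baseline, 2.0)
  expect_equal(st$tbr_relative, -0.5)
  # constant signal -> zero
  smp2 <- smp; smp2$tbr_raw <- 2
  expect_equal(session_tbr(smp2, ev)$tbr_relative, 0)
  # gated samples inside the baseline are excluded
  smp3 <- smp
  smp3$gated[smp3$t %in% 101:105] <- TRUE
  smp3$tbr_raw[smp3$t %in% 101:105] <- 99
  st3 <- session_tbr(smp3, ev)
  expect_equal(st3$mean_tbr_baseline, 2.0)
  expect_equal(st3$n_gated_excluded, 5L)
  expect_error(session_tbr(smp, ev[ev$trial_type != "calc_task", ]),
               "calc_task")
})

test_that("period_summary splits sessions 1-4 vs 5-8", {
  s <- data.frame(child = rep("c1", 8), session = 1:8,
                  tbr_relative = c(1, 1, 1, 1, 0, 0, 0, 0))
  ps <- period_summary(s)
  expect_equal(ps$per_child$period1_mean, 1.0)
  expect_equal(ps$per_child$period2_mean, 0.0)
  expect_true(ps$per_child$complete)
  # planted learning trend: period2 < period1 for every simulated child
  set.seed(15)
  cohort <- do.call(rbind, lapply(1:4, function(c) {
    data.frame(child = paste0("c", c), session = 1:8,
               tbr_relative = seq(0.5, -0.5, length.out = 8) + rnorm(8, 0, 0.05))
  }))
  ps2 <- period_summary(cohort)
  expect_true(all(ps2$per_child$period2_mean < ps2$per_child$period1_mean))
  # permuting children leaves cohort means unchanged
  perm <- cohort[sample(nrow(cohort)), ]
  ps3 <- period_summary(perm)
  o <- order(ps3$cohort_by_session$session)
  expect_equal(ps3$cohort_by_session$mean_tbr_relative[o],
               ps2$cohort_by_session$mean_tbr_relative)
  # missing sessions flagged, not fatal
  ps4 <- period_summary(cohort[cohort$session != 8 | cohort$child != "c1", ])
  expect_false(all(ps4$per_child$complete))
})

test_that("transfer_tbr epochs blocks and recovers a planted effect", {
  sf <- 250
  blocks <- transfer_paradigm()
  total_s <- 360
  t <- (0:(total_s * sf - 1)) / sf
  # theta amplitude halved during Regulation
  reg <- rep(FALSE, length(t))
  for (b in seq_len(nrow(blocks))) {
    if (blocks$trial_type[b] == "Regulation") {
      reg[t >= blocks$onset[b] & t < blocks$onset[b] + 30] <- TRUE
    }
  }
  th_amp <- ifelse(reg, 5, 10)
  sig <- th_amp * sin(2 * pi * 6 * t) + 4 * sin(2 * pi * 16 * t)
  set.seed(16)
  rec <- eeg_recording(rbind(sig, rnorm(length(t)), rnorm(length(t))), sf,
                       c("Fz", "Cz", "Pz"))
  res <- transfer_tbr(rec, blocks)
  expect_equal(res$per_condition$Rest$n_epochs, 18L)
  expect_equal(res$per_condition$Regulation$n_epochs, 18L)
  expect_lt(res$per_condition$Regulation$mean_tbr,
            res$per_condition$Rest$mean_tbr)
  # rejection accounting
  res2 <- transfer_tbr(rec, blocks, reject_idx = c(1, 2))
  expect_equal(res2$per_condition$Rest$n_epochs, 16L)
  expect_equal(res2$per_condition$Rest$n_rejected, 2L)
  # all epochs of one condition rejected -> explicit error naming it
  rest_idx <- res$epochs$epoch[res$epochs$condition == "Rest"]
  expect_error(transfer_tbr(rec, blocks, reject_idx = rest_idx), "Rest")
})

test_that("offline band powers equal the engine's band_power bit-for-bit", {
  rec <- make_recording(8, seed = 17)
  cfg <- engine_config()
  i_fz <- match("Fz", rec$ch_names)
  blocks <- data.frame(onset = 0, duration = 8, trial_type = "Rest")
  # transfer_tbr should use the same band_power on [0, 10)... here 8 s gives
  # no complete epoch; use 10 s fixture instead
  rec10 <- make_recording(10, seed = 17)
  res <- transfer_tbr(rec10, data.frame(onset = 0, duration = 30,
                                        trial_type = "Rest"))
  x <- rec10$data[match("Fz", rec10$ch_names), 1:(10 * 500)]
  expect_equal(res$epochs$theta[1], band_power(x, 500, cfg$theta_band),
               tolerance = 1e-9)
})
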