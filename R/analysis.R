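# Offline analysis: preprocessing of VR-session EEG (1-40 Hz FIR bandpass,
# 50 Hz notch, bad-segment masking, spherical-spline channel interpolation,
# average reference, optional ICA hook) and the session / transfer TBR
# statistics. The session statistic is
#   TBR_relative = mean TBR_helicopter - mean TBR_baseline
# with the baseline the first 20 s of the arithmetic task; training periods
# compare sessions 1-4 against sessions 5-8.

#' Preprocess a VR-session recording
#'
#' FIR bandpass 1-40 Hz, 50 Hz notch, optional ICA component-removal hook
#' (a function `rec -> rec`; the protocol's manual component selection is
#' external), spherical-spline interpolation of bad channels, average
#' reference last. Bad segments are not cut: they are recorded in
#' `meta$bad_mask` (a logical per-sample mask) so downstream statistics can
#' exclude them explicitly.
#'
#' @param rec an [eeg_recording()] with `sfreq >= 100`.
#' @param bad_annotations data.frame (`onset`, `duration`) of artifact
#'   segments to mask, or `NULL`.
#' @param bad_channels labels of channels to interpolate, or `NULL`.
#' @param ica_excluder optional function applied between filtering and
#'   interpolation.
#' @param band bandpass edges (Hz).
#' @param notch_hz line frequency to notch (0 disables).
#' @return the preprocessed recording; `meta$bad_mask`, `meta$bad_channels`
#'   and `meta$preprocess` document every decision.
#' @export
preprocess_vr <- function(rec, bad_annotations = NULL, bad_channels = NULL,
                          ica_excluder = NULL, band = c(1, 40),
                          notch_hz = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$sfreq < 100) stop_nfb("sfreq must be >= 100 Hz")
  eeg_idx <- which(rec$ch_roles == "eeg")
  if (!is.null(bad_channels) &&
      length(setdiff(rec$ch_names[eeg_idx], bad_channels)) == 0L) {
    stop_nfb("all channels are bad")
  }
  h_bp <- fir_bandpass(band[1], band[2], rec$sfreq,
                       trans_bw_hz = min(2 * band[1], 10))
  for (ch in eeg_idx) rec$data[ch, ] <- fir_apply(rec$data[ch, ], h_bp)
  if (notch_hz > 0 && notch_hz < rec$sfreq / 2) {
    h_bs <- fir_bandstop(notch_hz - 2, notch_hz + 2, rec$sfreq,
                         trans_bw_hz = 2)
    for (ch in eeg_idx) rec$data[ch, ] <- fir_apply(rec$data[ch, ], h_bs)
  }
  if (!is.null(ica_excluder)) rec <- ica_excluder(rec)
  if (!is.null(bad_channels) && length(bad_channels)) {
    rec <- interpolate_channels(rec, bad_channels)
  }
  rec$data <- average_reference(rec$data, rec$ch_roles)
  mask <- rep(FALSE, ncol(rec$data))
  if (!is.null(bad_annotations) && nrow(bad_annotations)) {
    for (i in seq_len(nrow(bad_annotations))) {
      i1 <- max(1L, floor(bad_annotations$onset[i] * rec$sfreq) + 1L)
      i2 <- min(ncol(rec$data),
                ceiling((bad_annotations$onset[i] +
                           bad_annotations$duration[i]) * rec$sfreq))
      if (i2 >= i1) mask[i1:i2] <- TRUE
    }
  }
  rec$meta$bad_mask <- mask
  rec$meta$bad_channels <- bad_channels %||% character(0)
  rec$meta$preprocess <- list(band = band, notch_hz = notch_hz,
                              ica = !is.null(ica_excluder))
  rec
}

#' Session-level TBR statistic
#'
#' Means are taken over ungated TBR samples only. The helicopter mean pools
#' the samples inside every event labelled `helicopter_run`; the baseline is
#' the first 20 s after the `calc_task` onset. The session statistic is
#' their difference (helicopter minus baseline).
#'
#' @param tbr_samples data.frame from [stream_tbr()] (columns `t`,
#'   `tbr_raw`, `gated`).
#' @param events event data.frame with `onset`, `duration`, `trial_type`
#'   containing `helicopter_run` rows and one `calc_task` row.
#' @param baseline_s baseline window length after the task onset (20).
#' @param session_id optional identifier carried through.
#' @return list of class `session_tbr`: `mean_tbr_helicopter`,
#'   `mean_tbr_baseline`, `tbr_relative`, sample counts.
#' @export
session_tbr <- function(tbr_samples, events, baseline_s = 20,
                        session_id = NA) {
  heli <- events[events$trial_type == "helicopter_run", , drop = FALSE]
  calc <- events[events$trial_type == "calc_task", , drop = FALSE]
  if (!nrow(heli)) stop_nfb("no 'helicopter_run' events found")
  if (!nrow(calc)) stop_nfb("no 'calc_task' event found")
  ok <- !tbr_samples$gated & is.finite(tbr_samples$tbr_raw)
  in_heli <- rep(FALSE, nrow(tbr_samples))
  for (i in seq_len(nrow(heli))) {
    in_heli <- in_heli | (tbr_samples$t >= heli$onset[i] &
                            tbr_samples$t < heli$onset[i] + heli$duration[i])
  }
  b0 <- calc$onset[1L]
  in_base <- tbr_samples$t >= b0 & tbr_samples$t < b0 + baseline_s
  mh <- mean(tbr_samples$tbr_raw[ok & in_heli])
  mb <- mean(tbr_samples$tbr_raw[ok & in_base])
  structure(list(session_id = session_id,
                 mean_tbr_helicopter = mh, mean_tbr_baseline = mb,
                 tbr_relative = mh - mb,
                 n_helicopter = sum(ok & in_heli),
                 n_baseline = sum(ok & in_base),
                 n_gated_excluded = sum(!ok & (in_heli | in_base))),
            class = "session_tbr")
}

#' Training-period summary across eight sessions
#'
#' Per child: period 1 is the mean `tbr_relative` of sessions 1-4, period 2
#' of sessions 5-8. Cohort means per session are also returned. Missing
#' sessions give a partial result with explicit flags.
#'
#' @param sessions data.frame with columns `child`, `session` (1..8),
#'   `tbr_relative`.
#' @return list: `per_child` (data.frame `child`, `period1_mean`,
#'   `period2_mean`, `complete`), `cohort_by_session` (data.frame
#'   `session`, `mean_tbr_relative`, `n`).
#' @export
period_summary <- function(sessions) {
  stopifnot(all(c("child", "session", "tbr_relative") %in% names(sessions)))
  if (any(!sessions$session %in% 1:8)) {
    stop_nfb("session ids must be in 1..8")
  }
  per_child <- do.call(rbind, lapply(split(sessions, sessions$child),
                                     function(s) {
    p1 <- s$tbr_relative[s$session %in% 1:4]
    p2 <- s$tbr_relative[s$session %in% 5:8]
    data.frame(child = s$child[1L],
               period1_mean = if (length(p1)) mean(p1) else NA_real_,
               period2_mean = if (length(p2)) mean(p2) else NA_real_,
               n_sessions = nrow(s),
               complete = nrow(s) == 8L)
  }))
  rownames(per_child) <- NULL
  cohort <- do.call(rbind, lapply(split(sessions, sessions$session),
                                  function(s) {
    data.frame(session = s$session[1L],
               mean_tbr_relative = mean(s$tbr_relative), n = nrow(s))
  }))
  rownames(cohort) <- NULL
  list(per_child = per_child, cohort_by_session = cohort)
}

#' Transfer-task TBR per condition
#'
#' Each 30 s Rest / Regulation block is divided into three non-overlapping
#' 10 s epochs fully inside the block; epochs listed in `reject_idx` are
#' dropped (and counted). Theta and beta power at the feedback channel use
#' the same [band_power()] as the real-time engine; per-condition means of
#' theta, beta and per-epoch TBR are reported.
#'
#' @param rec a cleaned, preprocessed [eeg_recording()].
#' @param blocks event data.frame (`onset`, `duration`, `trial_type` in
#'   `{"Rest", "Regulation"}`), e.g. from [transfer_paradigm()].
#' @param reject_idx integer indices of epochs to reject (in epoch order),
#'   or `NULL`.
#' @param config an [engine_config()] (bands, feedback channel).
#' @param epoch_s epoch length (10 s).
#' @return list of class `transfer_result`: per condition mean theta / beta
#'   power, mean TBR, `n_epochs`, `n_rejected`, plus the per-epoch table.
#' @export
transfer_tbr <- function(rec, blocks, reject_idx = NULL,
                         config = engine_config(), epoch_s = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  i_fb <- match(config$feedback_channel, rec$ch_names)
  if (is.na(i_fb)) stop_nfb("feedback channel '%s' missing",
                            config$feedback_channel)
  rows <- list()
  eid <- 0L
  for (b in seq_len(nrow(blocks))) {
    n_ep <- floor(blocks$duration[b] / epoch_s)
    for (e in seq_len(n_ep)) {
      eid <- eid + 1L
      t0 <- blocks$onset[b] + (e - 1L) * epoch_s
      i1 <- round(t0 * rec$sfreq) + 1L
      i2 <- i1 + round(epoch_s * rec$sfreq) - 1L
      if (i2 > ncol(rec$data)) next
      x <- rec$data[i_fb, i1:i2]
      th <- band_power(x, rec$sfreq, config$theta_band)
      be <- band_power(x, rec$sfreq, config$beta_band)
      rows[[length(rows) + 1L]] <-
        data.frame(epoch = eid, condition = blocks$trial_type[b],
                   t0 = t0, theta = th, beta = be,
                   tbr = if (be > 0) th / be else NA_real_,
                   rejected = eid %in% reject_idx)
    }
  }
  ep <- do.call(rbind, rows)
  out <- lapply(split(ep, ep$condition), function(s) {
    used <- s[!s$rejected & is.finite(s$tbr), , drop = FALSE]
    if (!nrow(used)) {
      stop_nfb("no surviving epochs in condition '%s'", s$condition[1L])
    }
    list(mean_theta = mean(used$theta), mean_beta = mean(used$beta),
         mean_tbr = mean(used$tbr), n_epochs = nrow(used),
         n_rejected = sum(s$rejected))
  })
  structure(list(per_condition = out, epochs = ep,
                 config = list(theta_band = config$theta_band,
                               beta_band = config$beta_band,
                               channel = config$feedback_channel,
                               epoch_s = epoch_s)),
            class = "transfer_result")
}
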