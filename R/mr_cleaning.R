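# Offline correction of MR gradient and ballistocardiogram (BCG) artifacts
# by hybrid mean/median moving-template subtraction: for every time point of
# the template the values of the L neighbouring artifact occurrences are
# sorted and the K smallest and K largest excluded before averaging
# (gradient: L = 30, K = 6; pulse: L = 40, K = 5). The trimmed template is
# robust to head-movement outlier epochs. The printed chain order is
# gradient subtraction -> 70 Hz FIR lowpass -> downsample to 500 Hz ->
# QRS detection -> pulse subtraction.

#' Template parameters (trimmed moving average)
#'
#' @param L number of neighbouring artifact occurrences entering each
#'   template.
#' @param K occurrences excluded at each extreme after sorting
#'   (`L > 2K >= 0`).
#' @return list of class `template_params`.
#' @export
template_params <- function(L, K) {
  stopifnot(L > 2 * K, K >= 0)
  structure(list(L = as.integer(L), K = as.integer(K)),
            class = "template_params")
}

#' Build a trimmed-mean artifact template
#'
#' Per time point: sort the `L` values across epochs, drop the `K` smallest
#' and `K` largest, average the remaining `L - 2K`. `K = 0` reduces to the
#' plain moving average.
#'
#' @param epochs numeric matrix, `L x epoch_len`: the L neighbouring
#'   artifact epochs of one channel.
#' @param K values excluded at each extreme.
#' @return numeric template waveform of length `epoch_len`.
#' @export
build_template <- function(epochs, K) {
  epochs <- as.matrix(epochs)
  L <- nrow(epochs); len <- ncol(epochs)
  if (L <= 2 * K) stop_nfb("need L > 2K (L=%d, K=%d)", L, K)
  if (K == 0L) return(colMeans(epochs))
  # column-wise sort in one radix pass
  sorted <- matrix(epochs[order(col(epochs), epochs)], nrow = L)
  colMeans(sorted[(K + 1L):(L - K), , drop = FALSE])
}

#' Artifact occurrences
#'
#' @param onsets occurrence onsets (s): TR markers for the gradient
#'   artifact, R-peaks (plus delay) for the pulse artifact.
#' @param epoch_len epoch length in samples.
#' @return list of class `artifact_occurrences`.
#' @export
artifact_occurrences <- function(onsets, epoch_len) {
  onsets <- sort(as.numeric(onsets))
  stopifnot(epoch_len >= 1)
  structure(list(onsets = onsets, epoch_len = as.integer(round(epoch_len))),
            class = "artifact_occurrences")
}

# Index window of the L temporally nearest occurrences, centred (floor(L/2)
# before, rest after), shifted at the edges.
neighbor_window <- function(i, n, L) {
  half <- L %/% 2L
  lo <- i - half
  hi <- lo + L - 1L
  if (lo < 1L) { lo <- 1L; hi <- L }
  if (hi > n) { hi <- n; lo <- n - L + 1L }
  lo:hi
}

#' Subtract a repeating artifact by trimmed-template subtraction
#'
#' Every artifact epoch gets the template built from its `L` temporally
#' nearest occurrences subtracted, per channel. Edge occurrences use the
#' nearest available `L`. Annotations are preserved.
#'
#' @param rec an [eeg_recording()].
#' @param occ an [artifact_occurrences()] with at least `L` onsets inside
#'   the recording.
#' @param params a [template_params()].
#' @param channels channel labels to clean (default: all).
#' @return the cleaned recording.
#' @export
subtract_artifact <- function(rec, occ, params, channels = rec$ch_names) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(occ, "artifact_occurrences"),
            inherits(params, "template_params"))
  ns <- ncol(rec$data)
  starts <- round(occ$onsets * rec$sfreq) + 1L
  keep <- starts >= 1L & starts <= ns
  starts <- starts[keep]
  n_occ <- length(starts)
  if (n_occ < params$L) {
    stop_nfb("only %d artifact occurrences, need >= L = %d", n_occ, params$L)
  }
  len <- occ$epoch_len
  ch_idx <- match(channels, rec$ch_names)
  if (anyNA(ch_idx)) stop_nfb("unknown channel in 'channels'")
  # per-occurrence usable length (last epoch may be truncated by the edge)
  use_len <- pmin(len, ns - starts + 1L)
  for (ch in ch_idx) {
    x <- rec$data[ch, ]
    # epoch matrix padded with NA beyond the recording end
    E <- matrix(NA_real_, n_occ, len)
    for (i in seq_len(n_occ)) {
      E[i, seq_len(use_len[i])] <- x[starts[i]:(starts[i] + use_len[i] - 1L)]
    }
    for (i in seq_len(n_occ)) {
      nb <- neighbor_window(i, n_occ, params$L)
      Enb <- E[nb, , drop = FALSE]
      # columns fully observed across the neighbourhood get the trimmed
      # mean; columns with missing tails fall back to the available mean
      complete <- colSums(is.na(Enb)) == 0L
      tmpl <- numeric(len)
      if (any(complete)) {
        tmpl[complete] <- build_template(Enb[, complete, drop = FALSE],
                                         params$K)
      }
      if (any(!complete)) {
        tmpl[!complete] <- colMeans(Enb[, !complete, drop = FALSE],
                                    na.rm = TRUE)
        tmpl[is.nan(tmpl)] <- 0
      }
      seg <- seq_len(use_len[i])
      x[starts[i]:(starts[i] + use_len[i] - 1L)] <-
        x[starts[i]:(starts[i] + use_len[i] - 1L)] - tmpl[seg]
    }
    rec$data[ch, ] <- x
  }
  rec
}

#' FIR lowpass and integer downsampling
#'
#' Applies a 70 Hz finite-impulse-response lowpass (half-amplitude at the
#' cutoff, ~53 dB stopband) and decimates to the target rate. Annotations,
#' stored in seconds, are untouched.
#'
#' @param rec an [eeg_recording()].
#' @param cutoff_hz lowpass cutoff (Hz).
#' @param target_sfreq output rate (Hz); must divide the input rate.
#' @param trans_bw_hz transition bandwidth (Hz).
#' @return the filtered, downsampled recording.
#' @export
lowpass_downsample <- function(rec, cutoff_hz = 70, target_sfreq = 500,
                               trans_bw_hz = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (cutoff_hz >= target_sfreq / 2) {
    stop_nfb("cutoff %g Hz is above the target Nyquist %g Hz",
             cutoff_hz, target_sfreq / 2)
  }
  factor <- rec$sfreq / target_sfreq
  if (abs(factor - round(factor)) > 1e-9) {
    stop_nfb("target rate must divide the source rate evenly")
  }
  factor <- as.integer(round(factor))
  h <- fir_lowpass(cutoff_hz + trans_bw_hz / 2, rec$sfreq, trans_bw_hz)
  out <- matrix(0, nrow(rec$data), ceiling(ncol(rec$data) / factor))
  for (ch in seq_len(nrow(rec$data))) {
    y <- fir_apply(rec$data[ch, ], h)
    out[ch, ] <- y[seq(1L, length(y), by = factor)]
  }
  eeg_recording(out, target_sfreq, rec$ch_names, rec$ch_roles,
                rec$annotations, rec$meta)
}

#' Detect R-peaks in an ECG channel
#'
#' Derivative-energy-threshold (Pan-Tompkins-style) design: 5-15 Hz
#' bandpass, differentiation, squaring, 150 ms moving-window integration,
#' adaptive threshold with a 300 ms refractory period, and refinement of
#' each detection to the maximum of the squared bandpassed signal. Squaring
#' makes detection polarity-robust.
#'
#' @param ecg numeric vector, one ECG channel (microvolts).
#' @param sfreq sampling rate (Hz).
#' @return R-peak onsets in seconds.
#' @export
detect_qrs <- function(ecg, sfreq) {
  if (length(ecg) < 2 * sfreq) stop_nfb("ECG shorter than 2 s")
  if (stats::sd(ecg) < 1e-9) stop_nfb("flat ECG signal: no beats found")
  bp <- fir_apply(ecg - mean(ecg), fir_bandpass(5, 15, sfreq, 5))
  sq <- (c(diff(bp), 0))^2
  w <- max(1L, round(0.150 * sfreq))
  integ <- stats::filter(sq, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)
  thr <- 0.3 * stats::quantile(integ, 0.995)
  refract <- round(0.300 * sfreq)
  cand <- which(integ > thr)
  if (!length(cand)) stop_nfb("no beats above threshold")
  peaks <- integer(0)
  last <- -Inf
  i <- 1L
  n <- length(integ)
  while (i <= length(cand)) {
    s <- cand[i]
    if (s - last < refract) { i <- i + 1L; next }
    # local maximum of the integrated energy in the next 300 ms
    e <- min(n, s + refract)
    pk <- s - 1L + which.max(integ[s:e])
    # refine to the squared bandpassed maximum within +/- 100 ms
    r1 <- max(1L, pk - round(0.1 * sfreq))
    r2 <- min(n, pk + round(0.1 * sfreq))
    pk <- r1 - 1L + which.max(bp[r1:r2]^2)
    peaks <- c(peaks, pk)
    last <- pk
    i <- which(cand > pk + refract)[1L]
    if (is.na(i)) break
  }
  (peaks - 1L) / sfreq
}

#' Full MR-artifact cleaning chain
#'
#' Gradient template subtraction (`L = 30, K = 6`) on every channel, 70 Hz
#' FIR lowpass, downsampling to 500 Hz, QRS detection on the (gradient-
#' cleaned) ECG channel, then pulse template subtraction (`L = 40, K = 5`)
#' on the scalp channels, epochs starting `bcg_delay_s` after each R-peak
#' with length the median RR interval. The ECG channel itself is logged
#' before pulse subtraction and never altered by it.
#'
#' @param rec an [eeg_recording()] at the MR sampling rate (5 kHz)
#'   containing an ECG channel.
#' @param tr_onsets TR marker onsets (s) from the events table.
#' @param params_grad,params_pulse [template_params()] for the gradient and
#'   pulse stages.
#' @param target_sfreq output rate (Hz).
#' @param bcg_delay_s delay of the pulse-artifact epoch after each R-peak.
#' @return the cleaned recording at `target_sfreq`; `meta$qc` holds the QC
#'   report: `(L, K)` pairs, per-channel pre/post RMS, residual power at the
#'   TR fundamental and harmonics, detected R-peaks.
#' @export
clean_mr_pipeline <- function(rec, tr_onsets,
                              params_grad = template_params(30, 6),
                              params_pulse = template_params(40, 5),
                              target_sfreq = 500, bcg_delay_s = 0.21) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!length(tr_onsets)) stop_nfb("TR markers are required")
  if (!any(rec$ch_roles == "ecg")) stop_nfb("ECG channel is required")
  rms <- function(m) sqrt(rowMeans(m^2))
  pre_rms <- rms(rec$data)

  tr_period <- stats::median(diff(sort(tr_onsets)))
  occ_grad <- artifact_occurrences(tr_onsets,
                                   epoch_len = round(tr_period * rec$sfreq))
  step1 <- subtract_artifact(rec, occ_grad, params_grad)
  step2 <- lowpass_downsample(step1, cutoff_hz = 70,
                              target_sfreq = target_sfreq)
  ecg_ch <- which(step2$ch_roles == "ecg")[1L]
  ecg_logged <- step2$data[ecg_ch, ]
  r_peaks <- detect_qrs(step2$data[ecg_ch, ], step2$sfreq)
  if (length(r_peaks) >= 2L) {
    rr <- stats::median(diff(r_peaks))
    occ_pulse <- artifact_occurrences(r_peaks + bcg_delay_s,
                                      epoch_len = round(rr * step2$sfreq))
    scalp <- step2$ch_names[step2$ch_roles == "eeg"]
    if (length(r_peaks) >= params_pulse$L) {
      step3 <- subtract_artifact(step2, occ_pulse, params_pulse,
                                 channels = scalp)
    } else {
      warning(sprintf("only %d R-peaks; pulse subtraction skipped (needs L=%d)",
                      length(r_peaks), params_pulse$L))
      step3 <- step2
    }
  } else {
    step3 <- step2
  }
  step3$data[ecg_ch, ] <- ecg_logged
  post_rms <- rms(step3$data)

  # residual power at the TR fundamental and first harmonics, Fz-like first
  # scalp channel
  ch1 <- which(step3$ch_roles == "eeg")[1L]
  f0 <- 1 / tr_period
  harm <- f0 * (1:5)
  res_pow <- vapply(harm, function(f) {
    band_power(step3$data[ch1, ], step3$sfreq,
               c(max(0, f - 0.05), f + 0.05), taper = "none")
  }, 0)
  step3$meta$qc <- list(
    gradient_L = params_grad$L, gradient_K = params_grad$K,
    pulse_L = params_pulse$L, pulse_K = params_pulse$K,
    pre_rms = stats::setNames(pre_rms, rec$ch_names),
    post_rms = stats::setNames(post_rms, rec$ch_names),
    tr_harmonic_hz = harm, tr_harmonic_power = res_pow,
    r_peaks = r_peaks)
  step3
}
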