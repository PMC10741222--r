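# Synthetic EEG, ECG, artifacts, MR contamination and simulated-child
# behavior, all with exported ground truth so every downstream stage can be
# tested by injection-recovery. Every generator is a pure function of
# (params, seed).

#' Parameters of the latent attention process
#'
#' The "level of concentration" is modeled as a clipped mean-reverting
#' (Ornstein-Uhlenbeck-type) process on `[0, 1]`: two interpretable knobs,
#' the stationary target and the volatility.
#'
#' @param target stationary mean in `[0, 1]`.
#' @param volatility diffusion scale per sqrt(second); 0 gives a
#'   deterministic trace.
#' @param revert_rate mean-reversion rate (1/s).
#' @param start initial value (defaults to `target`).
#' @return list of class `attention_params`.
#' @export
attention_params <- function(target = 0.5, volatility = 0.15,
                             revert_rate = 0.2, start = target) {
  stopifnot(target >= 0, target <= 1, volatility >= 0, revert_rate > 0,
            start >= 0, start <= 1)
  structure(list(target = target, volatility = volatility,
                 revert_rate = revert_rate, start = start),
            class = "attention_params")
}

#' Simulate a latent attention trace
#'
#' @param duration_s trace length in seconds (> 0).
#' @param rate_hz sampling rate of the trace (> 0); 1 Hz suffices for the
#'   1 s engine hop.
#' @param params an [attention_params()].
#' @param seed integer RNG seed; identical inputs give identical traces.
#' @return list of class `attention_trace` with `values` in `[0,1]`,
#'   `rate_hz`, `seed`.
#' @export
simulate_attention_trace <- function(duration_s, rate_hz = 1,
                                     params = attention_params(), seed = 1) {
  stopifnot(duration_s > 0, rate_hz > 0)
  n <- max(2L, ceiling(duration_s * rate_hz) + 1L)
  dt <- 1 / rate_hz
  with_seed(seed, {
    eps <- stats::rnorm(n - 1L)
    v <- numeric(n)
    v[1L] <- params$start
    for (i in 2:n) {
      v[i] <- v[i - 1L] +
        params$revert_rate * (params$target - v[i - 1L]) * dt +
        params$volatility * sqrt(dt) * eps[i - 1L]
      v[i] <- clip(v[i], 0, 1)
    }
    structure(list(values = v, rate_hz = rate_hz, seed = seed,
                   params = params),
              class = "attention_trace")
  })
}

# Attention value at arbitrary times (linear interpolation, constant tails).
attention_at <- function(trace, t) {
  tt <- (seq_along(trace$values) - 1L) / trace$rate_hz
  stats::approx(tt, trace$values, xout = t, rule = 2L)$y
}

#' Parameters of the synthetic EEG signal model
#'
#' Band-limited theta/alpha/beta oscillations ride on pink background noise;
#' at frontal channels the theta amplitude decreases and the beta amplitude
#' increases linearly with the latent attention, so the raw TBR is strictly
#' decreasing in attention (the property the calibration chain needs).
#' Eye blinks land on frontopolar channels, and an ECG channel carries QRS
#' complexes at the configured heart rate.
#'
#' @param theta_band,alpha_band,beta_band band edges, Hz.
#' @param theta_amp,alpha_amp,beta_amp base RMS amplitudes (microvolts).
#' @param attention_gain linear coupling in `[0, 2)`: band scale =
#'   `amp * (1 +/- attention_gain * (attention - 0.5))` (minus for theta,
#'   plus for beta) at frontal channels.
#' @param frontal_channels channels receiving the attention coupling.
#' @param pink_amp pink-noise RMS amplitude (microvolts).
#' @param blink_rate mean blink rate (Hz) on `blink_channels`.
#' @param blink_amp blink peak amplitude (microvolts).
#' @param blink_channels frontopolar channels receiving blinks.
#' @param heart_rate_bpm ECG rate, beats per minute.
#' @param ecg_amp R-peak amplitude (microvolts).
#' @param osc_type `"narrowband"` (band-limited noise carriers, default) or
#'   `"tone"` (sinusoid at each band's center frequency).
#' @return list of class `synth_eeg_params`.
#' @export
synth_eeg_params <- function(theta_band = c(4, 7.5), alpha_band = c(8, 12),
                             beta_band = c(13, 19),
                             theta_amp = 10, alpha_amp = 6, beta_amp = 4,
                             attention_gain = 0.8,
                             frontal_channels = c("Fz", "F3", "F4", "Fp1", "Fp2"),
                             pink_amp = 4,
                             blink_rate = 0.2, blink_amp = 80,
                             blink_channels = c("Fp1", "Fp2"),
                             heart_rate_bpm = 90, ecg_amp = 800,
                             osc_type = c("narrowband", "tone")) {
  stopifnot(theta_band[1] < theta_band[2], beta_band[1] < beta_band[2],
            theta_band[2] < beta_band[1],
            theta_amp >= 0, alpha_amp >= 0, beta_amp >= 0, pink_amp >= 0,
            attention_gain >= 0, attention_gain < 2)
  structure(list(theta_band = theta_band, alpha_band = alpha_band,
                 beta_band = beta_band, theta_amp = theta_amp,
                 alpha_amp = alpha_amp, beta_amp = beta_amp,
                 attention_gain = attention_gain,
                 frontal_channels = frontal_channels, pink_amp = pink_amp,
                 blink_rate = blink_rate, blink_amp = blink_amp,
                 blink_channels = blink_channels,
                 heart_rate_bpm = heart_rate_bpm, ecg_amp = ecg_amp,
                 osc_type = match.arg(osc_type)),
            class = "synth_eeg_params")
}

#' Default 32-channel montage (10-20 cap + one ECG channel)
#' @return character vector of channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "ECG")
}

# Synthetic ECG: one stylized PQRST complex per beat (sum of Gaussians).
synth_ecg <- function(n, sfreq, heart_rate_bpm, amp, seed_offset_rng = TRUE) {
  rr <- 60 / heart_rate_bpm
  # small physiological RR jitter (2%)
  peaks <- c()
  t <- rr * (0.3 + 0.4 * stats::runif(1))
  while (t < n / sfreq) {
    peaks <- c(peaks, t)
    t <- t + rr * (1 + 0.02 * stats::rnorm(1))
  }
  tt <- (0:(n - 1L)) / sfreq
  x <- numeric(n)
  add_wave <- function(center, width, a) {
    lo <- max(1L, floor((center - 4 * width) * sfreq))
    hi <- min(n, ceiling((center + 4 * width) * sfreq))
    if (hi < lo) return()
    idx <- lo:hi
    x[idx] <<- x[idx] + a * exp(-((tt[idx] - center)^2) / (2 * width^2))
  }
  for (p in peaks) {
    add_wave(p - 0.18, 0.035, 0.12 * amp)   # P
    add_wave(p - 0.025, 0.010, -0.15 * amp) # Q
    add_wave(p, 0.012, amp)                 # R
    add_wave(p + 0.025, 0.010, -0.20 * amp) # S
    add_wave(p + 0.28, 0.060, 0.25 * amp)   # T
  }
  list(signal = x, r_peaks = peaks)
}

#' Synthesize a multichannel EEG recording from an attention trace
#'
#' @param trace an [attention_trace][simulate_attention_trace()] covering the
#'   requested duration.
#' @param ch_names channel labels; defaults to [default_montage()]. Any
#'   channel named `ECG` (case-insensitive) becomes the ECG channel.
#' @param sfreq sampling rate, Hz.
#' @param params a [synth_eeg_params()].
#' @param seed integer RNG seed.
#' @param duration_s optional duration; defaults to the trace length.
#' @return an [eeg_recording()] whose `meta` carries the ground truth:
#'   `attention` (the trace), per-band envelopes at `Fz` (`theta_env`,
#'   `beta_env`, at `sfreq`), and `r_peaks` (seconds).
#' @export
synthesize_eeg <- function(trace, ch_names = default_montage(), sfreq = 500,
                           params = synth_eeg_params(), seed = 1,
                           duration_s = NULL) {
  stopifnot(inherits(trace, "attention_trace"))
  trace_dur <- (length(trace$values) - 1L) / trace$rate_hz
  duration_s <- duration_s %||% trace_dur
  if (duration_s > trace_dur + 1e-9) {
    stop_nfb("trace (%g s) does not cover requested duration (%g s)",
             trace_dur, duration_s)
  }
  n <- round(duration_s * sfreq)
  tt <- (0:(n - 1L)) / sfreq
  att <- attention_at(trace, tt)
  nch <- length(ch_names)
  is_ecg <- tolower(ch_names) == "ecg"

  with_seed(seed, {
    carrier <- function(band) {
      switch(params$osc_type,
             tone = {
               f0 <- mean(band)
               sqrt(2) * sin(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))
             },
             narrowband = narrowband_noise(n, sfreq, band[1], band[2]))
    }
    g <- params$attention_gain
    theta_env_frontal <- params$theta_amp * (1 - g * (att - 0.5))
    beta_env_frontal  <- params$beta_amp * (1 + g * (att - 0.5))

    data <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      if (is_ecg[ch]) next
      frontal <- ch_names[ch] %in% params$frontal_channels
      th_env <- if (frontal) theta_env_frontal else rep(params$theta_amp, n)
      be_env <- if (frontal) beta_env_frontal else rep(params$beta_amp, n)
      x <- numeric(n)
      if (params$theta_amp > 0) x <- x + th_env * carrier(params$theta_band)
      if (params$alpha_amp > 0) x <- x + params$alpha_amp * carrier(params$alpha_band)
      if (params$beta_amp > 0) x <- x + be_env * carrier(params$beta_band)
      if (params$pink_amp > 0) x <- x + params$pink_amp * pink_noise(n)
      data[ch, ] <- x
    }
    # eye blinks: ~300 ms positive deflections on frontopolar channels
    blink_idx <- which(ch_names %in% params$blink_channels)
    blink_times <- c()
    if (length(blink_idx) && params$blink_rate > 0 && params$blink_amp > 0) {
      n_blinks <- stats::rpois(1L, params$blink_rate * duration_s)
      if (n_blinks > 0) {
        blink_times <- sort(stats::runif(n_blinks, 0.2, duration_s - 0.2))
        for (b in blink_times) {
          shape <- params$blink_amp * exp(-((tt - b)^2) / (2 * 0.06^2))
          for (ch in blink_idx) data[ch, ] <- data[ch, ] + shape
        }
      }
    }
    r_peaks <- numeric(0)
    if (any(is_ecg)) {
      ecg <- synth_ecg(n, sfreq, params$heart_rate_bpm, params$ecg_amp)
      data[which(is_ecg)[1L], ] <- ecg$signal
      r_peaks <- ecg$r_peaks
    }
    eeg_recording(data, sfreq, ch_names,
                  ch_roles = ifelse(is_ecg, "ecg", "eeg"),
                  meta = list(attention = trace,
                              theta_env = theta_env_frontal,
                              beta_env = beta_env_frontal,
                              r_peaks = r_peaks,
                              blink_times = blink_times,
                              params = params, seed = seed))
  })
}

#' Inject jaw-muscle bursts
#'
#' Adds Hanning-shaped broadband (default 20-140 Hz) bursts on the listed
#' channels only, and records each burst in the annotations with label
#' `"muscle"`.
#'
#' @param rec an [eeg_recording()].
#' @param times numeric vector of burst onsets (s), or a data.frame with
#'   columns `onset` and `duration`.
#' @param channels channel labels receiving the bursts.
#' @param amplitude burst RMS amplitude (microvolts).
#' @param band burst frequency band (Hz); upper edge is capped at Nyquist.
#'   The spectrum rolls off with 15 Hz raised-cosine skirts rather than a
#'   brick wall, so a 20-140 Hz jaw burst still carries energy in the
#'   13-19 Hz beta band the gate watches (as real EMG does).
#' @param duration_s default burst duration when `times` is a plain vector.
#' @param seed RNG seed for the burst carrier noise.
#' @return the modified recording.
#' @export
inject_muscle_bursts <- function(rec, times, channels = "T7", amplitude = 50,
                                 band = c(20, 140), duration_s = 0.5,
                                 seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing_ch <- setdiff(channels, rec$ch_names)
  if (length(missing_ch)) stop_nfb("channel '%s' not found", missing_ch[1L])
  if (is.data.frame(times)) {
    onsets <- times$onset; durs <- times$duration
  } else {
    onsets <- as.numeric(times); durs <- rep(duration_s, length(onsets))
  }
  if (!length(onsets)) return(rec)
  dur_rec <- rec_duration(rec)
  if (any(onsets < 0) || any(onsets + durs > dur_rec + 1e-9)) {
    stop_nfb("burst times fall outside the recording")
  }
  band[2] <- min(band[2], 0.95 * rec$sfreq / 2)
  idx <- match(channels, rec$ch_names)
  with_seed(seed, {
    for (k in seq_along(onsets)) {
      i1 <- floor(onsets[k] * rec$sfreq) + 1L
      i2 <- min(ncol(rec$data), ceiling((onsets[k] + durs[k]) * rec$sfreq))
      nb <- i2 - i1 + 1L
      burst <- amplitude *
        narrowband_noise(nb, rec$sfreq, band[1], band[2], edge_hz = 15) *
        hanning_window(nb)
      for (ch in idx) rec$data[ch, i1:i2] <- rec$data[ch, i1:i2] + burst
    }
    rec$annotations <- rbind(rec$annotations,
                             data.frame(onset = onsets, duration = durs,
                                        label = "muscle"))
    rec$annotations <- rec$annotations[order(rec$annotations$onset), ]
    rownames(rec$annotations) <- NULL
    rec
  })
}

#' Parameters of MR contamination
#'
#' @param tr repetition time (s); the gradient artifact period.
#' @param gradient_amp gradient artifact amplitude (microvolts; default
#'   10 mV, i.e. orders of magnitude above EEG).
#' @param gradient_tail_frac fraction of each TR left artifact-free at the
#'   end of the template (silent tail).
#' @param jitter_s sub-sample onset jitter of each gradient occurrence (s).
#' @param bcg_amp ballistocardiogram amplitude (microvolts).
#' @param bcg_delay_s delay of the BCG pulse after each R-peak (s).
#' @param target_sfreq output sampling rate (Hz), 5 kHz for in-MRI.
#' @return list of class `mr_contamination_params`.
#' @export
mr_contamination_params <- function(tr = 1.760, gradient_amp = 10000,
                                    gradient_tail_frac = 0.1,
                                    jitter_s = 0, bcg_amp = 150,
                                    bcg_delay_s = 0.21,
                                    target_sfreq = 5000) {
  stopifnot(tr > 0, gradient_amp >= 0, bcg_amp >= 0, target_sfreq > 0,
            gradient_tail_frac >= 0, gradient_tail_frac < 1)
  structure(list(tr = tr, gradient_amp = gradient_amp,
                 gradient_tail_frac = gradient_tail_frac,
                 jitter_s = jitter_s, bcg_amp = bcg_amp,
                 bcg_delay_s = bcg_delay_s, target_sfreq = target_sfreq),
            class = "mr_contamination_params")
}

# One TR worth of gradient waveform: harmonics of the slice frequency with
# sharp edges, plus a silent tail. Deterministic given the RNG state.
gradient_template_waveform <- function(len, sfreq, tr, tail_frac, amp) {
  tt <- (0:(len - 1L)) / sfreq
  n_slices <- 32
  f_slice <- n_slices / tr
  x <- numeric(len)
  for (h in 1:6) {
    x <- x + (1 / h) * sin(2 * pi * h * f_slice * tt + stats::runif(1, 0, 2 * pi))
  }
  active <- tt < (1 - tail_frac) * tr
  x[!active] <- 0
  x <- x / max(abs(x)) * amp
  x
}

# Smooth damped-oscillation BCG pulse (~0.45 s, energy below ~4 Hz, no
# sharp attack: physiological ballistocardiogram waveforms rise over tens
# of milliseconds).
bcg_waveform <- function(sfreq, amp, dur = 0.45) {
  n <- round(dur * sfreq)
  tt <- (0:(n - 1L)) / sfreq
  w <- sin(2 * pi * 2.2 * tt) * exp(-((tt - 0.16)^2) / (2 * 0.09^2))
  amp * w / max(abs(w))
}

#' Contaminate a clean recording with MR gradient and BCG artifacts
#'
#' Upsamples the clean recording to `target_sfreq` (cubic spline; the clean
#' signal is band-limited far below the original Nyquist), adds a strictly
#' periodic gradient artifact on every channel and an R-peak-locked BCG
#' pulse on every scalp channel, and returns the contaminated recording
#' together with the untouched ground truth and an event table of TR markers
#' and R-peaks.
#'
#' @param rec_clean an [eeg_recording()] containing an ECG channel; its
#'   `meta$r_peaks` (from [synthesize_eeg()]) is used when present, else
#'   R-peaks are detected with [detect_qrs()].
#' @param params an [mr_contamination_params()].
#' @param seed RNG seed (gradient harmonic phases, per-channel BCG scaling).
#' @return list with `contaminated` (at `target_sfreq`), `ground_truth`
#'   (the input), and `events` (TR markers `tr`, R-peaks `r_peak`).
#' @export
contaminate_mr <- function(rec_clean, params = mr_contamination_params(),
                           seed = 1) {
  stopifnot(inherits(rec_clean, "eeg_recording"))
  if (!any(rec_clean$ch_roles == "ecg")) {
    stop_nfb("rec_clean must contain an ecg channel")
  }
  sf_out <- params$target_sfreq
  factor <- sf_out / rec_clean$sfreq
  if (abs(factor - round(factor)) > 1e-9) {
    stop_nfb("target_sfreq must be an integer multiple of the clean rate")
  }
  factor <- as.integer(round(factor))
  nch <- nrow(rec_clean$data)
  n_out <- ncol(rec_clean$data) * factor
  dur <- n_out / sf_out
  tr_len <- round(params$tr * sf_out)
  if (tr_len < 2L) stop_nfb("tr shorter than template resolution")

  up <- matrix(0, nch, n_out)
  for (ch in seq_len(nch)) {
    up[ch, ] <- if (factor == 1L) rec_clean$data[ch, ] else
      upsample_spline(rec_clean$data[ch, ], factor)
  }

  r_peaks <- rec_clean$meta$r_peaks
  if (is.null(r_peaks) || !length(r_peaks)) {
    ecg_ch <- which(rec_clean$ch_roles == "ecg")[1L]
    r_peaks <- detect_qrs(rec_clean$data[ecg_ch, ], rec_clean$sfreq)
  }

  with_seed(seed, {
    tr_onsets <- seq(0, dur - params$tr, by = params$tr)
    grad <- gradient_template_waveform(tr_len, sf_out, params$tr,
                                       params$gradient_tail_frac,
                                       params$gradient_amp)
    # per-channel gradient gain (coupling differs slightly across leads)
    g_gain <- stats::runif(nch, 0.8, 1.2)
    contaminated <- up
    if (params$gradient_amp > 0) {
      for (k in seq_along(tr_onsets)) {
        jit <- if (params$jitter_s > 0) stats::runif(1, -params$jitter_s,
                                                     params$jitter_s) else 0
        i1 <- round((tr_onsets[k] + jit) * sf_out) + 1L
        i2 <- min(n_out, i1 + tr_len - 1L)
        if (i1 > n_out) break
        seg <- 1L:(i2 - i1 + 1L)
        for (ch in seq_len(nch)) {
          contaminated[ch, i1:i2] <- contaminated[ch, i1:i2] +
            g_gain[ch] * grad[seg]
        }
      }
    }
    if (params$bcg_amp > 0 && length(r_peaks)) {
      pulse <- bcg_waveform(sf_out, params$bcg_amp)
      b_gain <- stats::runif(nch, 0.6, 1.4)
      scalp <- which(rec_clean$ch_roles == "eeg")
      for (p in r_peaks) {
        i1 <- round((p + params$bcg_delay_s) * sf_out) + 1L
        i2 <- min(n_out, i1 + length(pulse) - 1L)
        if (i1 > n_out) next
        seg <- 1L:(i2 - i1 + 1L)
        for (ch in scalp) {
          contaminated[ch, i1:i2] <- contaminated[ch, i1:i2] +
            b_gain[ch] * pulse[seg]
        }
      }
    }
    events <- rbind(
      data.frame(onset = tr_onsets, duration = params$tr, trial_type = "tr"),
      data.frame(onset = r_peaks, duration = 0, trial_type = "r_peak"))
    events <- events[order(events$onset), ]
    rownames(events) <- NULL
    rec_out <- eeg_recording(contaminated, sf_out, rec_clean$ch_names,
                             rec_clean$ch_roles,
                             meta = list(tr_onsets = tr_onsets,
                                         r_peaks = r_peaks,
                                         params = params))
    list(contaminated = rec_out, ground_truth = rec_clean, events = events)
  })
}

#' Simulate per-trial behavior of a child
#'
#' Omission probability decreases with attention; reaction time increases by
#' a fixed offset on trials carrying a distraction flag. With zero noise and
#' full attention every go trial is answered at the baseline RT.
#'
#' @param trace an [attention_trace][simulate_attention_trace()].
#' @param trials data.frame with columns `onset` (s), `is_nogo` (logical)
#'   and optionally `distracted` (logical).
#' @param params list: `base_rt_ms` (default 450), `rt_sd_ms` (60),
#'   `distraction_rt_offset_ms` (50), `attention_rt_slope_ms` (100; RT
#'   increases as attention falls), `omission_max` (0.4; omission
#'   probability is `omission_max * (1 - attention)`),
#'   `commission_prob` (0.25).
#' @param seed RNG seed.
#' @return data.frame per trial: `responded`, `rt_ms` (NA when no response).
#' @export
simulate_responses <- function(trace, trials, params = list(), seed = 1) {
  if (!nrow(trials)) stop_nfb("trials must be non-empty")
  p <- utils::modifyList(list(base_rt_ms = 450, rt_sd_ms = 60,
                              distraction_rt_offset_ms = 50,
                              attention_rt_slope_ms = 100,
                              omission_max = 0.4, commission_prob = 0.25),
                         params)
  att <- attention_at(trace, trials$onset)
  distracted <- if ("distracted" %in% names(trials)) trials$distracted else
    rep(FALSE, nrow(trials))
  with_seed(seed, {
    n <- nrow(trials)
    responded <- logical(n)
    rt <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (trials$is_nogo[i]) {
        responded[i] <- stats::runif(1) < p$commission_prob * (1 - 0.5 * att[i])
      } else {
        responded[i] <- stats::runif(1) >= p$omission_max * (1 - att[i])
      }
      if (responded[i]) {
        rt[i] <- p$base_rt_ms +
          p$attention_rt_slope_ms * (1 - att[i]) +
          p$distraction_rt_offset_ms * distracted[i] +
          p$rt_sd_ms * stats::rnorm(1)
        rt[i] <- max(rt[i], 120)
      }
    }
    data.frame(responded = responded, rt_ms = rt)
  })
}
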