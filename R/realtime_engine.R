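# Streaming theta/beta-ratio (TBR) engine.
#
# Every second a 3 s Hanning window ending "now" is average-referenced, the
# spectral power at Fz is computed in the theta (4-7.5 Hz) and beta
# (13-19 Hz) bands, and their ratio is emitted. A jaw-muscle gate zeroes the
# transmitted feedback whenever beta power at the temporal electrode T7
# exceeds 3x the beta power at Fz. Calibration maps each child's raw TBR
# range onto a normalized feedback value nfb in [0, 1].

#' Real-time engine configuration
#'
#' Defaults mirror the closed-loop protocol: a 3 s sliding Hanning window
#' updated every 1 s, theta 4-7.5 Hz and beta 13-19 Hz, feedback computed at
#' `Fz`, muscle gating from `T7` with factor 3.
#'
#' @param window_s analysis window length in seconds.
#' @param hop_s window update interval in seconds (`window_s >= hop_s > 0`).
#' @param theta_band,beta_band numeric length-2 band edges in Hz (inclusive).
#' @param feedback_channel channel whose band powers define the TBR.
#' @param gate_channel temporal channel watched for jaw-muscle bursts.
#' @param gate_factor gate fires when
#'   `beta(gate_channel) > gate_factor * beta(feedback_channel)` (strict).
#' @return list of class `engine_config`.
#' @export
engine_config <- function(window_s = 3.0, hop_s = 1.0,
                          theta_band = c(4, 7.5), beta_band = c(13, 19),
                          feedback_channel = "Fz", gate_channel = "T7",
                          gate_factor = 3.0) {
  if (!(window_s >= hop_s && hop_s > 0)) {
    stop_nfb("need window_s >= hop_s > 0")
  }
  if (gate_factor <= 0) stop_nfb("gate_factor must be > 0")
  stopifnot(length(theta_band) == 2L, length(beta_band) == 2L,
            theta_band[1] < theta_band[2], beta_band[1] < beta_band[2])
  if (theta_band[2] >= beta_band[1]) {
    stop_nfb("theta and beta bands must not overlap")
  }
  structure(list(window_s = window_s, hop_s = hop_s,
                 theta_band = theta_band, beta_band = beta_band,
                 feedback_channel = feedback_channel,
                 gate_channel = gate_channel, gate_factor = gate_factor),
            class = "engine_config")
}

#' Average-reference a window of multichannel EEG
#'
#' Subtracts, at every sample, the mean across the role-`eeg` channels from
#' each role-`eeg` channel. ECG channels pass through untouched.
#'
#' @param window numeric matrix, channels x samples.
#' @param roles character vector of per-channel roles (`"eeg"` / `"ecg"`).
#' @return matrix of the same shape.
#' @export
average_reference <- function(window, roles = rep("eeg", nrow(window))) {
  eeg <- roles == "eeg"
  if (sum(eeg) < 2L) stop_nfb("average reference needs >= 2 eeg channels")
  out <- window
  out[eeg, ] <- sweep(window[eeg, , drop = FALSE], 2L,
                      colMeans(window[eeg, , drop = FALSE]))
  out
}

#' Band power of one tapered window
#'
#' Power is the sum of one-sided periodogram bins whose frequencies fall
#' inside `[band[1], band[2]]` (edges inclusive), after applying a Hanning
#' taper. Normalisation is such that a pure in-band sinusoid of amplitude A
#' contributes `1.5 * A^2/2` (its variance times the Hanning equivalent
#' noise bandwidth); band ratios such as the TBR carry no common factor.
#'
#' @param x numeric vector, one channel's window.
#' @param sfreq sampling rate (Hz).
#' @param band numeric length-2, Hz; must lie below Nyquist.
#' @param taper `"hanning"` (default) or `"none"`.
#' @return non-negative scalar power in microvolts squared.
#' @export
band_power <- function(x, sfreq, band, taper = c("hanning", "none")) {
  taper <- match.arg(taper)
  n <- length(x)
  if (band[2] > sfreq / 2) stop_nfb("band [%g, %g] exceeds Nyquist %g Hz",
                                    band[1], band[2], sfreq / 2)
  w <- if (taper == "hanning") hanning_window(n) else rep(1, n)
  X <- stats::fft(x * w)
  freqs <- (0:(n - 1L)) * sfreq / n
  half <- 2:(floor(n / 2) + 1L)          # positive frequencies, skip DC
  p <- 2 * Mod(X[half])^2 / sum(w)^2
  keep <- freqs[half] >= band[1] & freqs[half] <= band[2]
  sum(p[keep])
}

#' Jaw-muscle gate
#'
#' @param beta_t7 beta power at the gate channel (microvolts squared).
#' @param beta_fz beta power at the feedback channel.
#' @param gate_factor threshold multiplier (default 3).
#' @return `TRUE` iff `beta_t7 > gate_factor * beta_fz` (strict inequality).
#' @export
gate_muscle <- function(beta_t7, beta_fz, gate_factor = 3.0) {
  stopifnot(beta_t7 >= 0, beta_fz >= 0)
  beta_t7 > gate_factor * beta_fz
}

# Compute one TBRSample from a raw (un-referenced) window matrix.
tbr_from_window <- function(win, roles, ch_names, config, t_end, bounds) {
  ref <- average_reference(win, roles)
  i_fb <- match(config$feedback_channel, ch_names)
  i_gt <- match(config$gate_channel, ch_names)
  sf <- attr(win, "sfreq")
  theta <- band_power(ref[i_fb, ], sf, config$theta_band)
  beta  <- band_power(ref[i_fb, ], sf, config$beta_band)
  beta_t7 <- band_power(ref[i_gt, ], sf, config$beta_band)
  gated <- gate_muscle(beta_t7, beta, config$gate_factor)
  tbr <- if (beta > 0) theta / beta else NA_real_
  nfb <- NA_real_
  if (!is.null(bounds)) {
    nfb <- if (gated) 0 else normalize_tbr(tbr, bounds)
  }
  data.frame(t = t_end, theta_power = theta, beta_power = beta,
             tbr_raw = tbr, gated = gated, nfb = nfb)
}

#' Stream TBR samples from a recording
#'
#' Emits one `TBRSample` per hop: the first at `t = window_s`, then every
#' `hop_s`, each computed from exactly the last `window_s` seconds
#' (re-referenced, tapered, gated). If calibration `bounds` are supplied the
#' normalized feedback value `nfb` is populated (0 when gated).
#'
#' @param rec an [eeg_recording()] longer than one window, containing the
#'   feedback and gate channels.
#' @param config an [engine_config()].
#' @param bounds optional [calibration_bounds()].
#' @return data.frame with columns `t`, `theta_power`, `beta_power`,
#'   `tbr_raw`, `gated`, `nfb`.
#' @export
stream_tbr <- function(rec, config = engine_config(), bounds = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  for (ch in c(config$feedback_channel, config$gate_channel)) {
    if (!ch %in% rec$ch_names) stop_nfb("channel '%s' not in recording", ch)
  }
  if (rec$sfreq / 2 <= config$beta_band[2]) {
    stop_nfb("sampling rate %g Hz too low for beta band", rec$sfreq)
  }
  nwin <- round(config$window_s * rec$sfreq)
  hop <- round(config$hop_s * rec$sfreq)
  ns <- ncol(rec$data)
  if (ns < nwin) stop_nfb("recording shorter than one window")
  ends <- seq(nwin, ns, by = hop)
  out <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    e <- ends[i]
    win <- rec$data[, (e - nwin + 1L):e, drop = FALSE]
    attr(win, "sfreq") <- rec$sfreq
    out[[i]] <- tbr_from_window(win, rec$ch_roles, rec$ch_names, config,
                                t_end = e / rec$sfreq, bounds = bounds)
  }
  res <- do.call(rbind, out)
  class(res) <- c("tbr_samples", class(res))
  res
}

#' Incremental TBR streamer
#'
#' Returns a stateful streamer whose `$feed(mat)` accepts any number of new
#' samples (channels x samples) and returns the TBR samples that became
#' complete, guaranteeing byte-identical output to a whole-recording
#' [stream_tbr()] call regardless of chunking.
#'
#' @param config an [engine_config()].
#' @param sfreq sampling rate of the incoming stream (Hz).
#' @param ch_names,ch_roles channel labels and roles of the stream.
#' @param bounds optional [calibration_bounds()].
#' @return list with functions `feed(mat)` and `collect()`.
#' @export
tbr_streamer <- function(config, sfreq, ch_names, ch_roles = NULL,
                         bounds = NULL) {
  ch_roles <- ch_roles %||% ifelse(toupper(ch_names) == "ECG", "ecg", "eeg")
  nwin <- round(config$window_s * sfreq)
  hop <- round(config$hop_s * sfreq)
  buf <- matrix(numeric(0), nrow = length(ch_names), ncol = 0)
  n_seen <- 0L          # total samples consumed
  next_end <- nwin      # absolute index of the next window end
  emitted <- list()
  feed <- function(mat) {
    mat <- as.matrix(mat)
    if (nrow(mat) != length(ch_names)) {
      # allow feeding a single sample as a plain vector
      if (is.null(dim(mat)) || ncol(mat) == length(ch_names)) mat <- t(mat)
    }
    buf <<- cbind(buf, mat)
    n_seen <<- n_seen + ncol(mat)
    new <- list()
    while (next_end <= n_seen) {
      # buffer holds samples (n_seen - ncol(buf) + 1) .. n_seen
      off <- n_seen - ncol(buf)
      i1 <- next_end - nwin + 1L - off
      i2 <- next_end - off
      win <- buf[, i1:i2, drop = FALSE]
      attr(win, "sfreq") <- sfreq
      new[[length(new) + 1L]] <-
        tbr_from_window(win, ch_roles, ch_names, config,
                        t_end = next_end / sfreq, bounds = bounds)
      next_end <<- next_end + hop
    }
    # drop samples that can never be needed again
    keep_from <- next_end - nwin + 1L
    off <- n_seen - ncol(buf)
    drop_n <- max(0L, keep_from - 1L - off)
    if (drop_n > 0L) buf <<- buf[, -(1:drop_n), drop = FALSE]
    if (length(new)) {
      res <- do.call(rbind, new)
      emitted[[length(emitted) + 1L]] <<- res
      res
    } else NULL
  }
  collect <- function() {
    if (!length(emitted)) return(NULL)
    res <- do.call(rbind, emitted)
    rownames(res) <- NULL
    class(res) <- c("tbr_samples", class(res))
    res
  }
  list(feed = feed, collect = collect)
}

#' Calibration bounds
#'
#' @param tbr_min,tbr_max per-child raw TBR normalization bounds
#'   (`0 < tbr_min <= tbr_max`).
#' @param n_samples_used ungated samples entering the computation.
#' @param n_rejected gated samples removed beforehand.
#' @return list of class `calibration_bounds`.
#' @export
calibration_bounds <- function(tbr_min, tbr_max, n_samples_used = NA_integer_,
                               n_rejected = NA_integer_) {
  if (!(tbr_min <= tbr_max)) stop_nfb("tbr_min must be <= tbr_max")
  if (tbr_min <= 0 || tbr_max <= 0) stop_nfb("bounds must be positive")
  structure(list(tbr_min = tbr_min, tbr_max = tbr_max,
                 n_samples_used = n_samples_used, n_rejected = n_rejected),
            class = "calibration_bounds")
}

#' Calibrate normalization bounds from the four-phase routine
#'
#' The calibration phase interleaves two relaxing and two focusing periods of
#' 20 s each; the raw TBR samples collected during all four are pooled.
#' Gated (muscle-artifact) samples are removed, the remainder sorted
#' ascending; the minimum bound is the smallest value and the maximum bound
#' the mean of the last quarter (top `ceiling(n/4)` values) of the sorted
#' array.
#'
#' @param samples a data.frame from [stream_tbr()] (columns `tbr_raw`,
#'   `gated`) or a numeric vector of raw TBRs (then `gated` may be given
#'   separately).
#' @param gated optional logical vector when `samples` is numeric.
#' @return a [calibration_bounds()].
#' @export
calibrate <- function(samples, gated = NULL) {
  if (is.data.frame(samples)) {
    tbr <- samples$tbr_raw
    gated <- samples$gated
  } else {
    tbr <- as.numeric(samples)
    gated <- gated %||% rep(FALSE, length(tbr))
  }
  keep <- !gated & is.finite(tbr)
  n_rej <- sum(!keep)
  vals <- sort(tbr[keep])
  n <- length(vals)
  if (n < 4L) {
    stop_nfb("calibration failed: only %d ungated samples (need >= 4)", n)
  }
  q <- ceiling(n / 4)
  calibration_bounds(tbr_min = vals[1L],
                     tbr_max = mean(vals[(n - q + 1L):n]),
                     n_samples_used = n, n_rejected = n_rej)
}

#' Normalize a raw TBR into the feedback range
#'
#' `nfb = clip((tbr_max - tbr_raw) / (tbr_max - tbr_min), 0, 1)`: a low raw
#' TBR (focused) maps to 1, a high raw TBR (inattentive) to 0. Degenerate
#' bounds (`tbr_max == tbr_min`) yield 0.5 with a warning.
#'
#' @param tbr_raw raw theta/beta ratio(s).
#' @param bounds a [calibration_bounds()].
#' @return nfb value(s) in `[0, 1]`.
#' @export
normalize_tbr <- function(tbr_raw, bounds) {
  stopifnot(inherits(bounds, "calibration_bounds"))
  rng <- bounds$tbr_max - bounds$tbr_min
  if (rng <= 0) {
    warning("degenerate calibration bounds (max == min); returning 0.5")
    return(rep(0.5, length(tbr_raw)))
  }
  clip((bounds$tbr_max - tbr_raw) / rng, 0, 1)
}

#' Serialize / load calibration bounds as JSON
#' @param bounds a [calibration_bounds()]; `path` a file path.
#' @param path JSON file path.
#' @return `read_bounds` returns a [calibration_bounds()].
#' @export
write_bounds <- function(bounds, path) {
  jsonlite::write_json(unclass(bounds), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bounds
#' @export
read_bounds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_bounds(x$tbr_min, x$tbr_max, x$n_samples_used, x$n_rejected)
}
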