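# Minimal FIR filtering toolbox (windowed-sinc design, zero-delay linear-phase
# application, polyphase-free integer decimation). No DSP package with FIR
# design ships with this R distribution, so the few primitives the pipelines
# need are implemented here and validated by spectral oracle tests.

hanning_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

# Number of taps for a Hamming-window design with the given transition width.
fir_n_taps <- function(trans_bw_hz, sfreq) {
  n <- ceiling(3.3 / (trans_bw_hz / sfreq))
  n <- as.integer(n)
  if (n %% 2L == 0L) n <- n + 1L
  max(n, 5L)
}

# Windowed-sinc lowpass kernel; fc is the half-amplitude (-6 dB) frequency.
fir_lowpass <- function(fc_hz, sfreq, trans_bw_hz) {
  n <- fir_n_taps(trans_bw_hz, sfreq)
  m <- (n - 1L) / 2
  k <- (0:(n - 1L)) - m
  fc <- fc_hz / sfreq
  h <- ifelse(k == 0, 2 * fc, sin(2 * pi * fc * k) / (pi * k))
  h <- h * hamming_window(n)
  h / sum(h)
}

# Spectral inversion of a lowpass -> highpass with the same -6 dB point.
fir_highpass <- function(fc_hz, sfreq, trans_bw_hz) {
  h <- fir_lowpass(fc_hz, sfreq, trans_bw_hz)
  h <- -h
  m <- (length(h) - 1L) / 2 + 1L
  h[m] <- h[m] + 1
  h
}

fir_bandpass <- function(lo_hz, hi_hz, sfreq, trans_bw_hz) {
  hl <- fir_lowpass(hi_hz, sfreq, trans_bw_hz)
  hh <- fir_highpass(lo_hz, sfreq, trans_bw_hz)
  n <- max(length(hl), length(hh))
  pad <- function(h) {
    d <- (n - length(h)) / 2
    if (d > 0) c(rep(0, d), h, rep(0, d)) else h
  }
  hl <- pad(hl); hh <- pad(hh)
  # cascade (convolve) so both edges hold; resulting length 2n-1 (odd)
  stats::convolve(hl, rev(hh), type = "open")
}

# Band-stop built as lowpass + highpass (parallel sum of linear-phase kernels).
fir_bandstop <- function(lo_hz, hi_hz, sfreq, trans_bw_hz) {
  hl <- fir_lowpass(lo_hz, sfreq, trans_bw_hz)
  hh <- fir_highpass(hi_hz, sfreq, trans_bw_hz)
  n <- max(length(hl), length(hh))
  pad <- function(h) {
    d <- (n - length(h)) / 2
    if (d > 0) c(rep(0, d), h, rep(0, d)) else h
  }
  pad(hl) + pad(hh)
}

# Apply an odd-length linear-phase FIR kernel with zero net delay.
# Edges are reflection-padded by the kernel half-length.
fir_apply <- function(x, h) {
  n <- length(x)
  m <- length(h)
  stopifnot(m %% 2L == 1L)
  d <- (m - 1L) / 2L
  if (n == 0L) return(x)
  pad_l <- if (n > 1) x[pmin(n, (d + 1L):2L)] else rep(x[1L], d)
  pad_r <- if (n > 1) x[pmax(1L, (n - 1L):(n - d))] else rep(x[n], d)
  xp <- c(pad_l, x, pad_r)
  y <- stats::convolve(xp, rev(h), type = "open")
  y[(2L * d + 1L):(2L * d + n)]
}

# Row-wise FIR over a channels x samples matrix.
fir_apply_mat <- function(mat, h) {
  t(apply(mat, 1L, fir_apply, h = h))
}

# Integer-factor decimation with anti-alias lowpass.
decimate <- function(x, factor, sfreq, cutoff_hz = NULL, trans_bw_hz = NULL) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(x)
  nyq_new <- sfreq / factor / 2
  cutoff_hz <- cutoff_hz %||% (0.8 * nyq_new)
  trans_bw_hz <- trans_bw_hz %||% (0.2 * nyq_new)
  h <- fir_lowpass(cutoff_hz, sfreq, trans_bw_hz)
  y <- fir_apply(x, h)
  y[seq(1L, length(y), by = factor)]
}

# Cubic-spline upsampling by an integer factor (used for MR contamination,
# where the clean signal is band-limited far below the original Nyquist).
upsample_spline <- function(x, factor) {
  n <- length(x)
  t_old <- seq_len(n)
  t_new <- seq(1, n, by = 1 / factor)
  out <- stats::spline(t_old, x, xout = t_new, method = "natural")$y
  # extend to exactly n * factor samples by holding the last value
  need <- n * factor - length(out)
  if (need > 0) out <- c(out, rep(out[length(out)], need))
  out
}

# 1/f ("pink") noise via FFT amplitude shaping; unit RMS.
pink_noise <- function(n) {
  if (n < 2L) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)          # symmetric frequency index
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Gaussian white noise band-limited to [lo, hi] Hz via FFT masking; unit
# RMS. `edge_hz > 0` replaces the brick wall with raised-cosine skirts (real
# physiological spectra roll off, they do not vanish).
narrowband_noise <- function(n, sfreq, lo, hi, edge_hz = 0) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- (0:(n - 1L)) * sfreq / n
  f <- pmin(f, sfreq - f)
  if (edge_hz > 0) {
    mask <- rep(1, n)
    below <- f < lo
    mask[below] <- 0.5 * (1 + cos(pi * pmin(1, (lo - f[below]) / edge_hz)))
    above <- f > hi
    mask[above] <- 0.5 * (1 + cos(pi * pmin(1, (f[above] - hi) / edge_hz)))
    X <- X * mask
  } else {
    X[f < lo | f > hi] <- 0
  }
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) rep(0, n) else x / s
}
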