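# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures ship with the package.

# Small montage used throughout the tests (fast, includes the feedback and
# gate channels plus ECG).
small_montage <- function() c("Fz", "Cz", "Pz", "T7", "Oz", "ECG")

# A short synthetic recording with default parameters.
make_recording <- function(duration_s = 12, seed = 7, target = 0.5,
                           volatility = 0.1, sfreq = 500,
                           ch_names = small_montage(), ...) {
  tr <- simulate_attention_trace(duration_s, 1,
                                 attention_params(target = target,
                                                  volatility = volatility),
                                 seed = seed)
  synthesize_eeg(tr, ch_names = ch_names, sfreq = sfreq, seed = seed,
                 duration_s = duration_s, ...)
}

# Independent brute-force DFT band power: explicit correlation sums per
# frequency bin (no fft call), same taper and normalization contract as
# band_power().
oracle_band_power <- function(x, sfreq, band) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xw <- x * w
  ks <- 1:floor(n / 2)
  freqs <- ks * sfreq / n
  keep <- ks[freqs >= band[1] & freqs <= band[2]]
  tot <- 0
  tvec <- 0:(n - 1)
  for (k in keep) {
    re <- sum(xw * cos(2 * pi * k * tvec / n))
    im <- -sum(xw * sin(2 * pi * k * tvec / n))
    tot <- tot + 2 * (re^2 + im^2) / sum(w)^2
  }
  tot
}

# Brute-force go/no-go scorer: literal translation of the rules, structured
# differently from the implementation (per-trial loop with explicit cells).
oracle_score_gonogo <- function(trials, responses, rt_limit = 1000) {
  hits <- omissions <- commissions <- crs <- 0L
  for (i in seq_len(nrow(trials))) {
    pressed <- isTRUE(responses$responded[i])
    rt <- responses$rt_ms[i]
    if (trials$is_nogo[i]) {
      if (pressed) commissions <- commissions + 1L else crs <- crs + 1L
    } else {
      ok <- pressed && !is.na(rt) && rt <= rt_limit
      if (ok) hits <- hits + 1L else omissions <- omissions + 1L
    }
  }
  list(hits = hits, omissions = omissions, commissions = commissions,
       correct_rejections = crs,
       accuracy = (hits + crs) / nrow(trials))
}

# Hand-rolled calibration oracle (sorting done differently: order()).
oracle_calibrate <- function(tbr, gated) {
  v <- tbr[!gated & is.finite(tbr)]
  v <- v[order(v)]
  n <- length(v)
  q <- ceiling(n / 4)
  list(tbr_min = v[1], tbr_max = sum(v[seq(n - q + 1, n)]) / q)
}

# Orthonormal average-referenced planted maps for microstate tests.
planted_maps <- function(n_ch, k, seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(n_ch * (k + 1)), n_ch)
  M <- sweep(M, 2, colMeans(M))           # average reference
  Q <- qr.Q(qr(M))[, 1:k, drop = FALSE]
  Q <- sweep(Q, 2, colMeans(Q))
  sweep(Q, 2, sqrt(colSums(Q^2)), "/")
}

# Synthetic microstate recording: random state sequence with dwell times,
# amplitude-modulated maps with random sign flips plus sensor noise.
planted_microstate_rec <- function(maps, n_samples = 2000, sfreq = 250,
                                   noise = 0.1, seed = 1, dwell = 20) {
  set.seed(seed)
  n_ch <- nrow(maps); k <- ncol(maps)
  lab <- integer(0)
  while (length(lab) < n_samples) {
    lab <- c(lab, rep(sample.int(k, 1), dwell + sample.int(dwell, 1)))
  }
  lab <- lab[1:n_samples]
  amp <- 5 + 3 * abs(sin(2 * pi * 11 * (1:n_samples) / sfreq))
  sgn <- sample(c(-1, 1), n_samples, replace = TRUE)
  X <- maps[, lab] * rep(amp * sgn, each = n_ch) +
    noise * 5 * matrix(rnorm(n_ch * n_samples), n_ch)
  X <- sweep(X, 2, colMeans(X))
  list(data = X, labels = lab)
}

expect_rel_equal <- function(x, y, tol) {
  expect_true(all(abs(x - y) <= tol * pmax(abs(y), 1e-12)),
              label = sprintf("max rel err %.3g <= %.3g",
                              max(abs(x - y) / pmax(abs(y), 1e-12)), tol))
}
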