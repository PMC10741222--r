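# EEG microstate analysis: topographies at global-field-power (GFP) peaks
# are clustered with a polarity-invariant modified k-means (k = 5, best of
# 100 restarts by global explained variance), recording-level maps are
# merged and re-clustered to a group level, and the winning maps are fitted
# back sample-by-sample by absolute spatial correlation with 50 ms
# neighborhood smoothing.

# GFP(t): standard deviation across scalp channels at each sample.
gfp_of <- function(mat) apply(mat, 2L, stats::sd)

# Average-reference a channels x samples matrix (plain, no roles).
center_cols <- function(mat) sweep(mat, 2L, colMeans(mat))

#' Extract topographies at GFP peaks
#'
#' GFP is the spatial standard deviation across role-`eeg` channels; its
#' strict local maxima mark the moments of highest topographic
#' signal-to-noise, and the (average-referenced) scalp maps at those
#' samples are returned.
#'
#' @param rec an [eeg_recording()] or a channels-x-samples matrix.
#' @return list: `topographies` (channels x n_peaks, average-referenced),
#'   `peak_idx` (sample indices), `gfp` (full GFP trace).
#' @export
gfp_peaks <- function(rec) {
  mat <- if (inherits(rec, "eeg_recording")) {
    rec$data[rec$ch_roles == "eeg", , drop = FALSE]
  } else as.matrix(rec)
  mat <- center_cols(mat)
  g <- gfp_of(mat)
  n <- length(g)
  if (n < 3L || max(g) - min(g) < 1e-12) {
    stop_nfb("constant signal: no GFP peaks")
  }
  # plateau-aware strict local maxima: collapse runs of equal GFP (exact
  # ties arise in noise-free synthetic signals) and require both
  # neighbouring runs to be lower; the run's first sample is reported
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  pk <- integer(0)
  if (nr >= 3L) {
    j <- 2:(nr - 1L)
    is_pk <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
    pk <- starts[j][is_pk]
  }
  if (!length(pk)) stop_nfb("no strict GFP local maxima found")
  list(topographies = mat[, pk, drop = FALSE], peak_idx = pk, gfp = g)
}

# Spatial correlation of each column of X (ch x n) with each map (ch x k):
# Pearson across channels; for average-referenced data this is the cosine
# of the centred vectors.
spatial_corr <- function(X, maps) {
  Xc <- center_cols(X)
  Mc <- center_cols(maps)
  Xn <- sweep(Xc, 2L, sqrt(colSums(Xc^2)), "/")
  Mn <- sweep(Mc, 2L, sqrt(colSums(Mc^2)), "/")
  crossprod(Mn, Xn)                      # k x n
}

# GEV of a labelled assignment: GFP^2-weighted squared spatial correlation.
gev_of <- function(X, maps, labels) {
  g2 <- colSums(center_cols(X)^2)
  r <- spatial_corr(X, maps)
  idx <- cbind(labels, seq_len(ncol(X)))
  ok <- !is.na(labels)
  sum(g2[ok] * r[idx[ok, , drop = FALSE]]^2) / sum(g2)
}

#' Modified k-means microstate clustering (polarity-invariant)
#'
#' Topographies are assigned to the map with maximal squared spatial
#' correlation (sign-free); each map is updated as the dominant eigenvector
#' of the outer-product sum of its assigned topographies. The best of
#' `n_reps` random restarts by global explained variance (GEV) wins.
#'
#' @param topos channels x n matrix of topographies (e.g. from
#'   [gfp_peaks()]); `n >= k`.
#' @param k number of maps (5 in the protocol).
#' @param n_reps random restarts (100).
#' @param seed RNG seed; results are deterministic given it.
#' @param tol convergence tolerance on the relative GEV change.
#' @param max_iter iteration cap per restart.
#' @return list of class `microstate_maps`: `maps` (channels x k, unit
#'   norm, average-referenced), `gev`, `labels` (per input topography),
#'   `source = "recording"`, `k`, `ch_names` when available.
#' @export
modified_kmeans <- function(topos, k = 5L, n_reps = 100L, seed = 1,
                            tol = 1e-8, max_iter = 300L) {
  X <- center_cols(as.matrix(topos))
  n <- ncol(X)
  if (n < k) stop_nfb("need at least k=%d topographies, got %d", k, n)
  norms <- sqrt(colSums(X^2))
  if (any(norms < 1e-12)) {
    keep <- norms >= 1e-12
    X <- X[, keep, drop = FALSE]
    n <- ncol(X)
    if (n < k) stop_nfb("too few non-degenerate topographies")
  }
  one_run <- function() {
    maps <- X[, sample.int(n, k), drop = FALSE]
    maps <- sweep(maps, 2L, sqrt(colSums(maps^2)), "/")
    gev_prev <- -Inf
    labels <- rep(1L, n)
    for (it in seq_len(max_iter)) {
      r <- spatial_corr(X, maps)               # k x n
      labels <- max.col(t(r^2), ties.method = "first")
      for (j in seq_len(k)) {
        idx <- which(labels == j)
        if (!length(idx)) {
          # re-seed an empty cluster with the worst-fitted topography
          fit <- r[cbind(labels, seq_len(n))]^2
          idx <- which.min(fit)
          labels[idx] <- j
        }
        Xj <- X[, idx, drop = FALSE]
        S <- tcrossprod(Xj)
        ev <- eigen(S, symmetric = TRUE)
        maps[, j] <- ev$vectors[, 1L]
      }
      gev <- gev_of(X, maps, labels)
      if (is.finite(gev_prev) && abs(gev - gev_prev) <= tol * max(gev, 1e-12)) break
      gev_prev <- gev
    }
    list(maps = maps, labels = labels, gev = gev_of(X, maps, labels))
  }
  best <- with_seed(seed, {
    best <- NULL
    for (rep in seq_len(n_reps)) {
      run <- one_run()
      if (is.null(best) || run$gev > best$gev) best <- run
    }
    best
  })
  maps <- sweep(best$maps, 2L, sqrt(colSums(best$maps^2)), "/")
  structure(list(maps = maps, gev = best$gev, labels = best$labels,
                 k = as.integer(k), source = "recording",
                 ch_names = rownames(as.matrix(topos))),
            class = "microstate_maps")
}

#' Two-level (recording -> group) microstate clustering
#'
#' Pools all recording-level maps as input topographies and reruns the same
#' modified k-means to extract the `k` topographies that best represent the
#' dataset.
#'
#' @param recording_maps list of `microstate_maps` (one per recording).
#' @param k,n_reps,seed passed to [modified_kmeans()].
#' @return a `microstate_maps` with `source = "group"`.
#' @export
two_level_cluster <- function(recording_maps, k = 5L, n_reps = 100L,
                              seed = 1) {
  if (!length(recording_maps)) stop_nfb("no recording-level maps")
  pooled <- do.call(cbind, lapply(recording_maps, `[[`, "maps"))
  out <- modified_kmeans(pooled, k = k, n_reps = n_reps, seed = seed)
  out$source <- "group"
  out
}

# Neighborhood-reward smoothing: the |correlation| evidence of the label
# dominating the surrounding window is multiplied by `factor` before the
# argmax. The paper-level parameters are only the window (50 ms) and the
# factor (10); the scheme itself is isolated here so alternatives can be
# swapped.
smooth_labels <- function(absr, labels, half_win, factor) {
  n <- ncol(absr)
  out <- labels
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_win); hi <- min(n, i + half_win)
    nb <- labels[lo:hi][-(i - lo + 1L)]
    if (!length(nb)) next
    tab <- tabulate(nb, nbins = nrow(absr))
    dom <- which.max(tab)
    ev <- absr[, i]
    ev[dom] <- ev[dom] * factor
    out[i] <- which.max(ev)
  }
  out
}

#' Back-fit microstate maps to a recording
#'
#' Each sample is assigned to the map with the highest absolute spatial
#' correlation; temporal smoothing over a 50 ms window multiplies the
#' evidence of the locally dominant label by the smoothing factor before
#' the argmax, enforcing temporal continuity. Polarity never matters.
#'
#' @param rec an [eeg_recording()] (or matrix) sharing the maps' channel
#'   space.
#' @param maps a `microstate_maps` from [modified_kmeans()] /
#'   [two_level_cluster()].
#' @param smoothing_window_s smoothing window (s), 0.05; 0 disables.
#' @param smoothing_factor evidence multiplier for the dominant neighbor
#'   label (10).
#' @return list of class `microstate_segmentation`: `labels` (per sample),
#'   `gev` (total), `gev_per_map`, `coverage` (fraction of samples per
#'   map), `mean_duration_s` (mean segment duration), `n_segments`,
#'   `correlation` (per-sample winning |correlation|).
#' @export
backfit <- function(rec, maps, smoothing_window_s = 0.05,
                    smoothing_factor = 10) {
  if (inherits(rec, "eeg_recording")) {
    mat <- rec$data[rec$ch_roles == "eeg", , drop = FALSE]
    sfreq <- rec$sfreq
  } else {
    mat <- as.matrix(rec)
    sfreq <- attr(rec, "sfreq") %||% 1
  }
  if (nrow(mat) != nrow(maps$maps)) {
    stop_nfb("channel mismatch: data has %d channels, maps %d",
             nrow(mat), nrow(maps$maps))
  }
  X <- center_cols(mat)
  r <- spatial_corr(X, maps$maps)
  absr <- abs(r)
  labels <- max.col(t(absr), ties.method = "first")
  if (smoothing_window_s > 0 && smoothing_factor != 1) {
    half <- max(1L, round(smoothing_window_s * sfreq / 2))
    labels <- smooth_labels(absr, labels, half, smoothing_factor)
  }
  n <- length(labels)
  g2 <- colSums(X^2)
  gev_num <- g2 * absr[cbind(labels, seq_len(n))]^2
  gev_tot <- sum(gev_num) / sum(g2)
  gev_map <- vapply(seq_len(maps$k), function(j) {
    sum(gev_num[labels == j]) / sum(g2)
  }, 0)
  runs <- rle(labels)
  structure(list(labels = labels,
                 gev = gev_tot, gev_per_map = gev_map,
                 coverage = tabulate(labels, maps$k) / n,
                 mean_duration_s = mean(runs$lengths) / sfreq,
                 n_segments = length(runs$lengths),
                 correlation = absr[cbind(labels, seq_len(n))]),
            class = "microstate_segmentation")
}

#' Match two map sets by absolute spatial correlation
#'
#' Evaluation helper (not part of the method): finds the permutation of
#' `maps_b` maximizing the mean |spatial correlation| with `maps_a`.
#' Exhaustive over permutations (exact) for `k <= 7`.
#'
#' @param maps_a,maps_b channels x k matrices (or `microstate_maps`).
#' @return list: `perm` (column of `maps_b` matched to each column of
#'   `maps_a`), `corrs` (|correlation| per matched pair), `mean_corr`.
#' @export
match_maps <- function(maps_a, maps_b) {
  A <- if (inherits(maps_a, "microstate_maps")) maps_a$maps else as.matrix(maps_a)
  B <- if (inherits(maps_b, "microstate_maps")) maps_b$maps else as.matrix(maps_b)
  k <- ncol(A)
  stopifnot(ncol(B) == k, k <= 7)
  R <- abs(spatial_corr(B, A))           # k(A-rows) x k(B-cols)
  perms <- permutations_of(k)
  best <- NULL; best_val <- -Inf
  for (p in perms) {
    v <- sum(R[cbind(seq_len(k), p)])
    if (v > best_val) { best_val <- v; best <- p }
  }
  corrs <- R[cbind(seq_len(k), best)]
  list(perm = best, corrs = corrs, mean_corr = mean(corrs))
}

permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in permutations_of(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}
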