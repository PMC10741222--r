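# Idealized 10-20 / 10-10 electrode positions on the unit sphere, built
# from the standard construction: the vertex Cz, the midline arc (36 deg
# steps) and the 10% outer ring (72 deg inclination, 18 deg azimuth steps);
# intermediate 10-10 electrodes are normalized spherical midpoints of their
# grid neighbours. Adequate for spherical-spline interpolation; not a
# digitized montage.

sph_point <- function(incl_deg, az_deg) {
  # inclination from the vertex; azimuth 0 = front (+y), positive to the
  # right (+x), z up
  i <- incl_deg * pi / 180
  a <- az_deg * pi / 180
  c(x = sin(i) * sin(a), y = sin(i) * cos(a), z = cos(i))
}

norm3 <- function(v) v / sqrt(sum(v^2))
mid3 <- function(a, b) norm3((a + b) / 2)

# Push a unit vector 'deg' further from the vertex along its meridian.
push_down <- function(v, deg = 18) {
  incl <- acos(v["z"]) + deg * pi / 180
  az <- atan2(v["x"], v["y"])
  c(x = sin(incl) * sin(az), y = sin(incl) * cos(az), z = cos(incl))
}

build_montage_positions <- function() {
  P <- list(
    Cz = sph_point(0, 0),
    Fpz = sph_point(72, 0), Oz = sph_point(72, 180),
    Fz = sph_point(36, 0), Pz = sph_point(36, 180),
    C3 = sph_point(36, -90), C4 = sph_point(36, 90),
    Fp1 = sph_point(72, -18), Fp2 = sph_point(72, 18),
    F7 = sph_point(72, -54), F8 = sph_point(72, 54),
    T7 = sph_point(72, -90), T8 = sph_point(72, 90),
    P7 = sph_point(72, -126), P8 = sph_point(72, 126),
    O1 = sph_point(72, -162), O2 = sph_point(72, 162))
  P$F3 <- mid3(P$Fz, P$F7); P$F4 <- mid3(P$Fz, P$F8)
  P$P3 <- mid3(P$Pz, P$P7); P$P4 <- mid3(P$Pz, P$P8)
  P$FCz <- mid3(P$Fz, P$Cz); P$CPz <- mid3(P$Cz, P$Pz)
  P$FC3 <- mid3(P$F3, P$C3); P$FC4 <- mid3(P$F4, P$C4)
  P$CP3 <- mid3(P$C3, P$P3); P$CP4 <- mid3(P$C4, P$P4)
  P$FT7 <- mid3(P$F7, P$T7); P$FT8 <- mid3(P$F8, P$T8)
  P$TP7 <- mid3(P$T7, P$P7); P$TP8 <- mid3(P$T8, P$P8)
  P$FC1 <- mid3(P$FCz, P$FC3); P$FC2 <- mid3(P$FCz, P$FC4)
  P$FC5 <- mid3(P$FC3, P$FT7); P$FC6 <- mid3(P$FC4, P$FT8)
  P$CP1 <- mid3(P$CPz, P$CP3); P$CP2 <- mid3(P$CPz, P$CP4)
  P$CP5 <- mid3(P$CP3, P$TP7); P$CP6 <- mid3(P$CP4, P$TP8)
  P$POz <- mid3(P$Pz, P$Oz)
  P$PO7 <- mid3(P$P7, P$O1); P$PO8 <- mid3(P$P8, P$O2)
  P$PO3 <- mid3(P$POz, P$PO7); P$PO4 <- mid3(P$POz, P$PO8)
  P$TP9 <- push_down(P$TP7); P$TP10 <- push_down(P$TP8)
  P$PO9 <- push_down(P$PO7); P$PO10 <- push_down(P$PO8)
  P
}

.montage_cache <- new.env(parent = emptyenv())

#' Idealized electrode positions for 10-20 / 10-10 labels
#'
#' @param labels channel labels (e.g. `c("Fz", "T7")`).
#' @return 3 x n matrix of unit vectors (columns named by label).
#' @export
standard_positions <- function(labels) {
  if (is.null(.montage_cache$P)) .montage_cache$P <- build_montage_positions()
  P <- .montage_cache$P
  unknown <- setdiff(labels, names(P))
  if (length(unknown)) {
    stop_nfb("no montage position for channel '%s'", unknown[1L])
  }
  m <- vapply(labels, function(l) P[[l]], numeric(3))
  rownames(m) <- c("x", "y", "z")
  m
}

# Legendre polynomials P_1..P_nmax at x (vector) via recurrence.
legendre_upto <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  p0 <- rep(1, length(x)); p1 <- x
  out[, 1L] <- p1
  for (n in 2:nmax) {
    p2 <- ((2 * n - 1) * x * p1 - (n - 1) * p0) / n
    out[, n] <- p2
    p0 <- p1; p1 <- p2
  }
  out
}

# Perrin-style spherical spline kernel g(cosine), stiffness m = 4.
spline_g <- function(cosang, m = 4, nterms = 20) {
  n <- 1:nterms
  L <- legendre_upto(as.numeric(cosang), nterms)
  as.numeric(L %*% ((2 * n + 1) / (n * (n + 1))^m)) / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' Fits a spherical spline (stiffness 4) through the good channels at every
#' sample and evaluates it at the bad channel positions.
#'
#' @param rec an [eeg_recording()].
#' @param bad_channels labels of the channels to rebuild.
#' @param reg ridge regularization added to the spline system.
#' @return the recording with the bad channels replaced.
#' @export
interpolate_channels <- function(rec, bad_channels, reg = 1e-5) {
  stopifnot(inherits(rec, "eeg_recording"))
  bad_channels <- intersect(bad_channels, rec$ch_names)
  if (!length(bad_channels)) return(rec)
  eeg_idx <- which(rec$ch_roles == "eeg")
  bad_idx <- match(bad_channels, rec$ch_names)
  good_idx <- setdiff(eeg_idx, bad_idx)
  if (length(good_idx) < 4L) stop_nfb("too few good channels to interpolate")
  pos_good <- standard_positions(rec$ch_names[good_idx])
  pos_bad <- standard_positions(rec$ch_names[bad_idx])
  ng <- length(good_idx)
  G <- matrix(spline_g(crossprod(pos_good)), ng, ng) + diag(reg, ng)
  A <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  Gi <- matrix(spline_g(crossprod(pos_good, pos_bad)), ng,
               length(bad_idx))
  V <- rbind(rec$data[good_idx, , drop = FALSE], 0)
  coefs <- solve(A, V)                   # (ng+1) x samples
  interp <- t(Gi) %*% coefs[1:ng, , drop = FALSE] +
    matrix(coefs[ng + 1L, ], length(bad_idx), ncol(rec$data), byrow = TRUE)
  rec$data[bad_idx, ] <- interp
  rec
}
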