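# EEG container and file input/output: BrainVision (.vhdr/.vmrk/.eeg), EDF,
# and BIDS-style event tables (TSV). All amplitudes are microvolts and all
# times are seconds from recording start, so resampling never invalidates
# annotations.

#' Construct an EEG recording container
#'
#' The universal signal container of the toolkit: a channels-by-samples
#' matrix of amplitudes in microvolts plus sampling rate, channel labels
#' (10-20 names such as `Fz`, `T7`), per-channel roles (`"eeg"` or `"ecg"`)
#' and annotations in seconds. Channels with role `"ecg"` are excluded from
#' every scalp aggregate computed downstream (average reference, GFP, ...).
#'
#' @param data numeric matrix, `n_channels x n_samples`, in microvolts.
#' @param sfreq sampling rate in Hz (> 0).
#' @param ch_names character vector of channel labels, one per row of `data`.
#' @param ch_roles character vector, `"eeg"` or `"ecg"` per channel. By
#'   default channels whose name matches `ecg_names` (case-insensitively)
#'   get role `"ecg"`.
#' @param annotations data.frame with columns `onset` (s), `duration` (s),
#'   `label`; may be empty.
#' @param meta free-form list of generator ground truth / provenance.
#' @param ecg_names channel names treated as ECG when `ch_roles` is `NULL`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, ch_names,
                          ch_roles = NULL,
                          annotations = empty_annotations(),
                          meta = list(),
                          ecg_names = c("ECG")) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_nfb("data must be numeric")
  if (nrow(data) != length(ch_names)) {
    stop_nfb("data has %d rows but %d channel names given",
             nrow(data), length(ch_names))
  }
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0) {
    stop_nfb("sfreq must be a single positive number")
  }
  if (is.null(ch_roles)) {
    ch_roles <- ifelse(tolower(ch_names) %in% tolower(ecg_names), "ecg", "eeg")
  }
  if (length(ch_roles) != length(ch_names)) {
    stop_nfb("ch_roles length (%d) != ch_names length (%d)",
             length(ch_roles), length(ch_names))
  }
  if (!all(ch_roles %in% c("eeg", "ecg"))) {
    stop_nfb("ch_roles must be 'eeg' or 'ecg'")
  }
  annotations <- as_annotations(annotations)
  dur <- ncol(data) / sfreq
  if (nrow(annotations) &&
      (any(annotations$onset < 0) || any(annotations$onset > dur))) {
    stop_nfb("annotation onsets must lie within [0, %g] s", dur)
  }
  rownames(data) <- ch_names
  structure(list(data = data, sfreq = sfreq,
                 ch_names = as.character(ch_names),
                 ch_roles = as.character(ch_roles),
                 annotations = annotations, meta = meta),
            class = "eeg_recording")
}

empty_annotations <- function() {
  data.frame(onset = numeric(0), duration = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

as_annotations <- function(x) {
  if (is.null(x)) return(empty_annotations())
  x <- as.data.frame(x)
  if (!all(c("onset", "duration", "label") %in% names(x))) {
    stop_nfb("annotations need columns onset, duration, label")
  }
  x$onset <- as.numeric(x$onset)
  x$duration <- as.numeric(x$duration)
  x$label <- as.character(x$label)
  if (any(x$duration < 0)) stop_nfb("annotation durations must be >= 0")
  x[, c("onset", "duration", "label")]
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), %d ecg, %d annotations\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq,
              sum(x$ch_roles == "ecg"), nrow(x$annotations)))
  invisible(x)
}

#' Number of samples / duration helpers
#' @param rec an `eeg_recording`.
#' @return sample count / duration in seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$sfreq

#' Drop ECG channels from a recording
#'
#' @param rec an `eeg_recording`.
#' @return the recording restricted to role-`eeg` channels.
#' @export
drop_ecg <- function(rec) {
  keep <- rec$ch_roles == "eeg"
  eeg_recording(rec$data[keep, , drop = FALSE], rec$sfreq,
                rec$ch_names[keep], rec$ch_roles[keep],
                rec$annotations, rec$meta)
}

#' Read an EEG recording (BrainVision or EDF)
#'
#' BrainVision triplets must be complete (`.vhdr`, `.vmrk`, `.eeg`); a missing
#' member raises an error naming it. Only IEEE float32 multiplexed binary data
#' in microvolts is supported (the format this package writes). EDF files are
#' read as 16-bit integers rescaled by the stored physical range; if a sidecar
#' `<stem>_events.tsv` exists its rows are attached as annotations.
#'
#' @param path path to the `.vhdr` (BrainVision) or `.edf` file.
#' @param format `"brainvision"` or `"edf"`; inferred from the extension when
#'   missing.
#' @param ecg_names channel names treated as ECG (case-insensitive).
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = NULL, ecg_names = c("ECG")) {
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               vhdr = "brainvision", edf = "edf",
                               stop_nfb("cannot infer format from '%s'", path))
  switch(match.arg(format, c("brainvision", "edf")),
         brainvision = read_brainvision(path, ecg_names),
         edf = read_edf(path, ecg_names))
}

#' Write an EEG recording (BrainVision or EDF)
#'
#' BrainVision is written as multiplexed IEEE float32 in microvolts (lossless
#' to float precision); annotations become `.vmrk` markers with onsets
#' quantised to samples. EDF is written as 16-bit integers scaled to each
#' channel's physical range (documented lossy); annotations, which basic EDF
#' cannot carry, go to a sidecar `<stem>_events.tsv`.
#'
#' @param rec an [eeg_recording()]; must contain at least one sample.
#' @param path output path (`.vhdr` or `.edf`).
#' @param format `"brainvision"` or `"edf"`; inferred from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) == 0L) stop_nfb("refusing to write an empty recording")
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               vhdr = "brainvision", edf = "edf",
                               stop_nfb("cannot infer format from '%s'", path))
  switch(match.arg(format, c("brainvision", "edf")),
         brainvision = write_brainvision(rec, path),
         edf = write_edf(rec, path))
  invisible(path)
}

## ---- BrainVision -----------------------------------------------------------

bv_stem <- function(path) sub("\\.vhdr$", "", path, ignore.case = TRUE)

write_brainvision <- function(rec, path) {
  stem <- bv_stem(path)
  base <- basename(stem)
  vhdr <- paste0(stem, ".vhdr")
  vmrk <- paste0(stem, ".vmrk")
  eeg  <- paste0(stem, ".eeg")

  nch <- nrow(rec$data); ns <- ncol(rec$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "; Written by nfbloop",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nch),
    sprintf("DataPoints=%d", ns),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$sfreq),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), rec$ch_names)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)

  ann <- rec$annotations
  if (nrow(ann) && any(grepl(",", ann$label))) {
    stop_nfb("annotation labels may not contain ','")
  }
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0")
  if (nrow(ann)) {
    pos <- pmax(1L, round(ann$onset * rec$sfreq) + 1L)
    siz <- pmax(1L, round(ann$duration * rec$sfreq))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,%d,0",
                        seq_len(nrow(ann)) + 1L, ann$label, pos, siz))
  }
  writeLines(mk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  invisible(path)
}

parse_ini <- function(lines) {
  lines <- lines[!grepl("^\\s*;", lines)]
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- out[[sec]] %||% character(0)
    } else if (!is.null(sec) && grepl("=", ln, fixed = TRUE)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      out[[sec]][key] <- val
    }
  }
  out
}

read_brainvision <- function(path, ecg_names = c("ECG")) {
  if (!file.exists(path)) stop_nfb("header file not found: %s", path)
  ini <- parse_ini(readLines(path, encoding = "UTF-8", warn = FALSE))
  ci <- ini[["Common Infos"]]
  dir <- dirname(path)
  eeg <- file.path(dir, ci[["DataFile"]])
  vmrk <- file.path(dir, ci[["MarkerFile"]])
  if (!file.exists(eeg)) {
    stop_nfb("BrainVision triplet incomplete: missing data file '%s'",
             ci[["DataFile"]])
  }
  if (!file.exists(vmrk)) {
    stop_nfb("BrainVision triplet incomplete: missing marker file '%s'",
             ci[["MarkerFile"]])
  }
  if (toupper(ci[["DataFormat"]]) != "BINARY" ||
      toupper(ci[["DataOrientation"]]) != "MULTIPLEXED") {
    stop_nfb("only BINARY MULTIPLEXED BrainVision data is supported")
  }
  bf <- toupper(ini[["Binary Infos"]][["BinaryFormat"]])
  if (bf != "IEEE_FLOAT_32") {
    stop_nfb("unsupported BinaryFormat '%s' (only IEEE_FLOAT_32)", bf)
  }
  nch <- as.integer(ci[["NumberOfChannels"]])
  sfreq <- 1e6 / as.numeric(ci[["SamplingInterval"]])

  chinfo <- ini[["Channel Infos"]]
  ord <- order(as.integer(sub("^Ch", "", names(chinfo))))
  chinfo <- chinfo[ord]
  parts <- strsplit(unname(chinfo), ",", fixed = TRUE)
  ch_names <- vapply(parts, `[`, "", 1L)
  units <- vapply(parts, function(p) if (length(p) >= 4L) p[4L] else "µV", "")
  ok_unit <- tolower(units) %in% c("µv", "uv", "microvolt", "microvolts", "")
  if (!all(ok_unit)) {
    stop_nfb("unknown unit '%s' on channel %s", units[!ok_unit][1L],
             ch_names[!ok_unit][1L])
  }

  n_float <- file.info(eeg)$size / 4
  if (n_float != round(n_float) || (n_float %% nch) != 0) {
    stop_nfb("corrupt .eeg binary: %g float32 values not divisible by %d channels",
             n_float, nch)
  }
  ns_found <- n_float / nch
  if (!is.null(ci[["DataPoints"]]) && !is.na(ci[["DataPoints"]])) {
    ns_expect <- as.numeric(ci[["DataPoints"]])
    if (ns_expect != ns_found) {
      stop_nfb("truncated .eeg binary: expected %g samples, found %g",
               ns_expect, ns_found)
    }
  }
  con <- file(eeg, "rb")
  on.exit(close(con))
  raw <- readBin(con, numeric(), n = n_float, size = 4L, endian = "little")
  data <- matrix(raw, nrow = nch)

  ann <- empty_annotations()
  mi <- parse_ini(readLines(vmrk, encoding = "UTF-8", warn = FALSE))[["Marker Infos"]]
  if (!is.null(mi)) {
    parts <- strsplit(unname(mi), ",", fixed = TRUE)
    keep <- vapply(parts, function(p) p[1L] != "New Segment", TRUE)
    parts <- parts[keep]
    if (length(parts)) {
      ann <- data.frame(
        onset = (as.numeric(vapply(parts, `[`, "", 3L)) - 1) / sfreq,
        duration = as.numeric(vapply(parts, `[`, "", 4L)) / sfreq,
        label = vapply(parts, `[`, "", 2L),
        stringsAsFactors = FALSE)
    }
  }
  eeg_recording(data, sfreq, ch_names, annotations = ann,
                ecg_names = ecg_names)
}

## ---- EDF -------------------------------------------------------------------

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  sf <- rec$sfreq
  if (abs(sf - round(sf)) > 1e-9) {
    stop_nfb("EDF writer requires an integer sampling rate, got %g", sf)
  }
  sf <- as.integer(round(sf))
  nch <- nrow(rec$data); ns <- ncol(rec$data)
  n_rec <- ceiling(ns / sf)
  pad_n <- n_rec * sf - ns
  dat <- rec$data
  if (pad_n > 0) dat <- cbind(dat, matrix(0, nch, pad_n))

  pmin_ <- apply(dat, 1L, min); pmax_ <- apply(dat, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s, type = "bytes"), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad("Startdate X X X X", 80))
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256L * (nch + 1L), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad(1, 8))
  wr(edf_pad(nch, 4))
  wr(paste0(vapply(rec$ch_names, edf_pad, "", width = 16), collapse = ""))
  wr(paste0(rep(edf_pad("", 80), nch), collapse = ""))
  wr(paste0(rep(edf_pad("uV", 8), nch), collapse = ""))
  wr(paste0(vapply(pmin_, edf_num, "", width = 8), collapse = ""))
  wr(paste0(vapply(pmax_, edf_num, "", width = 8), collapse = ""))
  wr(paste0(rep(edf_pad(dmin, 8), nch), collapse = ""))
  wr(paste0(rep(edf_pad(dmax, 8), nch), collapse = ""))
  wr(paste0(rep(edf_pad("", 80), nch), collapse = ""))
  wr(paste0(rep(edf_pad(sf, 8), nch), collapse = ""))
  wr(paste0(rep(edf_pad("", 32), nch), collapse = ""))

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * sf + 1L):(r * sf)
    for (ch in seq_len(nch)) {
      dig <- round((dat[ch, idx] - pmin_[ch]) * scale[ch] + dmin)
      writeBin(as.integer(clip(dig, dmin, dmax)), con, size = 2L,
               endian = "little")
    }
  }
  if (nrow(rec$annotations)) {
    write_events(rec$annotations, edf_sidecar(path))
  }
  invisible(path)
}

edf_sidecar <- function(path) paste0(sub("\\.edf$", "", path, ignore.case = TRUE),
                                     "_events.tsv")

read_edf <- function(path, ecg_names = c("ECG")) {
  if (!file.exists(path)) stop_nfb("EDF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur_rec <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  get_fields <- function(width) {
    vapply(seq_len(nch), function(i) trimws(rd(width)), "")
  }
  ch_names <- get_fields(16)
  get_fields(80)
  units <- get_fields(8)
  ok <- tolower(units) %in% c("uv", "µv", "")
  if (!all(ok)) stop_nfb("unknown EDF unit '%s'", units[!ok][1L])
  pmin_ <- as.numeric(get_fields(8))
  pmax_ <- as.numeric(get_fields(8))
  dmin <- as.numeric(get_fields(8))
  dmax <- as.numeric(get_fields(8))
  get_fields(80)
  spr <- as.integer(get_fields(8))
  get_fields(32)
  if (length(unique(spr)) != 1L) stop_nfb("mixed sampling rates not supported")
  sfreq <- spr[1L] / dur_rec

  data <- matrix(0, nch, n_rec * spr[1L])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      data[ch, ((r - 1L) * spr[1L] + 1L):(r * spr[1L])] <-
        (dig - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  ann <- empty_annotations()
  sc <- edf_sidecar(path)
  if (file.exists(sc)) {
    ev <- read_events(sc)
    ann <- data.frame(onset = ev$onset, duration = ev$duration,
                      label = ev$trial_type, stringsAsFactors = FALSE)
  }
  eeg_recording(data, sfreq, ch_names, annotations = ann, ecg_names = ecg_names)
}

## ---- Event tables ----------------------------------------------------------

#' Read / write an event table (BIDS-style TSV)
#'
#' Tab-separated with header columns `onset`, `duration`, `trial_type`
#' (additional columns pass through). Onsets must be non-decreasing;
#' `on_unsorted` selects whether violation is an error or a sort-with-warning.
#'
#' @param path TSV file path.
#' @param on_unsorted `"error"` (default) or `"sort"`.
#' @return data.frame of events.
#' @export
read_events <- function(path, on_unsorted = c("error", "sort")) {
  on_unsorted <- match.arg(on_unsorted)
  if (!file.exists(path)) stop_nfb("events file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop_nfb("events file is empty (missing header): %s", path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% hdr)) {
    stop_nfb("events header must contain onset, duration, trial_type")
  }
  if (length(lines) == 1L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(hdr)), hdr))
    out$onset <- numeric(0); out$duration <- numeric(0)
    return(out)
  }
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != length(hdr) ||
        is.na(suppressWarnings(as.numeric(r[match("onset", hdr)]))) ||
        is.na(suppressWarnings(as.numeric(r[match("duration", hdr)])))) {
      stop_nfb("malformed event row at line %d of %s", i + 1L, path)
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- hdr
  out$onset <- as.numeric(out$onset)
  out$duration <- as.numeric(out$duration)
  if (is.unsorted(out$onset)) {
    if (on_unsorted == "error") stop_nfb("event onsets are not non-decreasing")
    warning("event onsets were unsorted; sorting")
    out <- out[order(out$onset), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (any(out$duration < 0)) stop_nfb("event durations must be >= 0")
  out
}

#' @rdname read_events
#' @param events data.frame with at least `onset`, `duration`, `trial_type`
#'   (a `label` column is accepted as an alias for `trial_type`).
#' @export
write_events <- function(events, path) {
  events <- as.data.frame(events)
  if ("label" %in% names(events) && !"trial_type" %in% names(events)) {
    names(events)[names(events) == "label"] <- "trial_type"
  }
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(events))) {
    stop_nfb("events need columns onset, duration, trial_type")
  }
  events <- events[c(need, setdiff(names(events), need))]
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
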