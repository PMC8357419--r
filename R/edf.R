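#' Minimal EDF (European Data Format) I/O
#'
#' A small reader/writer pair for EDF/EDF+ continuous recordings, covering
#' the subset of the format produced by clinical EEG amplifiers: a 256-byte
#' fixed header, per-signal header fields, and data records of little-endian
#' int16 samples. Physical units are mapped linearly from the digital range
#' per the EDF specification.
#'
#' @name edf_io
NULL

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' All channels share the recording's sampling rate; data are split into
#' 1-second records and the final partial record, if any, is zero-padded.
#'
#' @param rec a `recording`.
#' @param path output path.
#' @param physical_dim physical dimension string (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_dim = "uV") {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  sig <- rec$signal
  n_ch <- nrow(sig)
  n_rec <- ceiling(ncol(sig) / fs)
  pad <- n_rec * fs - ncol(sig)
  if (pad > 0) sig <- cbind(sig, matrix(0, n_ch, pad))
  phys_max <- pmax(apply(abs(sig), 1L, max), 1e-6)
  dig_max <- 32767
  labels <- rec$channel_meta$label

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)                                  # version
  wr("X X X X", 80)                           # patient id
  wr("Startdate X X X X", 80)                 # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)        # start date/time
  wr(256L * (n_ch + 1L), 8)                   # header bytes
  wr("", 44)                                  # reserved
  wr(n_rec, 8)                                # number of data records
  wr(1, 8)                                    # record duration (s)
  wr(n_ch, 4)                                 # number of signals
  for (lab in labels) wr(lab, 16)
  for (i in seq_len(n_ch)) wr("", 80)         # transducer
  for (i in seq_len(n_ch)) wr(physical_dim, 8)
  for (i in seq_len(n_ch)) wr(format(-phys_max[i], digits = 6), 8)
  for (i in seq_len(n_ch)) wr(format(phys_max[i], digits = 6), 8)
  for (i in seq_len(n_ch)) wr(-dig_max, 8)
  for (i in seq_len(n_ch)) wr(dig_max, 8)
  for (i in seq_len(n_ch)) wr("", 80)         # prefiltering
  for (i in seq_len(n_ch)) wr(fs, 8)          # samples per record
  for (i in seq_len(n_ch)) wr("", 32)         # reserved
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(n_ch)) {
      dig <- as.integer(round(sig[i, idx] / phys_max[i] * dig_max))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

.edf_header <- function(con) {
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8); patient <- rd(80); recid <- rd(80)
  startdate <- rd(8); starttime <- rd(8)
  header_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  fld <- function(width) vapply(seq_len(n_ch), function(i) rd(width), "")
  labels <- fld(16); transducer <- fld(80); dim <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  prefilter <- fld(80); n_samp <- as.integer(fld(8)); fld(32)
  list(n_rec = n_rec, rec_dur = rec_dur, n_ch = n_ch, labels = labels,
       phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, n_samp = n_samp)
}

.match_edf_label <- function(labels, target) {
  # clinical labels come as e.g. "EEG P3-Ref", "P3", "EEG P3": match the
  # bare electrode name as a token, case-insensitively
  toks <- lapply(strsplit(toupper(labels), "[^A-Z0-9]+"), function(t) t[t != ""])
  which(vapply(toks, function(t) toupper(target) %in% t, logical(1)))
}

#' Read channels from an EDF file
#'
#' When `channels` is `NULL` the clinical preference order for somatosensory
#' coverage is applied: a parietal electrode (P3, then P4) is selected, and
#' only if neither is present a central electrode (C3, then C4) is used with
#' a `fallback` flag set on the result. With an explicit `channels` vector
#' the named electrodes are returned in that order.
#'
#' @param path an EDF/EDF+ file.
#' @param channels optional character vector of electrode names.
#' @return a `recording` (attribute `fallback` is `TRUE` when a central
#'   electrode replaced the preferred parietal ones).
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .edf_header(con)
  if (length(unique(h$n_samp)) != 1L)
    stop("read_edf supports a single sampling rate across signals")
  fs <- h$n_samp[1L] / h$rec_dur
  fallback <- FALSE
  if (is.null(channels)) {
    sel <- integer(0)
    for (lab in c("P3", "P4")) {
      sel <- .match_edf_label(h$labels, lab)
      if (length(sel)) break
    }
    if (!length(sel)) {
      for (lab in c("C3", "C4")) {
        sel <- .match_edf_label(h$labels, lab)
        if (length(sel)) { fallback <- TRUE; break }
      }
    }
    if (!length(sel))
      stop("none of P3/P4/C3/C4 present; available labels: ",
           paste(h$labels, collapse = ", "))
    sel <- sel[1L]
  } else {
    sel <- vapply(channels, function(lab) {
      i <- .match_edf_label(h$labels, lab)
      if (!length(i))
        stop("channel `", lab, "` not found; available labels: ",
             paste(h$labels, collapse = ", "))
      i[1L]
    }, integer(1))
  }
  n_samp <- h$n_samp[1L]
  sig <- matrix(0, length(sel), h$n_rec * n_samp)
  scale <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  for (r in seq_len(h$n_rec)) {
    for (i in seq_len(h$n_ch)) {
      dig <- readBin(con, integer(), n = n_samp, size = 2L, signed = TRUE,
                     endian = "little")
      k <- match(i, sel)
      if (!is.na(k)) {
        sig[k, ((r - 1L) * n_samp + 1L):(r * n_samp)] <-
          h$phys_min[i] + (dig - h$dig_min[i]) * scale[i]
      }
    }
  }
  rec <- recording(sig, fs,
                   channel_meta = data.frame(label = h$labels[sel]))
  attr(rec, "fallback") <- fallback
  rec
}
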