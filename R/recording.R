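#' Construct a multichannel recording
#'
#' The central container of the package: a channels x samples matrix of
#' voltages in microvolts together with the sampling rate and per-channel /
#' per-subject metadata. All downstream stages (state scoring, spectral
#' analysis, event detection, spiking) consume this object.
#'
#' @param signal numeric matrix, channels x samples, in uV.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_meta data.frame with one row per channel. Recognised
#'   columns: `label` (character), `x`, `y` (surface-array position in um),
#'   `depth` (probe depth in um), `zone` (one of `"superficial"`, `"deep"`,
#'   `"none"`), `functional` (logical). Missing columns are filled with
#'   defaults (generated labels, zone `"none"`, all channels functional).
#' @param subject_meta list with optional entries `species`, `age`,
#'   `age_unit` (`"postnatal_days"` or `"post_gestational_weeks"`), `id`.
#'
#' @return An object of class `recording`.
#' @export
recording <- function(signal, fs, channel_meta = NULL, subject_meta = NULL) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  stopifnot(is.matrix(signal), is.numeric(signal))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  n_ch <- nrow(signal)
  if (is.null(channel_meta)) {
    channel_meta <- data.frame(label = paste0("ch", seq_len(n_ch)))
  }
  channel_meta <- as.data.frame(channel_meta)
  if (nrow(channel_meta) != n_ch)
    stop("channel_meta has ", nrow(channel_meta), " rows but signal has ",
         n_ch, " channels")
  if (is.null(channel_meta$label))
    channel_meta$label <- paste0("ch", seq_len(n_ch))
  if (is.null(channel_meta$zone)) channel_meta$zone <- "none"
  if (is.null(channel_meta$functional)) channel_meta$functional <- TRUE
  for (pos_col in intersect(c("x", "y", "depth"), names(channel_meta))) {
    if (any(!is.finite(channel_meta[[pos_col]])))
      stop("non-finite channel position in column `", pos_col, "`")
  }
  if (!any(channel_meta$functional))
    stop("at least one channel must be functional")
  if (is.null(subject_meta)) subject_meta <- list()
  structure(
    list(signal = signal, fs = fs, channel_meta = channel_meta,
         subject_meta = subject_meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", nrow(x$signal), " channel(s) x ", ncol(x$signal),
      " samples @ ", x$fs, " Hz (",
      signif(ncol(x$signal) / x$fs, 4), " s)\n", sep = "")
  if (!is.null(x$subject_meta$species))
    cat("  subject:", x$subject_meta$species,
        if (!is.null(x$subject_meta$age))
          paste0("age ", x$subject_meta$age, " ",
                 x$subject_meta$age_unit %||% ""), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Duration of a recording in seconds
#' @param rec a `recording`.
#' @return duration in s.
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$fs

#' Write a recording as interleaved int16 binary with a JSON sidecar
#'
#' Samples are stored frame-major (sample 0 of every channel, then sample 1,
#' ...), the layout used by common acquisition systems. Voltages are divided
#' by `gain` and rounded to the nearest integer; the sidecar records the
#' channel order, sampling rate and gain needed to reconstruct uV.
#'
#' @param rec a `recording`.
#' @param path output file for the int16 data; the sidecar is written to
#'   `paste0(path, ".json")` unless `sidecar` is given.
#' @param gain uV per ADC count (int16 value x gain = uV).
#' @param sidecar optional explicit sidecar path.
#' @return `path`, invisibly.
#' @export
write_binary_int16 <- function(rec, path, gain = 0.195, sidecar = NULL) {
  stopifnot(inherits(rec, "recording"), gain > 0)
  counts <- round(rec$signal / gain)
  if (any(abs(counts) > 32767))
    stop("signal exceeds int16 range at gain ", gain, " uV/count")
  # column-major write of a channels x samples matrix == frame-major frames
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(counts), con, size = 2L, endian = "little")
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  meta <- list(
    channels = rec$channel_meta$label,
    fs = rec$fs,
    gain_uV_per_count = gain,
    n_samples = ncol(rec$signal)
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), sidecar)
  invisible(path)
}

#' Read interleaved int16 binary data
#'
#' @param path binary file of little-endian int16 samples, frame-major
#'   interleaved (all channels of sample 0, then sample 1, ...).
#' @param channel_map either the path to a JSON sidecar (as written by
#'   [write_binary_int16()]) or a list with elements `channels` (labels in
#'   file order), `gain_uV_per_count` and optionally `fs`.
#' @param fs sampling rate in Hz; taken from the sidecar when omitted.
#' @return a `recording` in uV.
#' @export
read_binary_int16 <- function(path, channel_map, fs = NULL) {
  if (is.character(channel_map) && length(channel_map) == 1L)
    channel_map <- jsonlite::fromJSON(channel_map)
  labels <- channel_map$channels
  if (is.null(labels) || length(labels) < 1L)
    stop("channel map must list channel labels in file order")
  gain <- channel_map$gain_uV_per_count
  if (is.null(gain))
    stop("channel map must provide `gain_uV_per_count` (uV per ADC count)")
  if (is.null(fs)) fs <- channel_map$fs
  if (is.null(fs)) stop("sampling rate not given and absent from channel map")
  n_ch <- length(labels)
  n_bytes <- file.info(path)$size
  if (is.na(n_bytes)) stop("cannot read file: ", path)
  if (n_bytes %% (2L * n_ch) != 0L) {
    stop("truncated or malformed file: ", n_bytes, " bytes is not a whole ",
         "number of ", n_ch, "-channel int16 frames (",
         n_bytes / (2 * n_ch), " frames, expected an integer)")
  }
  n_frames <- n_bytes %/% (2L * n_ch)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_counts <- readBin(con, integer(), n = n_ch * n_frames, size = 2L,
                        signed = TRUE, endian = "little")
  sig <- matrix(raw_counts * gain, nrow = n_ch)
  recording(sig, fs, channel_meta = data.frame(label = labels))
}
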