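#' Read and write recordings as CSV
#'
#' Plain-text interchange format: one row per channel, the first field the
#' channel name, a leading comment line `# fs=<Hz>` carrying the sampling
#' rate. Values are written with 17 significant digits so a round trip is
#' bitwise exact.
#'
#' @param path File path.
#' @param fs Sampling rate; overrides (and is required in the absence of)
#'   the `# fs=` line.
#' @return [read_eeg_csv()] returns an [eeg_recording()];
#'   [write_eeg_csv()] returns `path` invisibly.
#' @export
read_eeg_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop_eegclean("file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  fsl <- grep("^#\\s*fs=", meta, value = TRUE)
  if (is.null(fs)) {
    if (length(fsl) == 0L)
      stop_eegclean("no '# fs=' line in ", path, " and no 'fs' argument")
    fs <- as.numeric(sub("^#\\s*fs=", "", fsl[1L]))
  }
  if (length(body) == 0L) stop_eegclean("no channel rows in ", path)
  parts <- strsplit(body, ",", fixed = TRUE)
  lens <- lengths(parts)
  if (length(unique(lens)) != 1L)
    stop_eegclean("ragged CSV: line ", which(lens != lens[1L])[1L] ,
                  " has ", lens[lens != lens[1L]][1L],
                  " fields, expected ", lens[1L])
  names_ <- vapply(parts, `[[`, character(1L), 1L)
  data <- do.call(rbind, lapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-1L]))
    if (anyNA(v)) stop_eegclean("non-numeric sample value in channel ", p[1L])
    v
  }))
  eeg_recording(data, fs = fs, channel_names = names_)
}

#' @rdname read_eeg_csv
#' @param rec An [eeg_recording()].
#' @export
write_eeg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  rows <- vapply(seq_len(nrow(rec$data)), function(i)
    paste(c(rec$channel_names[i], sprintf("%.17g", rec$data[i, ])),
          collapse = ","), character(1L))
  writeLines(c(sprintf("# fs=%.17g", rec$fs), rows), path)
  invisible(path)
}

## --- Minimal EDF (European Data Format) support ------------------------
## 256-byte fixed header + 256 bytes per signal, 16-bit little-endian
## samples with per-signal physical/digital scaling. Enough for plain
## continuous EEG; annotations and discontinuous files are out of scope.

edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = width, flag = "-")
  substr(s, 1L, width)
}

## Format a number into EDF's 8-character numeric fields, losslessly
## re-parseable from the written text.
edf_num <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g")
    if (nchar(s) <= 8L) return(s)
  }
  substr(formatC(x, format = "e", digits = 1), 1L, 8L)
}

#' Read and write recordings in EDF
#'
#' A minimal reader/writer for continuous EDF files (16-bit samples with
#' linear physical scaling). Writing quantizes to the EDF 16-bit grid, so a
#' round trip is exact only to quantization accuracy.
#'
#' @param path File path.
#' @return [read_edf()] returns an [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_eegclean("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  rd(8L)                                    # version
  rd(80L); rd(80L); rd(8L); rd(8L)          # patient, recording, date, time
  as.integer(rd(8L))                        # header bytes
  rd(44L)                                   # reserved
  n_rec <- as.integer(rd(8L))
  dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop_eegclean("malformed EDF header: signal count")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16L), character(1L)))
  for (i in seq_len(ns)) rd(80L)            # transducer
  for (i in seq_len(ns)) rd(8L)             # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  for (i in seq_len(ns)) rd(80L)            # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  for (i in seq_len(ns)) rd(32L)            # reserved
  if (length(unique(spr)) != 1L)
    stop_eegclean("mixed sampling rates per signal are not supported")
  data <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      g <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      data[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        pmin[i] + (d - dmin[i]) * g
    }
  }
  eeg_recording(data, fs = spr[1L] / dur, channel_names = labels)
}

#' @rdname read_edf
#' @param rec An [eeg_recording()].
#' @param record_s Data-record length in seconds (the recording is truncated
#'   to whole records).
#' @export
write_edf <- function(rec, path, record_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  spr <- as.integer(round(rec$fs * record_s))
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec < 1L) stop_eegclean("recording shorter than one data record")
  ns <- nrow(rec$data)
  x <- rec$data[, seq_len(n_rec * spr), drop = FALSE]
  pmin <- apply(x, 1L, min); pmax <- apply(x, 1L, max)
  flat <- pmax == pmin
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(edf_pad(s, w)), con)
  wr("0", 8L)
  wr("eegclean", 80L); wr("synthetic", 80L)
  wr("01.01.26", 8L); wr("00.00.00", 8L)
  wr(256L + 256L * ns, 8L); wr("", 44L)
  wr(n_rec, 8L); wr(format(record_s), 8L); wr(ns, 4L)
  for (i in seq_len(ns)) wr(substr(rec$channel_names[i], 1L, 16L), 16L)
  for (i in seq_len(ns)) wr("", 80L)
  ## widen the physical bounds slightly so the 8-character header rounding
  ## can never place data outside them, then quantize against the bounds as
  ## actually written
  span <- pmax - pmin
  pmin_s <- vapply(pmin - 0.001 * span, edf_num, character(1L))
  pmax_s <- vapply(pmax + 0.001 * span, edf_num, character(1L))
  pmin_w <- as.numeric(pmin_s); pmax_w <- as.numeric(pmax_s)
  for (i in seq_len(ns)) wr("uV", 8L)
  for (i in seq_len(ns)) wr(pmin_s[i], 8L)
  for (i in seq_len(ns)) wr(pmax_s[i], 8L)
  for (i in seq_len(ns)) wr(dmin, 8L)
  for (i in seq_len(ns)) wr(dmax, 8L)
  for (i in seq_len(ns)) wr("", 80L)
  for (i in seq_len(ns)) wr(spr, 8L)
  for (i in seq_len(ns)) wr("", 32L)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- x[i, ((r - 1L) * spr + 1L):(r * spr)]
      d <- round(dmin + (seg - pmin_w[i]) * (dmax - dmin) /
                   (pmax_w[i] - pmin_w[i]))
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
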