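#' Multichannel EEG recording
#'
#' Container for a channels-by-samples signal matrix with its sampling rate
#' and channel names. All pipeline stages consume and return this class.
#'
#' @param data Numeric matrix, channels in rows, samples in columns, in
#'   microvolts. A vector is treated as a single channel.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Optional character vector, one name per channel.
#'
#' @return An object of class `eeg_recording` with elements `data`, `fs`
#'   and `channel_names`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 256), 2), fs = 256)
#' rec
#' @export
eeg_recording <- function(data, fs, channel_names = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop_eegclean("recording must have at least one channel and one sample")
  if (!all(is.finite(data)))
    stop_eegclean("recording contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_eegclean("'fs' must be a positive scalar sampling rate in Hz")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop_eegclean("one channel name per row is required")
  structure(
    list(data = data, fs = as.numeric(fs),
         channel_names = as.character(channel_names)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("channels:", paste(utils::head(x$channel_names, 8L), collapse = ", "),
      if (length(x$channel_names) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

as_recording <- function(x, fs = NULL) {
  if (inherits(x, "eeg_recording")) return(x)
  if (is.null(fs)) stop_eegclean("'fs' is required when passing a raw matrix")
  eeg_recording(x, fs)
}
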