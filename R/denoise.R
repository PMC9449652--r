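## Stationary (undecimated, a-trous) Haar wavelet transform with circular
## filtering on a symmetrically padded signal. Analysis at level j uses the
## Haar pair upsampled by 2^(j-1); synthesis averages the adjoint branches,
## giving perfect reconstruction.

#' Stationary wavelet decomposition
#'
#' Decomposes a signal into `levels` detail bands plus a deepest-level
#' approximation using the undecimated Haar transform. The signal is
#' symmetrically padded at the end to the next multiple of `2^levels`
#' (padding is recorded and trimmed again on inversion); all bands have the
#' padded length.
#'
#' @param x Numeric signal.
#' @param levels Decomposition depth (>= 1); an error is raised when
#'   `2^levels > 4 * length(x)`.
#' @return Object of class `swt` with `approx`, `details` (list, level 1 =
#'   finest), `levels`, `wavelet`, `n` (original length) and `N` (padded).
#' @export
swt_decompose <- function(x, levels = 5L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop_eegclean("signal must have at least two samples")
  levels <- as.integer(levels)
  if (levels < 1L) stop_eegclean("'levels' must be at least 1")
  if (2^levels > 4 * n)
    stop_eegclean("2^levels exceeds four times the signal length; ",
                  "use fewer decomposition levels")
  N <- as.integer(ceiling(n / 2^levels) * 2^levels)
  a <- pad_reflect(x, N)
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    sh <- 2L^(j - 1L)
    nxt <- circ_shift(a, -sh)
    details[[j]] <- (a - nxt) / sqrt(2)
    a <- (a + nxt) / sqrt(2)
  }
  structure(list(approx = a, details = details, levels = levels,
                 wavelet = "haar", n = n, N = N),
            class = "swt")
}

## Extend a signal to length N by repeated symmetric (half-point) reflection.
pad_reflect <- function(x, N) {
  while (length(x) < N) x <- c(x, rev(x))
  x[seq_len(N)]
}

#' Inverse stationary wavelet transform
#'
#' Reconstructs the signal from an [swt_decompose()] object (optionally with
#' modified coefficient bands) and trims the padding, so
#' `swt_reconstruct(swt_decompose(x))` equals `x` to machine precision.
#'
#' @param co An `swt` object.
#' @return Numeric vector of the original length.
#' @export
swt_reconstruct <- function(co) {
  stopifnot(inherits(co, "swt"))
  a <- co$approx
  for (j in co$levels:1L) {
    sh <- 2L^(j - 1L)
    d <- co$details[[j]]
    ## adjoint average of the low- and high-pass branches
    a <- ((a + circ_shift(a, sh)) + (d - circ_shift(d, sh))) / (2 * sqrt(2))
  }
  a[seq_len(co$n)]
}

#' Universal global threshold from finest-scale details
#'
#' `sigma * sqrt(2 log n)` with the noise scale estimated as
#' `median(|d1|) / 0.6745` from the level-1 detail coefficients. Returns 0
#' when the details are identically zero.
#'
#' @param detail1 Level-1 (finest) detail coefficients.
#' @param n Signal length used in the log term.
#' @return Non-negative threshold.
#' @examples
#' global_threshold(c(1, -1, 2, -2), 4) # ~3.703
#' @export
global_threshold <- function(detail1, n) {
  if (n < 2L) stop_eegclean("'n' must be at least 2")
  if (all(detail1 == 0)) return(0)
  sigma <- stats::median(abs(detail1)) / 0.6745
  sigma * sqrt(2 * log(n))
}

#' Soft thresholding
#'
#' `sign(c) * max(|c| - thr, 0)` — shrinks coefficients towards zero and
#' zeroes everything below the threshold.
#'
#' @param coefs Numeric coefficients.
#' @param thr Non-negative threshold.
#' @return Shrunk coefficients.
#' @export
soft_threshold <- function(coefs, thr) {
  if (thr < 0) stop_eegclean("threshold must be non-negative")
  sign(coefs) * pmax(abs(coefs) - thr, 0)
}

#' Suppress an artifactual source by wavelet thresholding
#'
#' Decomposes the source (stationary Haar transform), soft-thresholds the
#' detail bands with the universal global threshold (computed once per
#' source from the finest details), and reconstructs an artifact-only
#' signal from the untouched approximation plus the shrunk details — the
#' small detail values removed by the shrinkage are the neural activity
#' leaked into the component. The cleaned residue is `s - artifact_only`,
#' so `cleaned + artifact_only == s` exactly.
#'
#' @param s Numeric source signal.
#' @param levels Decomposition depth.
#' @param thr Optional fixed threshold; default the universal rule.
#' @return List with `artifact_only`, `cleaned` and `threshold`.
#' @export
suppress_component <- function(s, levels = 5L, thr = NULL) {
  s <- as.numeric(s)
  if (!all(is.finite(s))) stop_eegclean("source contains non-finite values")
  co <- swt_decompose(s, levels)
  if (is.null(thr)) thr <- global_threshold(co$details[[1L]], length(s))
  co$details <- lapply(co$details, soft_threshold, thr = thr)
  artifact_only <- swt_reconstruct(co)
  list(artifact_only = artifact_only, cleaned = s - artifact_only,
       threshold = thr)
}

#' Reconstruct EEG channels after suppressing flagged sources
#'
#' Replaces every flagged source by its cleaned residue (see
#' [suppress_component()]), leaves unflagged sources untouched, and projects
#' back to channel space through the mixing matrix, restoring the channel
#' means.
#'
#' @param dec A [sobi()] decomposition.
#' @param artifact_flags Logical vector, one flag per source.
#' @param levels Wavelet decomposition depth.
#' @return An [eeg_recording()] of the cleaned channels; per-source
#'   thresholds are attached as attribute `"thresholds"`.
#' @export
reconstruct_channels <- function(dec, artifact_flags, levels = 5L) {
  stopifnot(inherits(dec, "sobi"))
  if (length(artifact_flags) != nrow(dec$sources))
    stop_eegclean("'artifact_flags' must have one entry per source")
  S <- dec$sources
  thresholds <- rep(NA_real_, nrow(S))
  for (i in which(as.logical(artifact_flags))) {
    sup <- suppress_component(S[i, ], levels = levels)
    S[i, ] <- sup$cleaned
    thresholds[i] <- sup$threshold
  }
  out <- eeg_recording(dec$mixing %*% S + dec$means, fs = dec$fs,
                       channel_names = dec$channel_names)
  attr(out, "thresholds") <- thresholds
  out
}
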