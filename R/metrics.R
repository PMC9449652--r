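#' Welch power spectral density estimate
#'
#' Averaged periodogram with Hann-windowed segments (default 2 s) and 50%
#' overlap, one-sided, per channel.
#'
#' @param x Numeric matrix (channels x samples) or vector.
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds.
#' @param overlap Fractional segment overlap in `[0, 1)`.
#' @return List with `freq` (Hz) and `psd` (channels x frequencies).
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  w <- as.integer(round(window_s * fs))
  if (ncol(x) < w)
    stop_eegclean("signal shorter than one PSD window (", window_s, " s)")
  step <- max(1L, as.integer(round(w * (1 - overlap))))
  starts <- seq(1L, ncol(x) - w + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(w - 1L)) / (w - 1L))  # Hann
  norm <- fs * sum(win^2)
  nf <- w %/% 2L + 1L
  psd <- matrix(0, nrow(x), nf)
  for (s0 in starts) {
    seg <- x[, s0:(s0 + w - 1L), drop = FALSE] *
      matrix(win, nrow(x), w, byrow = TRUE)
    P <- abs(stats::mvfft(t(seg)))^2 / norm
    P <- t(P[seq_len(nf), , drop = FALSE])
    ## one-sided: double everything except DC (and Nyquist for even w)
    dbl <- rep(2, nf); dbl[1L] <- 1
    if (w %% 2L == 0L) dbl[nf] <- 1
    psd <- psd + P * matrix(dbl, nrow(x), nf, byrow = TRUE)
  }
  list(freq = (0:(nf - 1L)) * fs / w, psd = psd / length(starts))
}

#' Relative root-mean-square error in the time domain
#'
#' `RMS(X - Xhat) / RMS(X)`: the reconstruction error relative to the
#' reference signal's amplitude.
#'
#' @param x Reference matrix (e.g. pure EEG).
#' @param xhat Reconstructed matrix of the same shape.
#' @return Non-negative scalar.
#' @export
rrmse_time <- function(x, xhat) {
  if (!all(dim(as.matrix(x)) == dim(as.matrix(xhat))))
    stop_eegclean("shapes differ")
  r <- rms(x)
  if (r == 0) stop_eegclean("reference signal has zero RMS")
  rms(as.matrix(x) - as.matrix(xhat)) / r
}

#' Spectral relative errors between two recordings
#'
#' `rrmse_psd()` is the RMS of the PSD difference over channels and
#' frequencies divided by the RMS of the reference PSD; `rrmae_psd()` is the
#' (unnormalized) mean absolute PSD difference. Spectra come from
#' [welch_psd()].
#'
#' @param x,xhat Reference and reconstructed matrices of the same shape.
#' @param fs Sampling rate in Hz.
#' @param ... Passed to [welch_psd()].
#' @return Non-negative scalar.
#' @export
rrmse_psd <- function(x, xhat, fs, ...) {
  if (!all(dim(as.matrix(x)) == dim(as.matrix(xhat))))
    stop_eegclean("shapes differ")
  px <- welch_psd(x, fs, ...)$psd
  ph <- welch_psd(xhat, fs, ...)$psd
  rms(px - ph) / rms(px)
}

#' @rdname rrmse_psd
#' @export
rrmae_psd <- function(x, xhat, fs, ...) {
  if (!all(dim(as.matrix(x)) == dim(as.matrix(xhat))))
    stop_eegclean("shapes differ")
  px <- welch_psd(x, fs, ...)$psd
  ph <- welch_psd(xhat, fs, ...)$psd
  mean(abs(px - ph))
}

#' Average channel-wise Pearson correlation
#'
#' Mean over channels of the correlation between each reference channel and
#' its reconstructed counterpart. Constant channels are skipped with a
#' warning.
#'
#' @param x,xhat Matrices of the same shape.
#' @return Scalar in `[-1, 1]`.
#' @export
average_correlation <- function(x, xhat) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!all(dim(x) == dim(xhat))) stop_eegclean("shapes differ")
  rs <- vapply(seq_len(nrow(x)), function(i) {
    if (stats::sd(x[i, ]) == 0 || stats::sd(xhat[i, ]) == 0) NA_real_
    else stats::cor(x[i, ], xhat[i, ])
  }, numeric(1L))
  if (anyNA(rs)) warning(sum(is.na(rs)), " constant channel(s) skipped")
  mean(rs, na.rm = TRUE)
}

## Equal-count (quantile) bin assignment; collapses tied break points.
quantile_bins <- function(v, bins) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L)))
  if (length(br) < 2L) br <- c(br - 0.5, br + 0.5)
  cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Average mutual information between two recordings
#'
#' Per channel, a plug-in mutual-information estimate in bits from a 2-D
#' histogram of the joint distribution on equal-count (quantile) bins,
#' averaged over channels. MI is symmetric in its arguments.
#'
#' @param x,xhat Matrices of the same shape.
#' @param bins Marginal bin count (default 16); requires at least
#'   `10 * bins^2` samples per channel.
#' @return Non-negative scalar, in bits.
#' @export
average_mutual_information <- function(x, xhat, bins = 16L) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!all(dim(x) == dim(xhat))) stop_eegclean("shapes differ")
  if (ncol(x) < 10 * bins^2)
    stop_eegclean("need at least 10 * bins^2 = ", 10 * bins^2,
                  " samples per channel; use fewer bins")
  mean(vapply(seq_len(nrow(x)), function(i) {
    bx <- quantile_bins(x[i, ], bins)
    by <- quantile_bins(xhat[i, ], bins)
    joint <- table(bx, by) / length(bx)
    px <- rowSums(joint); py <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
  }, numeric(1L)))
}

#' Truncated-band spectral trade-off score
#'
#' Ratio of the spectral change inside the brain-activity band (4--30 Hz) to
#' the spectral change inside the artifact bands (1--4 Hz and above 30 Hz up
#' to Nyquist), computed from Welch spectra before and after artifact
#' removal. Small values mean the EEG band was preserved while the artifact
#' bands were suppressed.
#'
#' @param before,after Recordings (matrices) before and after cleaning.
#' @param fs Sampling rate in Hz.
#' @param ... Passed to [welch_psd()].
#' @return Non-negative scalar; an error is raised when nothing changed
#'   outside 4--30 Hz (the score is undefined).
#' @export
psd_tr <- function(before, after, fs, ...) {
  if (!all(dim(as.matrix(before)) == dim(as.matrix(after))))
    stop_eegclean("shapes differ")
  pb <- welch_psd(before, fs, ...)
  pa <- welch_psd(after, fs, ...)
  f <- pb$freq
  d <- pb$psd - pa$psd
  mid <- f >= 4 & f <= 30
  low <- f >= 1 & f < 4
  high <- f > 30
  denom <- rms(d[, low, drop = FALSE]) + rms(d[, high, drop = FALSE])
  if (denom == 0)
    stop_eegclean("no spectral change outside 4-30 Hz: the trade-off score ",
                  "is undefined")
  rms(d[, mid, drop = FALSE]) / denom
}

#' Full evaluation report for a cleaned scene
#'
#' Computes every evaluation criterion for a cleaned recording against the
#' scene's ground truth: time- and PSD-domain relative errors, the mean
#' absolute PSD error, average correlation, average mutual information
#' (all against the pure EEG), and the truncated-band trade-off score
#' (contaminated vs cleaned).
#'
#' @param scene An [build_scene()] scene.
#' @param cleaned Cleaned recording ([eeg_recording()] or matrix).
#' @param bins AMI bin count.
#' @return Named list of class `metrics_report`.
#' @export
metrics_report <- function(scene, cleaned, bins = 16L) {
  stopifnot(inherits(scene, "eeg_scene"))
  xh <- if (inherits(cleaned, "eeg_recording")) cleaned$data else as.matrix(cleaned)
  out <- list(
    rrmse_time = rrmse_time(scene$pure, xh),
    rrmse_psd = rrmse_psd(scene$pure, xh, scene$fs),
    rrmae_psd = rrmae_psd(scene$pure, xh, scene$fs),
    acc_corr = average_correlation(scene$pure, xh),
    ami_bits = average_mutual_information(scene$pure, xh, bins = bins),
    psd_tr = tryCatch(psd_tr(scene$contaminated, xh, scene$fs),
                      error = function(e) NA_real_))
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (nm in names(x))
    cat(sprintf("  %-11s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else sprintf("%.4f", x[[nm]])))
  invisible(x)
}
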