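#' Root-mean-square amplitude of a signal matrix
#'
#' RMS over all cells of a channels-by-samples matrix (or a vector),
#' `sqrt(mean(x^2))`. This is the amplitude measure used throughout the
#' simulator (artifact gain calibration) and the evaluation metrics.
#'
#' @param x Numeric vector or matrix.
#' @return Non-negative scalar.
#' @examples
#' rms(matrix(1, 3, 4)) # 1
#' rms(c(3, 4))         # sqrt(12.5)
#' @export
rms <- function(x) {
  if (length(x) == 0L) stop_eegclean("rms() of an empty input is undefined")
  sqrt(mean(as.numeric(x)^2))
}

#' Simulation configuration
#'
#' Study conditions for the synthetic contaminated-EEG generator: 19 channels
#' sampled at 256 Hz, built from 2-s segments, with artifacts injected at a
#' linear signal-to-noise ratio. These defaults are the reference
#' configuration used by every test and by the reproduction script.
#'
#' @param n_channels Number of EEG channels.
#' @param fs Sampling rate in Hz.
#' @param duration Recording length in seconds; must be a multiple of
#'   `segment_s`.
#' @param segment_s Segment length in seconds for both the pure-EEG generator
#'   and artifact burst placement.
#' @param snr Linear signal-to-noise ratio: RMS(pure EEG) / RMS(scaled
#'   artifact panel).
#' @param artifact_kinds Subset of `c("ECG","EMG","EOG","blink","white_noise")`.
#' @param min_nonzero_rows Minimum number of non-zero entries in each random
#'   channel projection.
#' @param seed Optional integer seed making the scene reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 19L, fs = 256, duration = 60,
                       segment_s = 2,
                       snr = 1,
                       artifact_kinds = c("ECG", "EMG", "EOG", "blink",
                                          "white_noise"),
                       min_nonzero_rows = 10L, seed = NULL) {
  if (duration <= 0 || abs(duration / segment_s - round(duration / segment_s)) > 1e-9)
    stop_eegclean("'duration' must be a positive multiple of 'segment_s'")
  if (!is.numeric(snr) || snr <= 0)
    stop_eegclean("'snr' must be a positive linear ratio")
  kinds <- match.arg(artifact_kinds,
                     c("ECG", "EMG", "EOG", "blink", "white_noise"),
                     several.ok = TRUE)
  if (min_nonzero_rows > n_channels)
    stop_eegclean("'min_nonzero_rows' cannot exceed 'n_channels'")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 duration = duration, segment_s = segment_s, snr = snr,
                 artifact_kinds = kinds,
                 min_nonzero_rows = as.integer(min_nonzero_rows),
                 seed = seed),
            class = "sim_config")
}

#' Convert between decibel and linear SNR
#'
#' @param x SNR value.
#' @return The converted value.
#' @export
snr_db_to_linear <- function(x) 10^(x / 20)

#' @rdname snr_db_to_linear
#' @export
snr_linear_to_db <- function(x) 20 * log10(x)

#' Generate pure simulated EEG
#'
#' Each channel is built from consecutive 2-s segments; each segment is the
#' sum of four unit-amplitude sinusoids with frequencies drawn independently
#' and uniformly from 4--30 Hz and phases uniform on \eqn{[0, 2\pi)}.
#' Segments are concatenated, so a 1-min channel consists of thirty
#' independent segments.
#'
#' @param cfg A [sim_config()].
#' @return Numeric matrix `n_channels x (duration * fs)`.
#' @export
generate_pseeg <- function(cfg) {
  with_seed(cfg$seed, {
    n_seg <- as.integer(round(cfg$duration / cfg$segment_s))
    seg_len <- as.integer(round(cfg$segment_s * cfg$fs))
    tt <- (seq_len(seg_len) - 1) / cfg$fs
    out <- matrix(0, cfg$n_channels, n_seg * seg_len)
    for (ch in seq_len(cfg$n_channels)) {
      for (sg in seq_len(n_seg)) {
        f <- stats::runif(4, 4, 30)
        ph <- stats::runif(4, 0, 2 * pi)
        seg <- colSums(sin(outer(2 * pi * f, tt) + ph))
        out[ch, ((sg - 1L) * seg_len + 1L):(sg * seg_len)] <- seg
      }
    }
    out
  })
}

## AR(12) coefficients for the synthetic ECG generator, fitted once (and
## cached) by Yule-Walker to a deterministic sum-of-Gaussians ECG beat
## template at 70 bpm. Yule-Walker estimates are always stationary.
ecg_ar_cache <- new.env(parent = emptyenv())

ecg_template <- function(fs, n_beats = 35) {
  beat_s <- 60 / 70
  t_beat <- seq(0, beat_s, by = 1 / fs)[-1]
  ## P, Q, R, S, T waves as Gaussians: centers (s), widths (s), amplitudes
  centers <- c(0.20, 0.28, 0.30, 0.32, 0.45) * beat_s
  widths  <- c(0.040, 0.010, 0.012, 0.010, 0.045) * beat_s
  amps    <- c(0.15, -0.20, 1.00, -0.25, 0.30)
  beat <- rowSums(mapply(function(c0, w, a) a * exp(-(t_beat - c0)^2 / (2 * w^2)),
                         centers, widths, amps))
  rep(beat, n_beats)
}

ecg_ar_coefficients <- function(fs) {
  key <- as.character(fs)
  if (!is.null(ecg_ar_cache[[key]])) return(ecg_ar_cache[[key]])
  fit <- stats::ar(ecg_template(fs), aic = FALSE, order.max = 12L,
                   method = "yule-walker")
  ecg_ar_cache[[key]] <- fit$ar
  fit$ar
}

#' Generate a single artifact waveform
#'
#' The five artifact classes of the simulator:
#' \describe{
#'   \item{ECG}{AR(12) process driven by white noise; coefficients fitted to
#'     a built-in synthetic sum-of-Gaussians ECG beat template (70 bpm).}
#'   \item{EMG}{White noise through a 20--60 Hz band-pass FIR filter
#'     (order 128, Hamming-window design).}
#'   \item{EOG}{0.2 Hz square wave (5-s period, 50% duty cycle).}
#'   \item{blink}{White noise band-pass filtered between 1 and 3 Hz.}
#'   \item{white_noise}{I.i.d. standard normal noise.}
#' }
#' With `bursts = TRUE` (the default) the waveform is gated so that each
#' consecutive 2-s window contains one burst of random length drawn uniformly
#' from 0.5--2 s (zero elsewhere). The returned waveform is normalized to
#' unit RMS over its full duration.
#'
#' @param kind One of `"ECG"`, `"EMG"`, `"EOG"`, `"blink"`, `"white_noise"`.
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed.
#' @param bursts Gate the waveform into per-window bursts?
#' @param segment_s Burst window length in seconds.
#' @return Numeric vector of `duration * fs` samples with unit RMS.
#' @export
generate_artifact <- function(kind, duration, fs, seed = NULL, bursts = TRUE,
                              segment_s = 2) {
  kind <- match.arg(kind, c("ECG", "EMG", "EOG", "blink", "white_noise"))
  n <- as.integer(round(duration * fs))
  with_seed(seed, {
    x <- switch(kind,
      ECG = {
        coefs <- ecg_ar_coefficients(fs)
        burn <- 512L
        e <- stats::rnorm(n + burn)
        as.numeric(stats::filter(e, coefs, method = "recursive"))[-seq_len(burn)]
      },
      EMG = {
        b <- signal::fir1(128, c(20, 60) / (fs / 2), type = "pass")
        pad <- 128L
        as.numeric(signal::filter(b, stats::rnorm(n + pad)))[-seq_len(pad)]
      },
      EOG = {
        tt <- (seq_len(n) - 1) / fs
        ifelse((tt * 0.2) %% 1 < 0.5, 1, -1)
      },
      blink = {
        bf <- signal::butter(4, c(1, 3) / (fs / 2), type = "pass")
        as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
      },
      white_noise = stats::rnorm(n)
    )
    if (bursts) {
      seg_len <- as.integer(round(segment_s * fs))
      n_seg <- n %/% seg_len
      mask <- numeric(n)
      for (sg in seq_len(n_seg)) {
        len_s <- stats::runif(1, 0.5, segment_s)
        start_s <- stats::runif(1, 0, segment_s - len_s)
        i0 <- (sg - 1L) * seg_len + 1L + as.integer(floor(start_s * fs))
        i1 <- min(i0 + as.integer(round(len_s * fs)) - 1L, sg * seg_len)
        mask[i0:i1] <- 1
      }
      ## samples beyond the last full window stay inactive
      x <- x * mask
    }
    r <- rms(x)
    if (r == 0) stop_eegclean("degenerate all-zero artifact waveform")
    x / r
  })
}

#' Project a waveform onto EEG channels with a random sparse gain vector
#'
#' The gain vector has at least `min_nonzero` non-zero entries (the number of
#' active channels is itself drawn uniformly between `min_nonzero` and
#' `n_channels`); non-zero gains are standard normal.
#'
#' @param waveform Numeric vector of samples.
#' @param n_channels Number of output channels.
#' @param seed Optional integer seed.
#' @param min_nonzero Minimum number of non-zero gains.
#' @return Matrix `n_channels x length(waveform)`; the gain vector is
#'   attached as attribute `"gain"`.
#' @export
random_projection <- function(waveform, n_channels, seed = NULL,
                              min_nonzero = 10L) {
  if (n_channels < min_nonzero)
    stop_eegclean("'n_channels' must be at least 'min_nonzero'")
  with_seed(seed, {
    m <- sample(min_nonzero:n_channels, 1L)
    rows <- sample.int(n_channels, m)
    gain <- numeric(n_channels)
    gain[rows] <- stats::rnorm(m)
    panel <- tcrossprod(gain, waveform)
    attr(panel, "gain") <- gain
    panel
  })
}

#' Mix a pure recording with an artifact panel at a requested SNR
#'
#' Solves for the artifact intensity \eqn{\lambda} so that
#' RMS(pure) / RMS(\eqn{\lambda} * artifacts) equals the requested linear
#' SNR, and returns the contaminated matrix `pure + lambda * artifacts`.
#'
#' @param pure Pure EEG matrix.
#' @param artifacts Artifact panel matrix of the same shape.
#' @param snr Requested linear SNR (> 0).
#' @return List with `contaminated` and `lambda`.
#' @export
mix_at_snr <- function(pure, artifacts, snr) {
  if (!all(dim(pure) == dim(artifacts)))
    stop_eegclean("pure and artifact matrices must have the same shape")
  ra <- rms(artifacts)
  if (ra == 0) stop_eegclean("artifact panel is identically zero; cannot set an SNR")
  lambda <- rms(pure) / (snr * ra)
  list(contaminated = pure + lambda * artifacts, lambda = lambda)
}

#' Build a simulated contaminated-EEG scene
#'
#' Generates pure EEG, one burst-gated artifact waveform per configured kind,
#' projects each onto the channels through a random sparse gain vector, sums
#' the panels, and mixes at the configured SNR. All ground truth (waveforms,
#' gains, lambda) is retained for downstream labeling and evaluation.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `eeg_scene` with elements `pure`,
#'   `contaminated`, `artifact_panel` (the unscaled summed panels),
#'   `waveforms` (named list of 1-D ground-truth waveforms), `gains`,
#'   `lambda`, `snr`, `fs` and `cfg`.
#' @examples
#' sc <- build_scene(sim_config(duration = 10, seed = 1))
#' rms(sc$pure) / rms(sc$lambda * sc$artifact_panel) # == sc$snr
#' @export
build_scene <- function(cfg) {
  if (length(cfg$artifact_kinds) == 0L)
    stop_eegclean("at least one artifact kind must be enabled")
  pure <- generate_pseeg(cfg)
  assemble_scene(pure, cfg)
}

#' Inject synthetic artifacts into a user-supplied clean recording
#'
#' Semi-simulated path: the pure EEG is taken from `clean` instead of the
#' sinusoidal generator; artifacts are generated, projected and mixed exactly
#' as in [build_scene()].
#'
#' @param clean An [eeg_recording()] providing the pure EEG.
#' @param cfg A [sim_config()]; `n_channels`, `fs` and `duration` must match
#'   the recording.
#' @return An `eeg_scene`, as in [build_scene()].
#' @export
inject_into_recording <- function(clean, cfg) {
  stopifnot(inherits(clean, "eeg_recording"))
  if (nrow(clean$data) != cfg$n_channels)
    stop_eegclean("recording has ", nrow(clean$data),
                  " channels but the configuration expects ", cfg$n_channels)
  if (ncol(clean$data) != round(cfg$duration * cfg$fs))
    stop_eegclean("recording length does not match the configured duration")
  assemble_scene(clean$data, cfg)
}

assemble_scene <- function(pure, cfg) {
  kinds <- cfg$artifact_kinds
  waveforms <- list()
  gains <- list()
  panel <- matrix(0, cfg$n_channels, ncol(pure))
  for (i in seq_along(kinds)) {
    w <- generate_artifact(kinds[i], cfg$duration, cfg$fs,
                           seed = child_seed(cfg$seed, i),
                           segment_s = cfg$segment_s)
    p <- random_projection(w, cfg$n_channels,
                           seed = child_seed(cfg$seed, 100 + i),
                           min_nonzero = cfg$min_nonzero_rows)
    waveforms[[kinds[i]]] <- w
    gains[[kinds[i]]] <- attr(p, "gain")
    attr(p, "gain") <- NULL
    panel <- panel + p
  }
  mix <- mix_at_snr(pure, panel, cfg$snr)
  structure(list(pure = pure, contaminated = mix$contaminated,
                 artifact_panel = panel, waveforms = waveforms,
                 gains = gains, lambda = mix$lambda, snr = cfg$snr,
                 fs = cfg$fs, cfg = cfg),
            class = "eeg_scene")
}

#' @export
print.eeg_scene <- function(x, ...) {
  cat(sprintf("<eeg_scene> %d channels x %d samples @ %g Hz, SNR %g (lambda %.4g)\n",
              nrow(x$pure), ncol(x$pure), x$fs, x$snr, x$lambda))
  cat("artifacts:", paste(names(x$waveforms), collapse = ", "), "\n")
  invisible(x)
}
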