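## Covariance convention: this module divides by the number of summed
## products (T, or T - q at lag q), so the lag-0 covariance of whitened data
## is exactly the identity.

#' Zero-mean and whiten a multichannel recording
#'
#' Removes each channel's mean and applies a whitening matrix from the
#' eigendecomposition of the channel covariance, so the whitened rows have
#' identity sample covariance.
#'
#' @param rec An [eeg_recording()] or numeric matrix (channels x samples).
#' @return List with `whitened` (matrix), `whitener` (matrix such that
#'   `whitener %*% centered` is white) and `means` (channel means).
#' @export
zero_mean_whiten <- function(rec) {
  x <- if (inherits(rec, "eeg_recording")) rec$data else as.matrix(rec)
  if (nrow(x) < 2L) stop_eegclean("at least two channels are required")
  means <- rowMeans(x)
  xc <- x - means
  C <- tcrossprod(xc) / ncol(xc)
  eg <- eigen(C, symmetric = TRUE)
  tol <- max(eg$values) * 1e-12
  bad <- which(eg$values <= tol)
  if (length(bad) > 0L) {
    ## name the channels dominating the null-space eigenvectors
    load <- abs(eg$vectors[, bad, drop = FALSE])
    chans <- sort(unique(unlist(apply(load, 2L, function(v)
      which(v > 0.5 * max(v))))))
    nm <- if (inherits(rec, "eeg_recording")) rec$channel_names[chans]
          else paste0("ch", chans)
    stop_eegclean("channel covariance is rank-deficient (singular input); ",
                  "offending channels: ", paste(nm, collapse = ", "))
  }
  whitener <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  list(whitened = whitener %*% xc, whitener = whitener, means = means)
}

#' Time-lagged covariance of a whitened signal matrix
#'
#' \eqn{R(q) = \frac{1}{T-q}\sum_t \bar X(t)\bar X^\top(t-q)}, symmetrized as
#' \eqn{(R + R^\top)/2} so the joint diagonalizer can operate on it.
#'
#' @param xw Whitened channels-by-samples matrix.
#' @param q Non-negative integer lag in samples, `q < n_samples`.
#' @return Symmetric matrix `n x n`.
#' @export
lagged_covariance <- function(xw, q) {
  xw <- as.matrix(xw)
  T <- ncol(xw)
  if (q < 0 || q >= T) stop_eegclean("lag 'q' must satisfy 0 <= q < n_samples")
  q <- as.integer(q)
  R <- if (q == 0L) tcrossprod(xw) / T
       else xw[, (q + 1L):T, drop = FALSE] %*%
            t(xw[, 1L:(T - q), drop = FALSE]) / (T - q)
  (R + t(R)) / 2
}

#' Joint approximate diagonalization of symmetric matrices
#'
#' Jacobi-style sweeps of Givens rotations (Cardoso--Souloumiac) that
#' minimize the summed squared off-diagonal mass of `t(V) %*% M_k %*% V`
#' over the set. Iteration stops when every rotation sine in a sweep falls
#' below `tol`, or after `max_sweeps` sweeps.
#'
#' @param mats List of square symmetric matrices of identical shape (or an
#'   `n x n x C` array).
#' @param tol Convergence tolerance on the rotation angles.
#' @param max_sweeps Sweep cap.
#' @return Orthogonal matrix `V`; the number of sweeps used is attached as
#'   attribute `"sweeps"`.
#' @export
joint_diagonalize <- function(mats, tol = 1e-8, max_sweeps = 1000L) {
  if (is.list(mats)) {
    if (length(mats) == 0L) stop_eegclean("empty matrix list")
    n <- nrow(mats[[1L]])
    A <- array(0, c(n, n, length(mats)))
    for (k in seq_along(mats)) {
      m <- mats[[k]]
      if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
        stop_eegclean("all matrices must be square with identical shape")
      if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
        stop_eegclean("matrix ", k, " is not symmetric")
      A[, , k] <- m
    }
  } else if (is.array(mats) && length(dim(mats)) == 3L) {
    A <- mats
    n <- dim(A)[1L]
  } else stop_eegclean("'mats' must be a list of matrices or a 3-D array")
  V <- diag(n)
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    rotated <- FALSE
    for (p in 1L:(n - 1L)) {
      for (q in (p + 1L):n) {
        g1 <- A[p, p, ] - A[q, q, ]
        g2 <- A[p, q, ] + A[q, p, ]
        ton <- sum(g1 * g1) - sum(g2 * g2)
        toff <- 2 * sum(g1 * g2)
        theta <- 0.5 * atan2(toff, ton + sqrt(ton * ton + toff * toff))
        s <- sin(theta)
        if (abs(s) > tol) {
          rotated <- TRUE
          cth <- cos(theta)
          Mp <- A[, p, ]; Mq <- A[, q, ]
          A[, p, ] <- cth * Mp + s * Mq
          A[, q, ] <- cth * Mq - s * Mp
          Rp <- A[p, , ]; Rq <- A[q, , ]
          A[p, , ] <- cth * Rp + s * Rq
          A[q, , ] <- cth * Rq - s * Rp
          Vp <- V[, p]; Vq <- V[, q]
          V[, p] <- cth * Vp + s * Vq
          V[, q] <- cth * Vq - s * Vp
        }
      }
    }
    if (!rotated || sweeps >= max_sweeps) break
  }
  attr(V, "sweeps") <- sweeps
  V
}

#' Second-order blind identification of EEG sources
#'
#' Estimates uncorrelated sources from a multichannel recording by whitening
#' followed by joint approximate diagonalization of a set of time-lagged
#' covariance matrices. The number of sources equals the number of channels
#' (square mixing). Source order, sign and scale are indeterminate, as in
#' any blind separation; downstream code must not rely on them.
#'
#' @param rec An [eeg_recording()], or a matrix with `fs` supplied.
#' @param lags Strictly increasing positive integer lags (samples); default
#'   1--100.
#' @param tol Joint-diagonalization rotation tolerance.
#' @param max_sweeps Sweep cap for the joint diagonalizer.
#' @param fs Sampling rate, required when `rec` is a raw matrix.
#' @return An object of class `sobi` with elements `sources`
#'   (`n_sources x n_samples`), `mixing`, `unmixing`, `whitener`, `means`,
#'   `lags`, `fs`, `channel_names` and `sweeps`. `mixing %*% sources`
#'   reconstructs the zero-meaned input.
#' @examples
#' t <- seq(0, 4, by = 1 / 256)[-1]
#' S <- rbind(sin(2 * pi * 5 * t), sin(2 * pi * 11 * t))
#' X <- matrix(c(1, 0.4, 0.5, 1), 2) %*% S
#' dec <- sobi(eeg_recording(X, fs = 256), lags = 1:20)
#' dec
#' @export
sobi <- function(rec, lags = 1:100, tol = 1e-8, max_sweeps = 1000L,
                 fs = NULL) {
  rec <- as_recording(rec, fs)
  lags <- as.integer(lags)
  if (any(lags <= 0L) || any(diff(lags) <= 0L))
    stop_eegclean("'lags' must be strictly positive and strictly increasing")
  if (max(lags) >= ncol(rec$data))
    stop_eegclean("largest lag must be smaller than the number of samples")
  w <- zero_mean_whiten(rec)
  n <- nrow(w$whitened)
  A <- array(0, c(n, n, length(lags)))
  for (k in seq_along(lags)) A[, , k] <- lagged_covariance(w$whitened, lags[k])
  V <- joint_diagonalize(A, tol = tol, max_sweeps = max_sweeps)
  sources <- t(V) %*% w$whitened
  unmixing <- t(V) %*% w$whitener
  mixing <- solve(unmixing)
  structure(list(sources = sources, mixing = mixing, unmixing = unmixing,
                 whitener = w$whitener, means = w$means, lags = lags,
                 fs = rec$fs, channel_names = rec$channel_names,
                 sweeps = attr(V, "sweeps")),
            class = "sobi")
}

#' @export
print.sobi <- function(x, ...) {
  cat(sprintf("<sobi> %d sources x %d samples @ %g Hz\n",
              nrow(x$sources), ncol(x$sources), x$fs))
  cat(sprintf("lags: %d..%d (C = %d); joint diagonalization converged in %d sweep(s)\n",
              min(x$lags), max(x$lags), length(x$lags), x$sweeps))
  invisible(x)
}

#' @export
coef.sobi <- function(object, ...) object$mixing

#' Reconstruct the channel data implied by a SOBI decomposition
#'
#' @param object A `sobi` object.
#' @param ... Unused.
#' @return Channels-by-samples matrix `mixing %*% sources + means`.
#' @export
fitted.sobi <- function(object, ...) {
  object$mixing %*% object$sources + object$means
}
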