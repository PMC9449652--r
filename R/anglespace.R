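#' Time-delay selection for phase-space embedding
#'
#' The delay is 0.2 times the sample standard deviation of the signal,
#' rounded to the nearest sample and floored at one sample. For a constant
#' signal the delay falls back to one sample with a warning.
#'
#' @param v Numeric vector (length >= 3).
#' @return Positive integer delay in samples.
#' @export
select_delay <- function(v) {
  if (length(v) < 3L) stop_eegclean("signal too short to choose a delay")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    warning("constant signal: falling back to delay tau = 1 sample")
    return(1L)
  }
  max(1L, as.integer(round(0.2 * s)))
}

#' Time-delay embedding of a scalar signal
#'
#' Builds the trajectory `V(i) = [v(i), v(i + tau), ..., v(i + (d-1) tau)]`
#' for `i = 1, ..., K - (d-1) tau`.
#'
#' @param v Numeric vector of length `K`.
#' @param d Embedding dimension (>= 2).
#' @param tau Delay in samples (>= 1).
#' @return Matrix with `K - (d-1) tau` rows and `d` columns, of class
#'   `phase_trajectory` with attributes `tau` and `source_length`.
#' @examples
#' delay_embed(1:5, d = 2, tau = 1)
#' @export
delay_embed <- function(v, d = 2L, tau = 1L) {
  K <- length(v)
  d <- as.integer(d); tau <- as.integer(tau)
  if (d < 2L) stop_eegclean("embedding dimension 'd' must be at least 2")
  if (tau < 1L) stop_eegclean("delay 'tau' must be at least 1 sample")
  npts <- K - (d - 1L) * tau
  if (npts < 3L)
    stop_eegclean("signal of length ", K, " is too short to embed with d = ",
                  d, ", tau = ", tau)
  P <- vapply(0:(d - 1L), function(j) v[(1L + j * tau):(npts + j * tau)],
              numeric(npts))
  structure(P, class = c("phase_trajectory", class(P)),
            tau = tau, source_length = K)
}

#' Turning angles and vector lengths of a planar phase trajectory
#'
#' For each triple of consecutive trajectory points the signed turning angle
#' between the two displacement vectors is computed via
#' `atan2(cross, dot)`, in degrees, in the interval (-180, 180]. A
#' zero-length displacement contributes a zero angle by convention (the
#' number of such degenerate triples is attached as attribute
#' `"n_degenerate"`).
#'
#' @param traj A two-column trajectory from [delay_embed()] (the angle is a
#'   planar quantity; higher embedding dimensions are rejected).
#' @return List of class `angle_series` with `angles_deg` (length
#'   `n_points - 2`) and `vector_lengths` (segment lengths, `n_points - 1`).
#' @export
angle_series <- function(traj) {
  P <- unclass(traj)
  if (!is.matrix(P) || ncol(P) != 2L)
    stop_eegclean("turning angles are defined for 2-D trajectories only")
  if (nrow(P) < 3L) stop_eegclean("at least three trajectory points required")
  U <- diff(P)                      # displacement vectors
  m <- nrow(U)
  u <- U[-m, , drop = FALSE]
  w <- U[-1L, , drop = FALSE]
  cross <- u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L]
  dot <- u[, 1L] * w[, 1L] + u[, 2L] * w[, 2L]
  ang <- atan2(cross, dot) * 180 / pi
  lens <- sqrt(rowSums(U^2))
  degen <- lens[-m] == 0 | lens[-1L] == 0
  ang[degen] <- 0
  structure(list(angles_deg = ang, vector_lengths = lens),
            class = "angle_series", n_degenerate = sum(degen))
}

#' Angle plot: turning angles on the unit circle
#'
#' Maps every turning angle to the point `(cos(theta), sin(theta))`,
#' preserving sequence order.
#'
#' @param av An [angle_series()] or a numeric vector of angles in degrees.
#' @return Two-column matrix of class `angle_plot`; every row has radius 1.
#' @export
angle_plot <- function(av) {
  ang <- if (inherits(av, "angle_series")) av$angles_deg else as.numeric(av)
  if (length(ang) == 0L) stop_eegclean("empty angle sequence")
  structure(cbind(x = cospi(ang / 180), y = sinpi(ang / 180)),
            class = c("angle_plot", "matrix", "array"))
}

#' Poincare-section crossing counts of an angle plot
#'
#' Counts chords between consecutive angle-plot points that cross one of the
#' five Poincare sections: the x axis (`PP1`), the y axis (`PP2`), the
#' diagonal y = x (`PP3`), the anti-diagonal y = -x (`PP4`), or a circle of
#' radius `r` around the origin (`PP5`, counted when the chord's minimum
#' distance to the origin falls below `r`). Line crossings are strict sign
#' changes; a chord that only touches a section is not counted.
#'
#' @param ap An [angle_plot()] (any two-column point matrix is accepted).
#' @param plane One of `"PP1"` to `"PP5"`.
#' @param r Radius of the circular section used by `PP5`.
#' @return Non-negative integer crossing count.
#' @export
poincare_count <- function(ap, plane, r = 0.001) {
  P <- unclass(ap)
  if (!is.matrix(P) || ncol(P) != 2L || nrow(P) < 2L)
    stop_eegclean("an angle plot with at least two points is required")
  plane <- match.arg(plane, paste0("PP", 1:5))
  a <- P[-nrow(P), , drop = FALSE]
  b <- P[-1L, , drop = FALSE]
  if (plane == "PP5") {
    return(sum(segment_origin_distance(a, b) < r))
  }
  f <- switch(plane,
              PP1 = function(p) p[, 2L],
              PP2 = function(p) p[, 1L],
              PP3 = function(p) p[, 2L] - p[, 1L],
              PP4 = function(p) p[, 2L] + p[, 1L])
  sum(f(a) * f(b) < 0)
}

## Minimum Euclidean distance from the origin to each segment a[i,]--b[i,].
segment_origin_distance <- function(a, b) {
  d <- b - a
  len2 <- rowSums(d^2)
  t <- ifelse(len2 > 0, pmin(1, pmax(0, -rowSums(a * d) / len2)), 0)
  p <- a + d * t
  sqrt(rowSums(p^2))
}

#' The twelve angle-plot features of an EEG source
#'
#' Embeds the source in two dimensions (delay from [select_delay()] unless
#' given), computes the turning-angle series, and extracts, in order:
#' mean (`AveAP`), variance (`VaAP`), skewness (`SkAP`), kurtosis (`KuAP`,
#' the raw fourth standardized moment, not excess), median (`MeAP`), the
#' non-normalized Shannon functional \eqn{-\sum \theta^2 \ln \theta^2}
#' (`ShAP`, with `0 ln 0 = 0`), the angle-series length (`LeAP`) and the
#' five Poincare crossing counts (`NPP1`..`NPP5`). Angles are in degrees.
#'
#' @param v Numeric source signal.
#' @param tau Optional fixed delay; default chosen by [select_delay()].
#' @param r Radius of the PP5 circular section.
#' @return Named numeric vector of length 12.
#' @export
ap_features <- function(v, tau = NULL, r = 0.001) {
  if (is.null(tau)) tau <- select_delay(v)
  as_ <- angle_series(delay_embed(v, 2L, tau))
  th <- as_$angles_deg
  m2 <- mean((th - mean(th))^2)
  if (m2 == 0) {
    warning("degenerate (constant) angle series: skewness and kurtosis set to 0")
    sk <- 0; ku <- 0
  } else {
    sk <- mean((th - mean(th))^3) / m2^1.5
    ku <- mean((th - mean(th))^4) / m2^2
  }
  th2 <- th^2
  sh <- -sum(ifelse(th2 > 0, th2 * log(th2), 0))
  ap <- angle_plot(th)
  c(AveAP = mean(th), VaAP = stats::var(th), SkAP = sk, KuAP = ku,
    MeAP = stats::median(th), ShAP = sh, LeAP = length(th),
    NPP1 = poincare_count(ap, "PP1"), NPP2 = poincare_count(ap, "PP2"),
    NPP3 = poincare_count(ap, "PP3"), NPP4 = poincare_count(ap, "PP4"),
    NPP5 = poincare_count(ap, "PP5", r = r))
}

#' Angle-plot feature matrix for a set of sources
#'
#' Applies [normalize_component()] then [ap_features()] to every row of a
#' sources matrix, mirroring the feature-extraction stage of the pipeline
#' (components are amplitude-normalized to \[-1, 1\] before feature
#' statistics).
#'
#' @param sources Sources-by-samples matrix (e.g. `dec$sources` from
#'   [sobi()]).
#' @param normalize Normalize each source to \[-1, 1\] first?
#' @return Matrix `n_sources x 12` with the feature abbreviations as column
#'   names.
#' @export
feature_matrix <- function(sources, normalize = TRUE) {
  sources <- as.matrix(sources)
  t(apply(sources, 1L, function(s) {
    if (normalize) s <- normalize_component(s)
    ap_features(s)
  }))
}
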