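#' @export
plot.angle_plot <- function(x, ...) {
  graphics::plot(x[, 1L], x[, 2L], asp = 1, pch = 16, cex = 0.4,
                 xlab = expression(cos(theta)), ylab = expression(sin(theta)),
                 main = "Angle plot", ...)
  th <- seq(0, 2 * pi, length.out = 361L)
  graphics::lines(cos(th), sin(th), col = "grey70")
  graphics::abline(h = 0, v = 0, col = "grey85", lty = 3)
  invisible(x)
}

#' @export
plot.eeg_recording <- function(x, n_channels = min(8L, nrow(x$data)),
                               seconds = min(10, ncol(x$data) / x$fs),
                               main = "EEG recording", ...) {
  n <- as.integer(round(seconds * x$fs))
  idx <- seq_len(n)
  tt <- idx / x$fs
  sel <- seq_len(n_channels)
  sc <- 2 * max(apply(x$data[sel, idx, drop = FALSE], 1L, stats::sd), 1e-12)
  graphics::plot(NA, xlim = range(tt), ylim = c(0.5, n_channels + 0.5),
                 xlab = "time (s)", ylab = "", yaxt = "n", main = main, ...)
  graphics::axis(2, at = rev(seq_len(n_channels)),
                 labels = x$channel_names[sel], las = 1, cex.axis = 0.7)
  for (i in sel)
    graphics::lines(tt, n_channels + 1 - i + x$data[i, idx] / sc / 2)
  invisible(x)
}

#' @export
plot.sobi <- function(x, n_sources = min(8L, nrow(x$sources)),
                      seconds = min(10, ncol(x$sources) / x$fs), ...) {
  rec <- eeg_recording(x$sources[seq_len(n_sources), , drop = FALSE], x$fs,
                       paste0("S", seq_len(n_sources)))
  plot(rec, n_channels = n_sources, seconds = seconds,
       main = "SOBI sources", ...)
  invisible(x)
}
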