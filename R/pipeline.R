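#' Run the full artifact-removal pipeline on a scene or recording
#'
#' Executes the whole chain: SOBI source estimation, amplitude
#' normalization, angle-plot feature extraction, ensemble labeling of every
#' source, stationary-wavelet suppression of the sources flagged
#' artifactual, and channel reconstruction through the mixing matrix. When
#' the input is a simulated scene the full metric suite is computed against
#' the ground truth.
#'
#' @param x An `eeg_scene` (the contaminated channels are cleaned and
#'   evaluated against the pure ones) or an [eeg_recording()].
#' @param model A trained [train_ensemble()] classifier. Sources predicted
#'   as anything but the neural class are flagged artifactual.
#' @param lags SOBI lag set.
#' @param levels Wavelet decomposition depth for the suppression stage.
#' @param neural_label Labels counting as neural (unflagged): `"EEG"` for a
#'   six-class model, `"neural"` for a binary one (both are recognized).
#' @param dec Optional precomputed [sobi()] decomposition of the input,
#'   bypassing the separation stage.
#' @return List of class `eeg_pipeline_result` with `cleaned`
#'   (an [eeg_recording()]), `labels`, `flags`, `decomposition` and
#'   (for scenes) `metrics` ([metrics_report()]).
#' @examples
#' \donttest{
#' sc <- build_scene(sim_config(duration = 10, seed = 42))
#' dec <- sobi(eeg_recording(sc$contaminated, sc$fs))
#' labs <- binary_labels(label_sources(dec, sc))
#' mdl <- train_ensemble(feature_matrix(dec$sources), labs, seed = 1)
#' res <- run_pipeline(sc, mdl)
#' res$metrics
#' }
#' @export
run_pipeline <- function(x, model, lags = 1:100, levels = 5L,
                         neural_label = c("EEG", "neural"), dec = NULL) {
  stopifnot(inherits(model, "eeg_ensemble"))
  is_scene <- inherits(x, "eeg_scene")
  rec <- if (is_scene) eeg_recording(x$contaminated, x$fs) else x
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(dec)) dec <- sobi(rec, lags = lags)
  feats <- feature_matrix(dec$sources)
  labels <- stats::predict(model, feats)
  flags <- !(as.character(labels) %in% neural_label)
  cleaned <- reconstruct_channels(dec, flags, levels = levels)
  out <- list(cleaned = cleaned, labels = labels, flags = flags,
              decomposition = dec)
  if (is_scene) out$metrics <- metrics_report(x, cleaned)
  structure(out, class = "eeg_pipeline_result")
}

#' @export
print.eeg_pipeline_result <- function(x, ...) {
  cat(sprintf("<eeg_pipeline_result> %d sources, %d flagged artifactual\n",
              length(x$flags), sum(x$flags)))
  print(table(x$labels))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
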