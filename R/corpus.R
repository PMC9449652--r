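#' Build a labeled component corpus from simulated scenes
#'
#' Reproduces the study corpus behind the classification experiments:
#' generates `n_scenes` contaminated scenes (SNR drawn uniformly from
#' `snr_range` per scene), runs SOBI on each, labels every estimated source
#' against the scene's ground truth, and extracts the twelve angle-plot
#' features per source.
#'
#' @param n_scenes Number of independent scenes.
#' @param duration Scene length in seconds (10, 30 or 60 in the study).
#' @param snr_range Range of the per-scene uniform SNR draw.
#' @param seed Integer seed; scene seeds are derived from it.
#' @param lags SOBI lag set.
#' @param keep_scenes Keep the scenes and decompositions (needed by the
#'   end-to-end cleaning experiments; memory-heavy for large corpora)?
#' @return List of class `component_corpus` with `features`
#'   (`n x 12` matrix), `labels` (six-class factor), `binary`
#'   (neural/artifactual factor), `scene_id`, and optionally `scenes` and
#'   `decompositions`.
#' @export
simulate_component_corpus <- function(n_scenes = 50L, duration = 10,
                                      snr_range = c(0.5, 2), seed = 1L,
                                      lags = 1:100, keep_scenes = FALSE) {
  features <- NULL
  labels <- character(0)
  scene_id <- integer(0)
  scenes <- if (keep_scenes) vector("list", n_scenes) else NULL
  decs <- if (keep_scenes) vector("list", n_scenes) else NULL
  for (i in seq_len(n_scenes)) {
    si <- child_seed(seed, i)
    snr <- with_seed(child_seed(si, 1), stats::runif(1, snr_range[1L],
                                                     snr_range[2L]))
    sc <- build_scene(sim_config(duration = duration, snr = snr, seed = si))
    dec <- sobi(eeg_recording(sc$contaminated, sc$fs), lags = lags)
    lab <- label_sources(dec, sc)
    features <- rbind(features, feature_matrix(dec$sources))
    labels <- c(labels, as.character(lab))
    scene_id <- c(scene_id, rep.int(i, nrow(dec$sources)))
    if (keep_scenes) { scenes[[i]] <- sc; decs[[i]] <- dec }
  }
  labels <- factor(labels,
                   levels = c("EEG", "ECG", "EMG", "EOG", "blink",
                              "white_noise"))
  structure(list(features = features, labels = droplevels(labels),
                 binary = binary_labels(labels), scene_id = scene_id,
                 scenes = scenes, decompositions = decs,
                 duration = duration, snr_range = snr_range, seed = seed),
            class = "component_corpus")
}

#' @export
print.component_corpus <- function(x, ...) {
  cat(sprintf("<component_corpus> %d components from %d scenes (%g s, SNR %g-%g)\n",
              nrow(x$features), max(x$scene_id), x$duration,
              x$snr_range[1L], x$snr_range[2L]))
  print(table(x$labels))
  invisible(x)
}
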