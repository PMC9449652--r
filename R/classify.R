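#' Amplitude-normalize a component to [-1, 1]
#'
#' Affine min-max map so the minimum is exactly -1 and the maximum exactly
#' +1. Components are normalized this way before feature statistics so all
#' sources share one amplitude range. A constant component maps to zeros
#' with a warning.
#'
#' @param s Numeric vector.
#' @return Numeric vector in \[-1, 1\].
#' @examples
#' normalize_component(c(0, 5, 10)) # -1 0 1
#' @export
normalize_component <- function(s) {
  r <- range(s)
  if (r[1L] == r[2L]) {
    warning("constant component: normalized to zeros")
    return(rep(0, length(s)))
  }
  2 * (s - r[1L]) / (r[2L] - r[1L]) - 1
}

#' Two-sample t-test feature screening
#'
#' Welch two-sample t-test per feature between the neural and artifactual
#' groups; features with p below `alpha` are selected. Features that are
#' constant within both groups (no variance to test) are never selected.
#'
#' @param features Samples-by-features numeric matrix.
#' @param labels Binary grouping factor/vector (two levels). Multiclass
#'   labels are collapsed with `neural_label` as one group and everything
#'   else as the other.
#' @param alpha Selection level.
#' @param neural_label Label treated as the neural group when `labels` has
#'   more than two levels.
#' @return Logical mask over features, with the p-values attached as
#'   attribute `"p_values"`.
#' @export
ttest_select <- function(features, labels, alpha = 0.05,
                         neural_label = "EEG") {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2L)
    stop_eegclean("feature screening needs samples from two classes")
  g <- if (nlevels(labels) > 2L) factor(labels == neural_label) else labels
  if (min(table(g)) < 2L)
    stop_eegclean("each class needs at least two samples for the t-test")
  p <- apply(features, 2L, function(x) {
    tryCatch(stats::t.test(x[g == levels(g)[1L]],
                           x[g == levels(g)[2L]])$p.value,
             error = function(e) NA_real_)
  })
  mask <- !is.na(p) & p < alpha
  attr(mask, "p_values") <- p
  mask
}

## Gaussian naive Bayes with a variance floor (keeps near-constant features
## from producing degenerate densities).
gauss_nb_fit <- function(x, y, var_floor = 1e-9) {
  y <- as.factor(y)
  stats_by <- lapply(levels(y), function(lv) {
    xi <- x[y == lv, , drop = FALSE]
    list(mean = colMeans(xi),
         var = pmax(apply(xi, 2L, stats::var), var_floor))
  })
  names(stats_by) <- levels(y)
  list(levels = levels(y), stats = stats_by,
       log_prior = log(as.numeric(table(y)) / length(y)))
}

gauss_nb_predict <- function(fit, x) {
  ll <- vapply(seq_along(fit$levels), function(k) {
    st <- fit$stats[[k]]
    rowSums(-0.5 * log(2 * pi * rep(1, nrow(x)) %o% st$var) -
            0.5 * sweep(x, 2L, st$mean)^2 / (rep(1, nrow(x)) %o% st$var)) +
      fit$log_prior[k]
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) ll <- matrix(ll, nrow = 1L)
  factor(fit$levels[max.col(ll, ties.method = "first")], levels = fit$levels)
}

#' Train the EEG source-classification ensemble
#'
#' Fits the member classifiers on angle-plot features: a single-hidden-layer
#' MLP (10 units), KNN with K = 20, Gaussian naive Bayes, and (for the
#' four-member mixture) an SVM. Features are screened by [ttest_select()]
#' and z-scored using training statistics only; both the mask and the
#' scaling are stored in the model and re-applied at prediction time.
#'
#' @param features Samples-by-features matrix (12 angle-plot features).
#' @param labels Class labels: binary (`artifactual`/`neural`) or six-class.
#' @param members Subset of `c("mlp","knn","bayes","svm")`; the reference
#'   mixtures are the three-member (no SVM) and four-member sets.
#' @param seed Integer seed controlling the MLP initialization and KNN
#'   tie-breaks.
#' @param knn_k Neighborhood size for KNN.
#' @param hidden MLP hidden-layer size.
#' @param svm_kernel `"linear"` or `"polynomial"` (degree 3). Default:
#'   polynomial in the four-member mixture, linear otherwise.
#' @param select_features Apply the t-test feature screen?
#' @param alpha Screening level.
#' @return Object of class `eeg_ensemble`.
#' @seealso [predict.eeg_ensemble()], [crossvalidate()]
#' @export
train_ensemble <- function(features, labels,
                           members = c("mlp", "knn", "bayes"),
                           seed = 1L, knn_k = 20L, hidden = 10L,
                           svm_kernel = NULL, select_features = TRUE,
                           alpha = 0.05) {
  members <- match.arg(members, c("mlp", "knn", "bayes", "svm"),
                       several.ok = TRUE)
  x <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2L) stop_eegclean("training data must contain >= 2 classes")
  if ("knn" %in% members && nrow(x) < knn_k)
    stop_eegclean("KNN needs at least K = ", knn_k,
                  " training samples; use a smaller 'knn_k'")
  mask <- if (select_features) ttest_select(x, y, alpha = alpha)
          else rep(TRUE, ncol(x))
  if (!any(mask)) mask[] <- TRUE   # never train on an empty feature set
  xs <- x[, mask, drop = FALSE]
  center <- colMeans(xs)
  scale_ <- apply(xs, 2L, stats::sd)
  scale_[scale_ == 0] <- 1
  xz <- sweep(sweep(xs, 2L, center), 2L, scale_, "/")
  if (is.null(svm_kernel))
    svm_kernel <- if (length(members) >= 4L) "polynomial" else "linear"
  fits <- list()
  if ("mlp" %in% members) {
    fits$mlp <- with_seed(seed, nnet::nnet(
      xz, nnet::class.ind(y), size = hidden, softmax = TRUE,
      decay = 1e-4, maxit = 500L, trace = FALSE, MaxNWts = 5000L))
  }
  if ("knn" %in% members) fits$knn <- list(x = xz, y = y, k = as.integer(knn_k))
  if ("bayes" %in% members) fits$bayes <- gauss_nb_fit(xz, y)
  if ("svm" %in% members) {
    fits$svm <- with_seed(child_seed(seed, 7), e1071::svm(
      xz, y, kernel = svm_kernel, degree = 3L, scale = FALSE))
  }
  structure(list(members = members, fits = fits, mask = mask,
                 center = center, scale = scale_, levels = levels(y),
                 svm_kernel = svm_kernel, seed = seed),
            class = "eeg_ensemble")
}

#' @export
print.eeg_ensemble <- function(x, ...) {
  cat("<eeg_ensemble>", paste(toupper(x$members), collapse = " + "),
      sprintf("(%d-class: %s)\n", length(x$levels),
              paste(x$levels, collapse = ", ")))
  cat(sprintf("features kept by t-test screen: %d of %d; SVM kernel: %s\n",
              sum(x$mask), length(x$mask),
              if ("svm" %in% x$members) x$svm_kernel else "none"))
  invisible(x)
}

## Majority vote with the reference tie-breaks: a four-member tie goes to the
## SVM's vote; a three-member multiclass tie follows the fixed member
## priority bayes > knn > mlp.
resolve_votes <- function(votes, levels) {
  stopifnot(is.character(votes), !is.null(names(votes)))
  tab <- table(factor(votes, levels = levels))
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  if ("svm" %in% names(votes)) return(unname(votes[["svm"]]))
  for (m in c("bayes", "knn", "mlp"))
    if (m %in% names(votes) && votes[[m]] %in% top)
      return(unname(votes[[m]]))
  top[1L]
}

#' Predict source classes with the ensemble
#'
#' Each member votes; the plurality label wins. In the four-member mixture a
#' tie is resolved by the SVM's vote; in the three-member mixture multiclass
#' ties follow the fixed priority Bayes > KNN > MLP (a three-member binary
#' vote cannot tie).
#'
#' @param object An `eeg_ensemble` from [train_ensemble()].
#' @param newdata Samples-by-features matrix (the full 12-column feature
#'   matrix; the stored mask is applied internally).
#' @param type `"class"` for the fused label, `"votes"` for the per-member
#'   vote matrix.
#' @param ... Unused.
#' @return Factor of predicted labels, or a character matrix of votes.
#' @export
predict.eeg_ensemble <- function(object, newdata, type = c("class", "votes"),
                                 ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (is.null(dim(x)) || ncol(x) == 1L && length(object$mask) > 1L)
    x <- matrix(x, nrow = 1L)
  xz <- sweep(sweep(x[, object$mask, drop = FALSE], 2L, object$center),
              2L, object$scale, "/")
  votes <- matrix(NA_character_, nrow(xz), length(object$members),
                  dimnames = list(NULL, object$members))
  for (m in object$members) {
    votes[, m] <- switch(m,
      mlp = {
        pr <- stats::predict(object$fits$mlp, xz)
        object$levels[max.col(pr, ties.method = "first")]
      },
      knn = as.character(with_seed(object$seed, class::knn(
        object$fits$knn$x, xz, object$fits$knn$y, k = object$fits$knn$k))),
      bayes = as.character(gauss_nb_predict(object$fits$bayes, xz)),
      svm = as.character(stats::predict(object$fits$svm, xz)))
  }
  if (type == "votes") return(votes)
  fused <- apply(votes, 1L, function(v) {
    names(v) <- object$members
    resolve_votes(v, object$levels)
  })
  factor(fused, levels = object$levels)
}

## Pooled confusion-matrix metrics, in percent. Binary: the positive class
## is "artifactual"; multiclass: macro-averaged one-vs-rest.
confusion_metrics <- function(truth, pred, positive = "artifactual") {
  truth <- as.factor(truth)
  pred <- factor(pred, levels = levels(truth))
  acc <- 100 * mean(pred == truth)
  lv <- levels(truth)
  if (length(lv) == 2L && positive %in% lv) lv <- positive
  per_class <- vapply(lv, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    c(sen = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      spc = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
      per = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_)
  }, numeric(3L))
  c(Acc = acc,
    Sen = mean(per_class["sen", ], na.rm = TRUE),
    Spc = mean(per_class["spc", ], na.rm = TRUE),
    Per = mean(per_class["per", ], na.rm = TRUE))
}

#' Stratified k-fold cross-validation of the ensemble
#'
#' Splits every class evenly across `k` folds, then refits the full training
#' path inside each fold: the t-test feature mask and z-scoring statistics
#' are recomputed from the training fold only, the members are retrained,
#' and accuracy, sensitivity, specificity and precision are computed on the
#' held-out fold. In the binary task the positive class is `artifactual`;
#' in the six-class task the per-class rates are macro-averaged one-vs-rest.
#'
#' @param features Samples-by-features matrix.
#' @param labels Class labels.
#' @param members Ensemble members, as in [train_ensemble()].
#' @param k Number of folds.
#' @param seed Seed controlling fold assignment and member initialization.
#' @param ... Passed to [train_ensemble()].
#' @return Object of class `cv_metrics`: a list with `folds` (k x 4 matrix
#'   of per-fold percentages), `mean`, `sd`, `members` and `n`.
#' @export
crossvalidate <- function(features, labels, members = c("mlp", "knn", "bayes"),
                          k = 10L, seed = 1L, ...) {
  x <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (min(table(y)) < k)
    stop_eegclean("the smallest class has ", min(table(y)),
                  " samples; use k <= that (stratified folds)")
  fold <- integer(nrow(x))
  with_seed(seed, for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  res <- t(vapply(seq_len(k), function(f) {
    tr <- fold != f
    mdl <- train_ensemble(x[tr, , drop = FALSE], y[tr], members = members,
                          seed = child_seed(seed, f), ...)
    pred <- stats::predict(mdl, x[!tr, , drop = FALSE])
    confusion_metrics(y[!tr], pred)
  }, numeric(4L)))
  structure(list(folds = res, mean = colMeans(res),
                 sd = apply(res, 2L, stats::sd),
                 members = members, n = nrow(x), k = k,
                 levels = levels(y), seed = seed),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("<cv_metrics> %d-fold CV, %s, n = %d (%d-class)\n",
              x$k, paste(toupper(x$members), collapse = " + "), x$n,
              length(x$levels)))
  for (m in colnames(x$folds))
    cat(sprintf("  %s %6.2f +/- %.2f %%\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Ground-truth labels for sources estimated from a simulated scene
#'
#' Labels each estimated source with the class of the ground-truth waveform
#' (artifact waveforms and pure-EEG channels) attaining the largest absolute
#' Pearson correlation; when no ground-truth waveform reaches `threshold`
#' the source is labeled `EEG` (dominant background).
#'
#' @param sources Estimated sources matrix (`n_sources x n_samples`) or a
#'   `sobi` object.
#' @param scene The generating [build_scene()] scene.
#' @param threshold Minimum absolute correlation for an artifact label.
#' @return Factor with levels `EEG` plus the scene's artifact kinds; the
#'   matched correlations are attached as attribute `"max_r"`.
#' @export
label_sources <- function(sources, scene, threshold = 0.3) {
  if (inherits(sources, "sobi")) sources <- sources$sources
  sources <- as.matrix(sources)
  stopifnot(inherits(scene, "eeg_scene"))
  if (ncol(sources) != ncol(scene$pure))
    stop_eegclean("source length does not match the scene")
  truth <- rbind(do.call(rbind, scene$waveforms), scene$pure)
  truth_labels <- c(names(scene$waveforms),
                    rep("EEG", nrow(scene$pure)))
  r <- abs(stats::cor(t(sources), t(truth)))
  r[!is.finite(r)] <- 0
  best <- max.col(r, ties.method = "first")
  max_r <- r[cbind(seq_len(nrow(r)), best)]
  lab <- truth_labels[best]
  lab[max_r < threshold] <- "EEG"
  out <- factor(lab, levels = c("EEG", names(scene$waveforms)))
  attr(out, "max_r") <- max_r
  out
}

#' Collapse six-class source labels to the binary task
#'
#' @param labels Factor of six-class labels (`EEG` is the neural class).
#' @return Factor with levels `neural`, `artifactual`.
#' @export
binary_labels <- function(labels) {
  factor(ifelse(as.character(labels) == "EEG", "neural", "artifactual"),
         levels = c("neural", "artifactual"))
}
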