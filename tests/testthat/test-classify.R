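test_that("component normalization maps exactly onto [-1, 1]", {
  expect_equal(normalize_component(c(0, 5, 10)), c(-1, 0, 1))
  expect_equal(normalize_component(c(-1, 0.2, 1)), c(-1, 0.2, 1))
  expect_equal(normalize_component(c(-3, -1)), c(-1, 1))
  expect_warning(z <- normalize_component(rep(4, 5)), "constant")
  expect_equal(z, rep(0, 5))
})

test_that("the t-test screen is calibrated at its nominal level under the null", {
  set.seed(30)
  g <- factor(rep(c("a", "b"), each = 200))
  hits <- 0L; total <- 0L
  for (rep in 1:1000) {
    X <- matrix(rnorm(400 * 12), 400)
    hits <- hits + sum(ttest_select(X, g))
    total <- total + 12L
  }
  rate <- hits / total
  band <- 2 * sqrt(0.05 * 0.95 / total)
  expect_lt(abs(rate - 0.05), band + 0.002)
})

test_that("the t-test screen detects a strong mean shift essentially always", {
  set.seed(31)
  g <- factor(rep(c("a", "b"), each = 100))
  sel <- vapply(1:200, function(i) {
    X <- cbind(c(rnorm(100), rnorm(100, 2)), matrix(rnorm(200 * 11), 200))
    ttest_select(X, g)[1]
  }, logical(1))
  expect_gt(mean(sel), 0.99)
})

test_that("screening masks are data-dependent (refit per training set)", {
  set.seed(32)
  g <- factor(rep(c("a", "b"), each = 60))
  X1 <- cbind(c(rnorm(60), rnorm(60, 1.5)), matrix(rnorm(120 * 11), 120))
  X2 <- matrix(rnorm(120 * 12), 120)
  m1 <- ttest_select(X1, g); m2 <- ttest_select(X2, g)
  expect_true(m1[1])
  expect_false(identical(unclass(m1), unclass(m2)))
  mdl <- train_ensemble(X1, g, seed = 1)
  expect_identical(unname(mdl$mask), unname(unclass(m1)))
})

test_that("every member separates wide-margin blobs perfectly at training time", {
  set.seed(33)
  n <- 40
  X <- rbind(matrix(rnorm(n * 12, 0, 0.1), n),
             matrix(rnorm(n * 12, 5, 0.1), n))
  y <- factor(rep(c("neural", "artifactual"), each = n))
  mdl <- train_ensemble(X, y, members = c("mlp", "knn", "bayes", "svm"),
                        seed = 2, knn_k = 20)
  votes <- predict(mdl, X, type = "votes")
  for (m in colnames(votes))
    expect_identical(unname(votes[, m]), as.character(y))
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  set.seed(34)
  accs <- vapply(1:10, function(i) {
    X <- matrix(rnorm(120 * 12), 120)
    y <- factor(rep(c("neural", "artifactual"), each = 60))
    cv <- crossvalidate(X, y, k = 5, seed = i)
    cv$mean["Acc"]
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 3 * sd(accs))
})

test_that("training is deterministic under a fixed seed", {
  set.seed(35)
  X <- matrix(rnorm(100 * 12), 100)
  y <- factor(rep(c("neural", "artifactual"), each = 50))
  Xt <- matrix(rnorm(30 * 12), 30)
  m1 <- train_ensemble(X, y, seed = 9)
  m2 <- train_ensemble(X, y, seed = 9)
  expect_identical(predict(m1, Xt), predict(m2, Xt))
})

test_that("KNN refuses training sets smaller than its neighborhood", {
  X <- matrix(rnorm(10 * 12), 10)
  y <- factor(rep(c("a", "b"), each = 5))
  expect_error(train_ensemble(X, y, seed = 1), "smaller")
})

test_that("vote fusion follows the documented tie-breaks", {
  lv <- c("EEG", "ECG", "EMG", "EOG", "blink", "white_noise")
  res <- eegclean:::resolve_votes
  ## unanimity
  expect_identical(res(c(mlp = "blink", knn = "blink", bayes = "blink"), lv),
                   "blink")
  ## four-member tie goes to the SVM
  expect_identical(res(c(mlp = "EEG", knn = "EMG", bayes = "EEG",
                         svm = "EMG"), lv), "EMG")
  ## three-member multiclass tie: fixed priority Bayes > KNN > MLP
  expect_identical(res(c(mlp = "EEG", knn = "EMG", bayes = "EOG"), lv), "EOG")
  ## plurality without tie
  expect_identical(res(c(mlp = "EEG", knn = "EMG", bayes = "EEG", svm = "EMG",
                         extra = "EEG"), lv), "EEG")
})

test_that("a three-member binary vote cannot tie", {
  votes <- expand.grid(mlp = c("a", "b"), knn = c("a", "b"),
                       bayes = c("a", "b"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(votes))) {
    v <- unlist(votes[i, ])
    tab <- table(v)
    expect_false(length(tab) == 2 && tab[1] == tab[2])
  }
})

test_that("fold metrics reproduce the confusion-matrix formulas", {
  truth <- factor(rep(c("artifactual", "neural"), c(50, 50)),
                  levels = c("neural", "artifactual"))
  pred <- truth
  pred[1:5] <- "neural"      # 5 false negatives  (TP = 45)
  pred[51:60] <- "artifactual"  # 10 false positives (TN = 40)
  m <- eegclean:::confusion_metrics(truth, pred)
  expect_equal(unname(m["Acc"]), 85)
  expect_equal(unname(m["Sen"]), 90)
  expect_equal(unname(m["Spc"]), 80)
  expect_equal(unname(m["Per"]), 100 * 45 / 55, tolerance = 1e-6)
  perf <- eegclean:::confusion_metrics(truth, truth)
  expect_equal(unname(perf), c(100, 100, 100, 100))
})

test_that("cross-validated metrics agree with a pooled recount oracle", {
  set.seed(36)
  n <- 60
  X <- rbind(matrix(rnorm(n * 12, 0, 1), n), matrix(rnorm(n * 12, 1.5, 1), n))
  y <- factor(rep(c("neural", "artifactual"), each = n))
  k <- 5
  cv <- crossvalidate(X, y, members = c("knn", "bayes", "mlp"), k = k,
                      seed = 4)
  ## recount: rebuild the folds and predictions independently
  fold <- integer(2 * n)
  eegclean:::with_seed(4, for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  accs <- vapply(seq_len(k), function(f) {
    mdl <- train_ensemble(X[fold != f, ], y[fold != f],
                          members = c("knn", "bayes", "mlp"),
                          seed = eegclean:::child_seed(4, f))
    mean(predict(mdl, X[fold == f, ]) == y[fold == f]) * 100
  }, numeric(1))
  expect_equal(unname(cv$folds[, "Acc"]), accs)
  expect_equal(unname(cv$mean["Acc"]), mean(accs))
})

test_that("label noise cannot improve cross-validated accuracy", {
  set.seed(37)
  diffs <- vapply(1:10, function(i) {
    n <- 50
    X <- rbind(matrix(rnorm(n * 12, 0, 1), n),
               matrix(rnorm(n * 12, 2, 1), n))
    y <- factor(rep(c("neural", "artifactual"), each = n))
    yn <- y
    flip <- sample(2 * n, 20)
    yn[flip] <- rev(levels(y))[as.integer(y[flip])]
    clean <- crossvalidate(X, y, members = c("knn", "bayes"), k = 5,
                           seed = i)$mean["Acc"]
    noisy <- crossvalidate(X, yn, members = c("knn", "bayes"), k = 5,
                           seed = i)$mean["Acc"]
    noisy - clean
  }, numeric(1))
  expect_lt(mean(diffs), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("simulated sources are labeled by best ground-truth correlation", {
  sc <- build_scene(sim_config(duration = 4, seed = 40))
  kinds <- names(sc$waveforms)
  ## permuted, sign-flipped, rescaled true waveforms are recovered exactly
  perm <- c(3, 1, 5, 2, 4)
  S <- do.call(rbind, lapply(sc$waveforms[perm], function(w) -2.5 * w))
  labs <- label_sources(S, sc)
  expect_identical(as.character(labs), kinds[perm])
  ## an exact copy of the blink waveform is labeled blink
  expect_identical(as.character(label_sources(matrix(sc$waveforms$blink, 1),
                                              sc)), "blink")
  ## uncorrelated noise falls back to the EEG label
  set.seed(41)
  noise <- matrix(rnorm(ncol(sc$pure)), 1)
  lab <- label_sources(noise, sc)
  expect_identical(as.character(lab), "EEG")
  expect_lt(attr(lab, "max_r"), 0.3)
  expect_error(label_sources(matrix(rnorm(10), 1), sc), "length")
})
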