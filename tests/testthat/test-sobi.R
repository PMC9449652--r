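test_that("whitening yields identity covariance and zero-mean rows", {
  set.seed(10)
  x <- rbind(2 * rnorm(4000) + 5, 3 * rnorm(4000) - 2)  # cov ~ diag(4, 9)
  w <- zero_mean_whiten(eeg_recording(x, fs = 256))
  expect_lt(max(abs(rowMeans(w$whitened))), 1e-12)
  C <- tcrossprod(w$whitened) / ncol(x)
  expect_lt(max(abs(C - diag(2))), 1e-8)
})

test_that("whitening an already-white input gives an orthogonal whitener", {
  set.seed(11)
  x <- matrix(rnorm(3 * 3000), 3)
  xw <- zero_mean_whiten(eeg_recording(x, fs = 100))$whitened
  w2 <- zero_mean_whiten(eeg_recording(xw, fs = 100))$whitener
  expect_lt(max(abs(crossprod(w2) - diag(3))), 1e-8)
})

test_that("rank-deficient input raises a singular-input error naming channels", {
  set.seed(12)
  ch <- rnorm(500)
  rec <- eeg_recording(rbind(ch, ch, rnorm(500)), fs = 100,
                       channel_names = c("Fp1", "Fp2", "Cz"))
  expect_error(zero_mean_whiten(rec), "singular")
  expect_error(sobi(rec, lags = 1:5), "singular")
})

test_that("lagged covariance matches its defining properties", {
  set.seed(13)
  x <- matrix(rnorm(2 * 4000), 2)
  xw <- zero_mean_whiten(eeg_recording(x, fs = 256))$whitened
  expect_lt(max(abs(lagged_covariance(xw, 0) - diag(2))), 1e-8)
  ## long i.i.d. noise decorrelates at positive lags
  R5 <- lagged_covariance(xw, 5)
  expect_lt(max(abs(R5)), 5 / sqrt(4000))
  expect_identical(R5, t(R5))
  ## a sinusoid is perfectly autocorrelated at its period
  per <- 32L
  s <- matrix(sin(2 * pi * (1:6400) / per), 1)
  s2 <- rbind(s, cos(2 * pi * (1:6400) / per))
  Rp <- lagged_covariance(s2, per)
  R0 <- lagged_covariance(s2, 0)
  expect_equal(diag(Rp), diag(R0), tolerance = 1e-2)
  expect_error(lagged_covariance(xw, ncol(xw)), "lag")
})

test_that("joint diagonalization recovers a planted rotation", {
  th <- 30 * pi / 180
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mats <- list(Q %*% diag(c(1, 2)) %*% t(Q), Q %*% diag(c(3, 1)) %*% t(Q))
  V <- joint_diagonalize(mats)
  ## columns match Q up to permutation and sign
  M <- abs(crossprod(Q, V))
  expect_lt(max(abs(M - diag(2)[, max.col(t(M))])), 1e-8)
  off <- sum(vapply(mats, function(m) {
    D <- t(V) %*% m %*% V; sum((D - diag(diag(D)))^2)
  }, numeric(1)))
  expect_lt(off, 1e-8)
})

test_that("joint diagonalization of diagonal inputs leaves them untouched", {
  V <- joint_diagonalize(list(diag(c(1, 2, 3)), diag(c(3, 1, 0.5))))
  expect_lt(max(abs(abs(V) - diag(3))), 1e-10)  # identity up to sign
})

test_that("a single matrix is diagonalized by its eigenvectors", {
  set.seed(14)
  A <- crossprod(matrix(rnorm(16), 4))
  V <- joint_diagonalize(list(A))
  E <- eigen(A, symmetric = TRUE)$vectors
  M <- abs(crossprod(E, V))           # permutation matrix up to sign
  expect_equal(sort(apply(M, 2, max)), rep(1, 4), tolerance = 1e-6)
  expect_lt(max(abs(crossprod(V) - diag(4))), 1e-10)
})

test_that("joint diagonalization validates its inputs", {
  expect_error(joint_diagonalize(list()), "empty")
  expect_error(joint_diagonalize(list(matrix(1:4, 2))), "symmetric")
})

test_that("sobi unmixes a two-sinusoid mixture", {
  t <- seq(1, 4 * 256) / 256
  S <- rbind(sin(2 * pi * 5 * t), sin(2 * pi * 11 * t))
  A <- matrix(c(1, 0.4, 0.5, 1), 2)
  dec <- sobi(eeg_recording(A %*% S, fs = 256), lags = 1:20)
  r <- abs(cor(t(dec$sources), t(S)))
  expect_gt(min(apply(r, 1, max)), 0.99)
  ## reconstruction identity on the zero-meaned input
  X0 <- A %*% S - rowMeans(A %*% S)
  rel <- norm(dec$mixing %*% dec$sources - X0, "F") / norm(X0, "F")
  expect_lt(rel, 1e-6)
  expect_lt(max(abs(dec$unmixing %*% dec$mixing - diag(2))), 1e-8)
})

test_that("identity mixing returns the channels up to permutation/sign/scale", {
  set.seed(15)
  t <- seq(1, 2048) / 256
  X <- rbind(sin(2 * pi * 6 * t), sin(2 * pi * 17 * t), sin(2 * pi * 29 * t))
  dec <- sobi(eeg_recording(X, fs = 256), lags = 1:20)
  r <- abs(cor(t(dec$sources), t(X)))
  expect_gt(min(apply(r, 1, max)), 0.999)
})

test_that("sobi recovers well-separated narrowband sources across seeded trials", {
  rs <- vapply(1:100, function(i) {
    set.seed(i)
    k <- sample(2:6, 1)
    t <- seq(1, 1024) / 256
    freqs <- seq(4, 60, length.out = 6)[seq_len(k)] + runif(k, -1, 1)
    S <- t(sapply(freqs, function(f) sin(2 * pi * f * t + runif(1, 0, 2 * pi))))
    A <- matrix(rnorm(k * k), k)
    dec <- sobi(eeg_recording(A %*% S, fs = 256), lags = 1:30)
    r <- abs(cor(t(dec$sources), t(S)))
    mean(apply(r, 2, max))
  }, numeric(1))
  expect_gt(mean(rs), 0.95)
})

test_that("sobi rejects invalid lag sets", {
  x <- eeg_recording(matrix(rnorm(2 * 100), 2), fs = 10)
  expect_error(sobi(x, lags = c(0, 1)), "positive")
  expect_error(sobi(x, lags = c(5, 3)), "increasing")
  expect_error(sobi(x, lags = c(1, 100)), "lag")
})
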