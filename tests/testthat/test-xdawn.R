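# A tiny hand-made schedule for design-matrix tests.
toy_schedule <- function(onsets, is_target = rep(TRUE, length(onsets))) {
  ev <- data.frame(onset_s = onsets / 100, onset_sample = as.integer(onsets),
                   stim_id = rep_len(c("R0", "C0"), length(onsets)),
                   is_target = is_target,
                   char_index = 1L, repetition = seq_along(onsets))
  structure(list(events = ev, timing = training_timing(), targets = "A",
                 fs = 100), class = "flash_schedule")
}

test_that("toeplitz design places ones at post-onset lags", {
  D <- build_toeplitz(toy_schedule(0), n_samples = 5, epoch_len = 3)
  expect_equal(dim(D), c(5, 3))
  expect_equal(as.matrix(D)[cbind(1:3, 1:3)], rep(1, 3))
  expect_equal(sum(D), 3)
  # two non-overlapping events: every lag covered twice
  D2 <- build_toeplitz(toy_schedule(c(0, 10)), 20, 3)
  expect_equal(Matrix::colSums(D2), rep(2, 3), ignore_attr = TRUE)
})

test_that("overlapping events superpose linearly", {
  D <- build_toeplitz(toy_schedule(c(0, 2)), 10, 4)
  expect_true(any(Matrix::rowSums(D) > 1))
  A <- matrix(c(1, 2, 3, 4), 4, 1)
  direct <- numeric(10)
  for (on in c(0, 2)) direct[on + 1:4] <- direct[on + 1:4] + A[, 1]
  expect_equal(as.numeric(D %*% A), direct)
})

test_that("trailing epochs overrunning the recording are truncated", {
  expect_message(D <- build_toeplitz(toy_schedule(c(0, 8)), 10, 4),
                 "truncated")
  expect_equal(sum(D[, 3]), 1)   # second event lost lags 2,3
  expect_equal(sum(D[, 4]), 1)
})

test_that("the evoked response is recovered exactly from noise-free data", {
  set.seed(5)
  sch <- toy_schedule(c(0, 10, 25, 40))
  A <- matrix(rnorm(5 * 3), 5, 3)
  D <- build_toeplitz(sch, 50, 5)
  X <- as.matrix(D %*% A)
  expect_equal(estimate_erp(X, D), A, tolerance = 1e-12)
})

test_that("erp estimation error shrinks with more events", {
  set.seed(6)
  A <- matrix(rnorm(5 * 2), 5, 2)
  err <- sapply(c(10, 160), function(n_ev) {
    on <- seq(0, by = 8, length.out = n_ev)
    sch <- toy_schedule(on)
    D <- build_toeplitz(sch, max(on) + 10, 5)
    X <- as.matrix(D %*% A) + matrix(rnorm(nrow(D) * 2), ncol = 2)
    sqrt(mean((estimate_erp(X, D) - A)^2))
  })
  expect_lt(err[2], err[1] / 2)  # ~1/sqrt(16) expected
})

test_that("rank-deficient designs are reported with the deficient lags", {
  D <- suppressMessages(build_toeplitz(toy_schedule(0), 2, 4))
  expect_error(estimate_erp(matrix(0, 2, 1), D), "deficient")
})

test_that("fit_xdawn matches a dense generalized-eigenproblem oracle", {
  # 4 channels, short recording: oracle = eigen(solve(den) %*% num)
  set.seed(8)
  on <- seq(0, by = 12, length.out = 15)
  sch <- toy_schedule(on)
  n <- 200; n_ch <- 4; len <- 8
  A <- matrix(rnorm(len * n_ch), len, n_ch)
  D <- build_toeplitz(sch, n, len)
  X <- as.matrix(D %*% A) + 0.5 * matrix(rnorm(n * n_ch), n, n_ch)
  fit <- fit_xdawn(X, sch, epoch_len = len, k = 4)
  A_hat <- estimate_erp(X, D)
  S <- as.matrix(D %*% A_hat)
  num <- crossprod(S) / n; den <- crossprod(X) / n
  oracle <- eigen(solve(den) %*% num)
  expect_equal(fit$ssnr, sort(Re(oracle$values), decreasing = TRUE),
               tolerance = 1e-8)
  for (j in 1:4) {
    u <- fit$U[, j]; v <- Re(oracle$vectors[, j])
    expect_equal(abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)), 1,
                 tolerance = 1e-8)
  }
  expect_true(all(diff(fit$ssnr) <= 1e-12))
})

test_that("the top filter maximizes the SSNR quotient", {
  sp <- small_pipeline()
  X <- t(sp$dec$data)
  top <- ssnr_quotient(sp$xd$U[, 1, drop = FALSE], X, sp$dec$markers, 62)
  set.seed(17)
  V <- matrix(rnorm(ncol(X) * 1000), ncol(X))
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  rand <- ssnr_quotient(V, X, sp$dec$markers, 62)
  expect_true(all(top >= rand))
  expect_equal(as.numeric(top), sp$xd$ssnr[1], tolerance = 1e-10)
  # stationarity: small perturbations never increase the quotient
  set.seed(18)
  for (i in 1:25) {
    d <- rnorm(ncol(X)); d <- d / sqrt(sum(d^2))
    u2 <- sp$xd$U[, 1] + 1e-4 * d * sqrt(sum(sp$xd$U[, 1]^2))
    q2 <- ssnr_quotient(matrix(u2), X, sp$dec$markers, 62)
    expect_lte(as.numeric(q2), sp$xd$ssnr[1] * (1 + 1e-6))
  }
})

test_that("SSNR values are invariant to joint orthonormal channel rotation", {
  set.seed(9)
  on <- seq(0, by = 12, length.out = 20)
  sch <- toy_schedule(on)
  n <- 260; n_ch <- 4; len <- 6
  A <- matrix(rnorm(len * n_ch), len, n_ch)
  D <- build_toeplitz(sch, n, len)
  X <- as.matrix(D %*% A) + 0.3 * matrix(rnorm(n * n_ch), n, n_ch)
  Q <- qr.Q(qr(matrix(rnorm(n_ch^2), n_ch)))
  f1 <- fit_xdawn(X, sch, len, k = n_ch)
  f2 <- fit_xdawn(X %*% Q, sch, len, k = n_ch)
  expect_equal(f1$ssnr, f2$ssnr, tolerance = 1e-9)
})

test_that("planted spatial pattern is recovered by the top filter", {
  fp <- full_pipeline()
  pattern <- full_session()$truth$spatial_pattern
  # map the filter to pattern space through the total covariance
  X <- t(fp$dec$data)
  fwd <- crossprod(X) %*% fp$xd$U[, 1]
  cosim <- abs(sum(fwd * pattern)) / sqrt(sum(fwd^2) * sum(pattern^2))
  expect_gte(cosim, 0.95)
})

test_that("full-rank projection is lossless", {
  sp <- small_pipeline()
  xd_full <- fit_xdawn(t(sp$dec$data), sp$dec$markers, 62,
                       k = nrow(sp$dec$data))
  expect_gt(abs(det(xd_full$U)), 0)
  ep1 <- sp$ep$epochs[1, , ]
  feats <- apply_xdawn(xd_full, sp$ep)
  k <- nrow(sp$dec$data)
  proj <- matrix(feats[1, ], nrow = k, byrow = TRUE)
  expect_equal(solve(t(xd_full$U)) %*% proj, ep1, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("apply_xdawn is linear and shape-checked", {
  sp <- small_pipeline()
  n_ch <- dim(sp$ep$epochs)[2]
  U_id <- diag(n_ch)[, 1:3]
  xd_id <- sp$xd; xd_id$U <- U_id
  feats <- apply_xdawn(xd_id, sp$ep)
  expect_equal(feats[5, 1:62], sp$ep$epochs[5, 1, ])   # raw channel 1
  sc <- sp$ep; sc$epochs <- sc$epochs * 3
  expect_equal(apply_xdawn(sp$xd, sc), 3 * apply_xdawn(sp$xd, sp$ep))
  bad <- sp$ep; bad$epochs <- bad$epochs[, 1:4, , drop = FALSE]
  expect_error(apply_xdawn(sp$xd, bad), "channels")
})
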