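two_blobs <- function(n = 60, d = 4, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * d), ncol = d),
             matrix(rnorm(n / 2 * d, mean = sep / sqrt(d)), ncol = d))
  list(X = X, y = rep(c(-1, 1), each = n / 2))
}

test_that("LDA separates distant spherical clouds perfectly", {
  b <- two_blobs()
  m <- fit_lda(b$X, b$y)
  expect_equal(mean((predict_score(m, b$X) > 0) == (b$y > 0)), 1)
  expect_identical(levels(predict_label(m, b$X)), c("NoTarget", "Target"))
})

test_that("the LDA direction maximizes the Fisher quotient", {
  sp <- small_pipeline()
  m <- fit_lda(sp$feats, sp$ep$labels)
  J_fit <- p300speller:::lda_quotient(m$v, m$S_b, m$S_w)
  set.seed(2)
  for (i in 1:1000) {
    v <- rnorm(length(m$v))
    expect_lte(p300speller:::lda_quotient(v, m$S_b, m$S_w), J_fit * (1 + 1e-9))
  }
  expect_equal(J_fit, m$J, tolerance = 1e-10)
})

test_that("LDA direction agrees with an established reference", {
  skip_if_not_installed("MASS")
  b <- two_blobs(n = 200, sep = 4, seed = 3)
  m <- fit_lda(b$X, b$y, shrinkage = 0)
  ref <- MASS::lda(b$X, grouping = factor(b$y))
  v_ref <- as.numeric(ref$scaling)
  cosim <- abs(sum(m$v * v_ref)) / sqrt(sum(m$v^2) * sum(v_ref^2))
  expect_gte(cosim, 1 - 1e-8)
})

test_that("label swap flips the LDA direction, not its quotient", {
  b <- two_blobs(seed = 4)
  m1 <- fit_lda(b$X, b$y)
  m2 <- fit_lda(b$X, -b$y)
  expect_equal(m1$v, -m2$v, tolerance = 1e-10)
  expect_equal(m1$J, m2$J, tolerance = 1e-10)
  expect_error(fit_lda(b$X, rep(1, nrow(b$X))), "both classes")
})

test_that("adding the LDA direction to features raises the score linearly", {
  b <- two_blobs()
  m <- fit_lda(b$X, b$y)
  x <- b$X[1, , drop = FALSE]
  c0 <- 2.5
  expect_equal(predict_score(m, x + c0 * rep(m$v, each = 1)) -
                 predict_score(m, x),
               c0 * sum(m$v^2), tolerance = 1e-10)
})

test_that("the cubic kernel solves XOR with hard margins", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- c(-1, 1, 1, -1)
  m <- fit_svm(X, y, C = 1e4, tol = 1e-8, class_weight = NULL, scale = FALSE)
  expect_true(all(y * predict_score(m, X) >= 1 - 1e-6))
  expect_identical(as.character(predict_label(m, X)),
                   ifelse(y > 0, "Target", "NoTarget"))
})

test_that("SVM dual feasibility holds after fitting", {
  sp <- small_pipeline()
  m <- fit_svm(sp$feats, sp$ep$labels)
  expect_true(all(m$alpha >= 0))
  expect_true(all(m$alpha <= m$C_i + 1e-8))
  expect_lt(abs(sum(m$alpha * m$sv_y)), 1e-6)
  expect_lt(m$kkt_gap, 1e-4)
})

test_that("free support vectors sit on the margin", {
  b <- two_blobs(n = 100, sep = 4, seed = 5)
  m <- fit_svm(b$X, b$y, C = 1, tol = 1e-6, class_weight = NULL,
               scale = FALSE)
  free <- m$alpha > 1e-6 & m$alpha < m$C_i - 1e-6
  expect_true(any(free))
  margins <- m$sv_y * predict_score(m, m$sv_x)
  expect_true(all(abs(margins[free] - 1) < 1e-3))
})

test_that("duplicating training points leaves the decision unchanged", {
  b <- two_blobs(n = 40, sep = 6, seed = 6)
  m1 <- fit_svm(b$X, b$y, C = 1, tol = 1e-6, class_weight = NULL,
                scale = FALSE)
  m2 <- fit_svm(rbind(b$X, b$X), c(b$y, b$y), C = 1, tol = 1e-6,
                class_weight = NULL, scale = FALSE)
  grid_pts <- two_blobs(n = 20, sep = 6, seed = 7)$X
  expect_equal(predict_score(m1, grid_pts), predict_score(m2, grid_pts),
               tolerance = 0.05)
})

test_that("tiny C collapses the decision toward a constant", {
  b <- two_blobs(n = 40, sep = 6, seed = 8)
  spread <- sapply(c(1e-6, 1e-9), function(C) {
    m <- fit_svm(b$X, b$y, C = C, class_weight = NULL, scale = FALSE)
    expect_true(all(m$alpha <= C + 1e-12))
    diff(range(predict_score(m, b$X) - m$b))
  })
  # the kernel part of the decision shrinks proportionally with C
  expect_lt(spread[2], 0.01 * spread[1])
})

test_that("SVM decision values match an independent solver", {
  skip_if_not_installed("e1071")
  set.seed(9)
  X <- rbind(matrix(rnorm(100), 50, 2), matrix(rnorm(100, 2), 50, 2))
  y <- rep(c(-1, 1), each = 50)
  m <- fit_svm(X, y, C = 1, tol = 1e-6, class_weight = NULL, scale = FALSE)
  ref <- e1071::svm(X, factor(y), kernel = "polynomial", degree = 3,
                    gamma = 1, coef0 = 1, cost = 1, scale = FALSE)
  dv <- attr(predict(ref, X, decision.values = TRUE), "decision.values")
  sgn <- if (colnames(dv)[1] == "1/-1") 1 else -1
  expect_lt(max(abs(predict_score(m, X) - sgn * as.numeric(dv))), 0.01)
})

test_that("backpropagation gradients match finite differences", {
  set.seed(10)
  X <- matrix(rnorm(12 * 5), 12, 5)
  y01 <- rep(c(0, 1), 6)
  par <- p300speller:::mlp_init(5, c(4, 3))
  lg <- p300speller:::mlp_loss_grad(par, X, y01)
  h <- 1e-6
  for (nm in names(par)) {
    g_num <- par[[nm]]
    for (i in seq_along(g_num)) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - h
      g_num[i] <- (p300speller:::mlp_loss_grad(pp, X, y01)$loss -
                     p300speller:::mlp_loss_grad(pm, X, y01)$loss) / (2 * h)
    }
    denom <- pmax(abs(g_num), abs(lg$grad[[nm]]), 1e-8)
    expect_lt(max(abs(g_num - lg$grad[[nm]]) / denom), 1e-5)
  }
})

test_that("zero-initialized symmetric hidden units stay symmetric", {
  # gradient argument for random init: with all-zero weights every hidden
  # unit receives an identical gradient, so units could never diverge
  set.seed(11)
  X <- matrix(rnorm(20), 10, 2)
  y01 <- rep(c(0, 1), 5)
  par0 <- p300speller:::mlp_init(2, c(4, 3))
  for (nm in names(par0)) par0[[nm]][] <- 0
  g <- p300speller:::mlp_loss_grad(par0, X, y01)$grad
  expect_equal(g$W1, g$W1[, c(1, 1, 1, 1)], ignore_attr = TRUE)
  expect_true(all(g$W2 == 0))
})

test_that("the MLP learns separable blobs", {
  b <- two_blobs(n = 120, sep = 6, seed = 12)
  m <- fit_mlp(b$X, b$y, n_iter = 300, seed = 13)
  expect_gte(mean((predict_score(m, b$X) > 0) == (b$y > 0)), 0.99)
  expect_true(all(diff(m$loss_trace) <= 1e-6))   # non-increasing loss
})

test_that("score dimensions are validated", {
  b <- two_blobs()
  m <- fit_lda(b$X, b$y)
  expect_error(predict_score(m, b$X[, 1:2]), "dimension")
})

test_that("cross-validation is stratified and reproducible", {
  sp <- small_pipeline()
  r1 <- cross_validate(sp$feats, sp$ep$labels, "lda", k = 5, seed = 1)
  r2 <- cross_validate(sp$feats, sp$ep$labels, "lda", k = 5, seed = 1)
  expect_identical(r1$fold_accuracy, r2$fold_accuracy)
  expect_length(r1$fold_accuracy, 5)
  expect_equal(r1$mean, mean(r1$fold_accuracy))
  expect_equal(r1$sd, sd(r1$fold_accuracy))
  expect_gte(r1$mean, 0.9)
  expect_error(cross_validate(sp$feats[1:3, ], sp$ep$labels[1:3], "lda"),
               "at least k")
})

test_that("epoch ordering does not change LDA or SVM scores", {
  sp <- small_pipeline()
  idx <- sample(nrow(sp$feats))
  probe <- sp$feats[1:20, ]
  m1 <- fit_lda(sp$feats, sp$ep$labels)
  m2 <- fit_lda(sp$feats[idx, ], sp$ep$labels[idx])
  expect_equal(predict_score(m1, probe), predict_score(m2, probe),
               tolerance = 1e-6)
})
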