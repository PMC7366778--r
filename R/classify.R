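## Binary Target / NoTarget epoch detectors. All three are trained on the
## xDAWN feature matrix (n_epochs x (k * epoch_samples)) but accept any
## numeric feature matrix. Labels may be given as the epoch_set factor
## (Target/NoTarget), as logicals, or as 0/1; internally Target = +1.

as_binary_labels <- function(y) {
  if (is.factor(y)) return(ifelse(y == "Target", 1, -1))
  if (is.logical(y)) return(ifelse(y, 1, -1))
  u <- sort(unique(y))
  if (all(u %in% c(0, 1))) return(ifelse(y == 1, 1, -1))
  if (all(u %in% c(-1, 1))) return(as.numeric(y))
  stop("labels must be Target/NoTarget, logical, 0/1 or -1/1")
}

#' Fisher linear discriminant detector
#'
#' Maximizes the ratio of between-class to within-class scatter
#' J(v) = (v' S_b v) / (v' S_w v). For two classes the maximizer is
#' v = S_w^{-1} (m_T - m_N), computed with a small shrinkage ridge on S_w
#' (features can outnumber what the within-class scatter supports). The
#' decision threshold sits at the midpoint of the projected class means.
#'
#' @param X Feature matrix, n x d.
#' @param y Labels (Target/NoTarget factor, logical, 0/1 or -1/1).
#' @param shrinkage Relative ridge: \code{eps = shrinkage * tr(S_w) / d}.
#' @return An \code{lda_model}: \code{v} (direction), \code{bias},
#'   \code{J} (attained quotient), class means, and the scatter matrices.
#' @export
fit_lda <- function(X, y, shrinkage = 1e-6) {
  X <- as.matrix(X)
  yb <- as_binary_labels(y)
  if (length(unique(yb)) < 2) stop("both classes must be present")
  m_pos <- colMeans(X[yb > 0, , drop = FALSE])
  m_neg <- colMeans(X[yb < 0, , drop = FALSE])
  Xc <- X
  Xc[yb > 0, ] <- sweep(X[yb > 0, , drop = FALSE], 2, m_pos)
  Xc[yb < 0, ] <- sweep(X[yb < 0, , drop = FALSE], 2, m_neg)
  S_w <- crossprod(Xc)
  d <- ncol(X)
  eps <- shrinkage * sum(diag(S_w)) / d
  diff <- m_pos - m_neg
  v <- solve(S_w + diag(eps, d), diff)
  S_b <- tcrossprod(diff)
  J <- as.numeric((t(v) %*% S_b %*% v) / (t(v) %*% S_w %*% v))
  structure(list(v = as.numeric(v), bias = sum(v * (m_pos + m_neg)) / 2,
                 J = J, mean_target = m_pos, mean_nontarget = m_neg,
                 S_w = S_w, S_b = S_b, shrinkage = shrinkage, dim = d),
            class = "lda_model")
}

# Fisher quotient for arbitrary directions (verification utility).
lda_quotient <- function(v, S_b, S_w) {
  as.numeric((t(v) %*% S_b %*% v) / (t(v) %*% S_w %*% v))
}

polynomial_kernel <- function(A, B, degree = 3, coef0 = 1) {
  (tcrossprod(A, B) + coef0)^degree
}

#' Soft-margin SVM with a cubic polynomial kernel
#'
#' Solves the dual of the soft-margin problem with the kernel
#' K(x, y) = (x'y + 1)^3 by sequential minimal optimization with
#' maximal-violating-pair working-set selection. The box constraint is
#' per-sample: \code{C} times a class weight, by default inversely
#' proportional to class frequency to counter the 1:5 Target/NoTarget
#' imbalance of the speller paradigm. Features are standardized internally
#' (stored in the model) for kernel conditioning.
#'
#' @param X Feature matrix, n x d.
#' @param y Labels.
#' @param C Box constraint (before class weighting).
#' @param degree,coef0 Kernel parameters of \code{(x'y + coef0)^degree}.
#' @param class_weight \code{"balanced"} (n / (2 * class count)) or a
#'   named vector \code{c(Target = ., NoTarget = .)} or NULL (no weighting).
#' @param tol KKT violation tolerance for the stopping rule.
#' @param max_passes Iteration cap, in multiples of n.
#' @param scale Standardize features before the kernel (default TRUE).
#' @return An \code{svm_model}: support vectors, \code{alpha} (>= 0),
#'   \code{sv_y}, \code{b}, kernel parameters, per-sample upper bounds, and
#'   the attained KKT residual.
#' @export
fit_svm <- function(X, y, C = 1, degree = 3, coef0 = 1,
                    class_weight = "balanced", tol = 1e-4,
                    max_passes = 400, scale = TRUE) {
  X <- as.matrix(X)
  yb <- as_binary_labels(y)
  n <- nrow(X)
  if (length(unique(yb)) < 2) stop("both classes must be present")
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (scale) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  w_cls <- c(`1` = 1, `-1` = 1)
  if (identical(class_weight, "balanced")) {
    w_cls <- c(`1` = n / (2 * sum(yb > 0)), `-1` = n / (2 * sum(yb < 0)))
  } else if (!is.null(class_weight) && !identical(class_weight, "none")) {
    w_cls <- c(`1` = unname(class_weight["Target"]),
               `-1` = unname(class_weight["NoTarget"]))
  }
  C_i <- C * ifelse(yb > 0, w_cls["1"], w_cls["-1"])
  K <- polynomial_kernel(X, X, degree, coef0)
  alpha <- rep(0, n)
  f <- rep(0, n)                       # f_i = sum_j alpha_j y_j K_ij
  max_iter <- max_passes * n
  iter <- 0L
  repeat {
    grad <- yb - f                     # -y_i G_i in dual-gradient terms
    up <- (yb > 0 & alpha < C_i - 1e-12) | (yb < 0 & alpha > 1e-12)
    low <- (yb > 0 & alpha > 1e-12) | (yb < 0 & alpha < C_i - 1e-12)
    if (!any(up) || !any(low)) break
    i <- which(up)[which.max(grad[up])]
    j <- which(low)[which.min(grad[low])]
    m_up <- grad[i]; m_low <- grad[j]
    if (m_up - m_low < tol) break
    if (iter >= max_iter)
      stop(sprintf("SMO did not converge: KKT gap %.3g after %d iterations (tol %.1g)",
                   m_up - m_low, iter, tol))
    s <- yb[i] * yb[j]
    if (s < 0) {
      L <- max(0, alpha[j] - alpha[i])
      H <- min(C_i[j], C_i[i] + alpha[j] - alpha[i])
    } else {
      L <- max(0, alpha[i] + alpha[j] - C_i[i])
      H <- min(C_i[j], alpha[i] + alpha[j])
    }
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 1e-12) eta <- 1e-12
    E_i <- f[i] - yb[i]; E_j <- f[j] - yb[j]
    aj_new <- min(max(alpha[j] + yb[j] * (E_i - E_j) / eta, L), H)
    ai_new <- alpha[i] + s * (alpha[j] - aj_new)
    df <- (ai_new - alpha[i]) * yb[i] * K[, i] +
      (aj_new - alpha[j]) * yb[j] * K[, j]
    f <- f + df
    alpha[i] <- ai_new; alpha[j] <- aj_new
    iter <- iter + 1L
  }
  grad <- yb - f
  up <- (yb > 0 & alpha < C_i - 1e-12) | (yb < 0 & alpha > 1e-12)
  low <- (yb > 0 & alpha > 1e-12) | (yb < 0 & alpha < C_i - 1e-12)
  m_up <- if (any(up)) max(grad[up]) else -Inf
  m_low <- if (any(low)) min(grad[low]) else Inf
  b <- if (is.finite(m_up) && is.finite(m_low)) (m_up + m_low) / 2 else 0
  sv <- which(alpha > 1e-10)
  structure(list(sv_x = X[sv, , drop = FALSE], sv_y = yb[sv],
                 alpha = alpha[sv], b = b, C = C, C_i = C_i[sv],
                 degree = degree, coef0 = coef0,
                 center = ctr, scale_sd = scl, scaled = scale,
                 kkt_gap = max(0, m_up - m_low), n_iter = iter,
                 dim = ncol(X)),
            class = "svm_model")
}

#' Two-hidden-layer perceptron detector
#'
#' A multilayer perceptron with two tanh hidden layers and a logistic
#' output, trained by full-batch gradient descent on the cross-entropy
#' loss, with gradients from backpropagation. Inputs are standardized
#' internally; weights start at small seeded uniform values (symmetric
#' zero initialization would leave hidden units identical forever).
#'
#' @param X Feature matrix, n x d.
#' @param y Labels.
#' @param hidden Sizes of the two hidden layers.
#' @param lr Learning rate.
#' @param n_iter Number of full-batch iterations.
#' @param seed Seed for weight initialization.
#' @return An \code{mlp_model}: weight matrices/biases, the standardization
#'   used, and the training-loss trace.
#' @export
fit_mlp <- function(X, y, hidden = c(32, 16), lr = 0.5, n_iter = 500,
                    seed = 1) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in features")
  yb <- as_binary_labels(y)
  y01 <- as.numeric(yb > 0)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  set.seed(as.integer(seed))
  par <- mlp_init(ncol(X), hidden)
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    lg <- mlp_loss_grad(par, Xs, y01)
    if (!is.finite(lg$loss))
      stop("MLP training diverged (non-finite loss); reduce lr")
    trace[it] <- lg$loss
    for (nm in names(par)) par[[nm]] <- par[[nm]] - lr * lg$grad[[nm]]
  }
  structure(list(par = par, hidden = hidden, center = ctr, scale_sd = scl,
                 loss_trace = trace, lr = lr, n_iter = n_iter, seed = seed,
                 dim = ncol(X)),
            class = "mlp_model")
}

mlp_init <- function(d, hidden) {
  r <- function(n_in, n_out) matrix(stats::runif(n_in * n_out, -1, 1) /
                                      sqrt(n_in), n_in, n_out)
  list(W1 = r(d, hidden[1]), b1 = rep(0, hidden[1]),
       W2 = r(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
       W3 = r(hidden[2], 1), b3 = 0)
}

mlp_forward <- function(par, X) {
  Z1 <- sweep(X %*% par$W1, 2, par$b1, "+"); A1 <- tanh(Z1)
  Z2 <- sweep(A1 %*% par$W2, 2, par$b2, "+"); A2 <- tanh(Z2)
  z3 <- A2 %*% par$W3 + par$b3
  p <- 1 / (1 + exp(-z3))
  list(A1 = A1, A2 = A2, p = as.numeric(p))
}

# Cross-entropy loss and backprop gradients; kept separate so the
# gradients can be checked against finite differences.
mlp_loss_grad <- function(par, X, y01) {
  n <- nrow(X)
  fw <- mlp_forward(par, X)
  p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
  loss <- -mean(y01 * log(p) + (1 - y01) * log(1 - p))
  d3 <- matrix((fw$p - y01) / n, ncol = 1)
  gW3 <- crossprod(fw$A2, d3); gb3 <- sum(d3)
  d2 <- (d3 %*% t(par$W3)) * (1 - fw$A2^2)
  gW2 <- crossprod(fw$A1, d2); gb2 <- colSums(d2)
  d1 <- (d2 %*% t(par$W2)) * (1 - fw$A1^2)
  gW1 <- crossprod(X, d1); gb1 <- colSums(d1)
  list(loss = loss,
       grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                   W3 = gW3, b3 = gb3))
}

#' Real-valued P300 score per epoch
#'
#' LDA: signed distance \code{v'x - bias}; SVM: kernel decision value
#' \code{sum alpha_i y_i K(x_i, x) + b}; MLP: logistic output minus 0.5.
#' In all three, positive means Target.
#'
#' @param model A fitted \code{lda_model}, \code{svm_model} or
#'   \code{mlp_model}.
#' @param X Feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return Numeric score vector.
#' @export
predict_score <- function(model, X, ...) UseMethod("predict_score")

check_dim <- function(model, X) {
  if (ncol(X) != model$dim)
    stop(sprintf("feature dimension %d does not match training dimension %d",
                 ncol(X), model$dim))
}

#' @export
predict_score.lda_model <- function(model, X, ...) {
  X <- as.matrix(X); check_dim(model, X)
  as.numeric(X %*% model$v) - model$bias
}

#' @export
predict_score.svm_model <- function(model, X, ...) {
  X <- as.matrix(X); check_dim(model, X)
  if (model$scaled)
    X <- sweep(sweep(X, 2, model$center), 2, model$scale_sd, "/")
  K <- polynomial_kernel(X, model$sv_x, model$degree, model$coef0)
  as.numeric(K %*% (model$alpha * model$sv_y)) + model$b
}

#' @export
predict_score.mlp_model <- function(model, X, ...) {
  X <- as.matrix(X); check_dim(model, X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale_sd, "/")
  mlp_forward(model$par, Xs)$p - 0.5
}

#' Predicted Target/NoTarget labels
#'
#' Thresholds [predict_score()] at zero (equivalently, the MLP's logistic
#' output at 0.5).
#'
#' @inheritParams predict_score
#' @return Factor with levels NoTarget, Target.
#' @export
predict_label <- function(model, X, ...) {
  sc <- predict_score(model, X, ...)
  factor(ifelse(sc > 0, "Target", "NoTarget"),
         levels = c("NoTarget", "Target"))
}

#' Stratified k-fold cross-validation
#'
#' Splits epochs into k folds preserving the Target/NoTarget proportion,
#' fits on k-1 folds, scores the held-out fold, and reports per-fold
#' accuracies with their mean and sample (n-1 denominator) standard
#' deviation. If a training split ends up single-class the partition is
#' redrawn (with a message).
#'
#' @param X Feature matrix.
#' @param y Labels.
#' @param classifier One of \code{"lda"}, \code{"svm"}, \code{"mlp"}.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment (and MLP init).
#' @param ... Passed to the fitting function.
#' @return A \code{train_report}: \code{fold_accuracy}, \code{mean},
#'   \code{sd}, \code{k}, \code{classifier}.
#' @export
cross_validate <- function(X, y, classifier = c("lda", "svm", "mlp"),
                           k = 5, seed = 1, ...) {
  classifier <- match.arg(classifier)
  X <- as.matrix(X)
  yb <- as_binary_labels(y)
  n <- nrow(X)
  if (n < k) stop("need at least k samples")
  fit_fun <- switch(classifier, lda = fit_lda, svm = fit_svm,
                    mlp = function(X, y, ...) fit_mlp(X, y, seed = seed, ...))
  set.seed(as.integer(seed))
  for (attempt in 1:20) {
    folds <- integer(n)
    for (cls in c(1, -1)) {
      idx <- which(yb == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(yb[folds != f])) == 2 && sum(folds == f) > 0, logical(1)))
    if (ok) break
    message("cross_validate: single-class training split, redrawing partition")
  }
  acc <- vapply(seq_len(k), function(f) {
    fit <- fit_fun(X[folds != f, , drop = FALSE], yb[folds != f], ...)
    pred <- predict_score(fit, X[folds == f, , drop = FALSE]) > 0
    mean(pred == (yb[folds == f] > 0))
  }, numeric(1))
  structure(list(fold_accuracy = acc, mean = mean(acc),
                 sd = stats::sd(acc), k = k, classifier = classifier),
            class = "train_report")
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s): accuracy %.2f%% +/- %.2f%%\n", x$k,
              x$classifier, 100 * x$mean, 100 * x$sd))
  invisible(x)
}
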