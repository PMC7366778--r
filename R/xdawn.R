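#' Toeplitz design matrix for stimulus-locked responses
#'
#' Builds the sparse 0/1 matrix D (n_samples x epoch_len) whose column k
#' carries ones at the samples k steps after each selected event onset, so
#' that \code{D \%*\% A} replicates a time-locked waveform \code{A} at every
#' onset. Overlapping events (ISI shorter than the epoch) simply add: the
#' model assumes linear superposition of evoked responses.
#'
#' @param markers A \code{flash_schedule} (its \code{onset_sample} column is
#'   used, 0-based, at the rate of the recording being modeled).
#' @param n_samples Number of samples of the recording.
#' @param epoch_len Epoch length in samples.
#' @param which \code{"target"} or \code{"nontarget"} events.
#' @return A \code{dgCMatrix} of dimension n_samples x epoch_len.
#' @export
build_toeplitz <- function(markers, n_samples, epoch_len,
                           which = c("target", "nontarget")) {
  which <- match.arg(which)
  stopifnot(inherits(markers, "flash_schedule"))
  ev <- markers$events
  onsets <- ev$onset_sample[if (which == "target") ev$is_target else !ev$is_target]
  if (any(onsets < 0) || any(onsets >= n_samples))
    stop("marker onsets outside the recording")
  rows <- outer(onsets, 0:(epoch_len - 1L), "+")   # 0-based sample index
  cols <- matrix(rep(seq_len(epoch_len), each = length(onsets)),
                 nrow = length(onsets))
  keep <- rows < n_samples                          # truncate trailing epochs
  n_trunc <- sum(!keep)
  if (n_trunc > 0)
    message(sprintf("build_toeplitz: %d trailing row(s) truncated at recording end", n_trunc))
  Matrix::sparseMatrix(i = rows[keep] + 1L, j = cols[keep], x = 1,
                       dims = c(n_samples, epoch_len))
}

#' Least-squares estimate of the evoked response
#'
#' Solves \code{argmin_A || X - D A ||^2} by the normal equations: the
#' stimulus-locked average corrected for overlapping flashes.
#'
#' @param X Preprocessed recording, samples x channels.
#' @param D Toeplitz design from [build_toeplitz()].
#' @return \code{A_hat}, epoch_len x channels.
#' @export
estimate_erp <- function(X, D) {
  stopifnot(nrow(X) == nrow(D))
  G <- as.matrix(Matrix::crossprod(D))              # epoch_len x epoch_len
  d <- diag(G)
  if (any(d == 0))
    stop("rank-deficient design: no events cover lag(s) ",
         paste(which(d == 0) - 1L, collapse = ", "))
  ch <- chol(G)
  rhs <- as.matrix(Matrix::crossprod(D, X))
  backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
}

#' Fit xDAWN spatial filters by SSNR maximization
#'
#' Models the preprocessed recording as a target evoked response replicated
#' at each target onset plus residual activity, estimates the response by
#' least squares ([estimate_erp()]), and finds spatial filters maximizing
#' the signal-to-signal-plus-noise ratio: the generalized Rayleigh quotient
#' with the evoked-signal covariance \code{(D A)' (D A) / n} in the
#' numerator and the total signal covariance \code{X'X / n} in the
#' denominator. Solved by whitening the denominator (Cholesky) and an
#' ordinary symmetric eigendecomposition; the top \code{k} eigenvectors are
#' kept and eigenvalues reported as SSNR values. Eigenvector signs are
#' fixed so each filter's largest-magnitude coefficient is positive.
#'
#' @param X Preprocessed recording, samples x channels.
#' @param markers A \code{flash_schedule} at the recording's rate.
#' @param epoch_len Epoch length in samples (default \code{floor(0.5 * fs)}
#'   is the caller's responsibility; no default here).
#' @param k Number of filters to keep (default 3).
#' @param ridge Relative ridge added to the denominator covariance if it is
#'   not positive definite.
#' @return An \code{xdawn_model}: \code{U} (channels x k), \code{ssnr}
#'   (descending eigenvalues), \code{A_hat} (epoch_len x channels),
#'   \code{epoch_len}, \code{n_channels}.
#' @export
fit_xdawn <- function(X, markers, epoch_len, k = 3, ridge = 1e-9) {
  stopifnot(is.matrix(X), epoch_len >= 1)
  n <- nrow(X); n_ch <- ncol(X)
  if (k > n_ch) stop("k cannot exceed the channel count")
  D1 <- build_toeplitz(markers, n, epoch_len, "target")
  A_hat <- estimate_erp(X, D1)
  S_hat <- as.matrix(D1 %*% A_hat)                  # evoked part of X
  num <- crossprod(S_hat) / n
  den <- crossprod(X) / n
  eig_ok <- FALSE
  eps_used <- 0
  for (attempt in 0:6) {
    eps_used <- if (attempt == 0) 0 else ridge * 10^(attempt - 1) *
      mean(diag(den))
    den_r <- den + diag(eps_used, n_ch)
    L <- tryCatch(chol(den_r), error = function(e) NULL)
    if (!is.null(L)) { eig_ok <- TRUE; break }
  }
  if (!eig_ok) stop("denominator covariance could not be factorized")
  if (eps_used > 0)
    message(sprintf("fit_xdawn: denominator ridge-regularized (eps = %.3g)", eps_used))
  Linv <- backsolve(L, diag(n_ch))                  # L %*% Linv = I (upper)
  B <- t(Linv) %*% num %*% Linv
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  U <- Linv %*% e$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|.| coefficient positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(U[, j]))
    if (U[i_max, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(U = U, ssnr = e$values[seq_len(k)], A_hat = A_hat,
                 epoch_len = as.integer(epoch_len), n_channels = n_ch),
            class = "xdawn_model")
}

#' @export
print.xdawn_model <- function(x, ...) {
  cat(sprintf("xdawn_model: %d filters over %d channels, SSNR = %s\n",
              ncol(x$U), x$n_channels,
              paste(sprintf("%.4f", x$ssnr), collapse = ", ")))
  invisible(x)
}

#' Evaluate the SSNR Rayleigh quotient for arbitrary filters
#'
#' Utility for diagnostics and verification: the ratio of evoked-signal to
#' total-signal energy of \code{X} projected on each column of \code{V}.
#'
#' @param V Channels x m matrix of candidate filters.
#' @param X Preprocessed recording, samples x channels.
#' @param markers A \code{flash_schedule}.
#' @param epoch_len Epoch length in samples.
#' @return Numeric vector of m quotients.
#' @export
ssnr_quotient <- function(V, X, markers, epoch_len) {
  V <- as.matrix(V)
  n <- nrow(X)
  D1 <- build_toeplitz(markers, n, epoch_len, "target")
  A_hat <- estimate_erp(X, D1)
  S_hat <- as.matrix(D1 %*% A_hat)
  num <- crossprod(S_hat) / n
  den <- crossprod(X) / n
  colSums(V * (num %*% V)) / colSums(V * (den %*% V))
}

#' Project epochs through xDAWN filters
#'
#' Multiplies each epoch (channels x samples) by the spatial filters and
#' flattens the k enhanced component traces into one feature vector:
#' k * epoch_samples features per epoch (186 for 3 filters x 62 samples).
#'
#' @param model An \code{xdawn_model}.
#' @param epochs An \code{epoch_set} (or a n x channels x samples array).
#' @return Feature matrix, n_epochs x (k * epoch_samples); component-major
#'   layout (component 1 trace, then component 2, ...).
#' @export
apply_xdawn <- function(model, epochs) {
  stopifnot(inherits(model, "xdawn_model"))
  arr <- if (inherits(epochs, "epoch_set")) epochs$epochs else epochs
  stopifnot(length(dim(arr)) == 3)
  if (dim(arr)[2] != model$n_channels)
    stop(sprintf("epochs have %d channels, model expects %d",
                 dim(arr)[2], model$n_channels))
  n <- dim(arr)[1]; ns <- dim(arr)[3]; k <- ncol(model$U)
  out <- matrix(0, n, k * ns)
  for (i in seq_len(n)) {
    proj <- crossprod(model$U, arr[i, , ])          # k x samples
    out[i, ] <- as.vector(t(proj))                  # component-major
  }
  out
}
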