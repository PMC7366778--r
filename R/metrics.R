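#' Two-class confusion matrix
#'
#' Counts of the four outcomes of binary Target/NoTarget detection:
#' TP (target predicted target), FN (target missed), FP (false alarm),
#' TN (correct rejection).
#'
#' @param y_true,y_pred Labels of equal length (Target/NoTarget factor,
#'   logical, or 0/1; Target is the positive class).
#' @return A \code{confusion_matrix}: list with \code{TP}, \code{FN},
#'   \code{FP}, \code{TN}.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  t_pos <- as_binary_labels(y_true) > 0
  p_pos <- as_binary_labels(y_pred) > 0
  structure(list(TP = sum(t_pos & p_pos), FN = sum(t_pos & !p_pos),
                 FP = sum(!t_pos & p_pos), TN = sum(!t_pos & !p_pos)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(True = c("Target", "NoTarget"),
                              Predicted = c("Target", "NoTarget")))
  print(m)
  invisible(x)
}

#' Row-normalized confusion matrix
#'
#' Each true-class row divided by its total, so rows sum to 1.
#'
#' @param cm A [confusion()] object.
#' @return 2 x 2 numeric matrix.
#' @export
normalize_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pos <- cm$TP + cm$FN; neg <- cm$FP + cm$TN
  if (pos == 0 || neg == 0) stop("empty true class: normalization undefined")
  matrix(c(cm$TP / pos, cm$FN / pos, cm$FP / neg, cm$TN / neg), 2, 2,
         byrow = TRUE,
         dimnames = list(True = c("Target", "NoTarget"),
                         Predicted = c("Target", "NoTarget")))
}

metric_guard <- function(num, den, what) {
  if (any(den == 0)) stop(what, " undefined: zero denominator")
  num / den
}

#' Sensitivity (true positive rate)
#' @param cm A [confusion()] object.
#' @return TP / (TP + FN).
#' @export
sensitivity <- function(cm) metric_guard(cm$TP, cm$TP + cm$FN, "sensitivity")

#' Precision (positive predictive value)
#' @param cm A [confusion()] object.
#' @return TP / (TP + FP).
#' @export
precision <- function(cm) metric_guard(cm$TP, cm$TP + cm$FP, "precision")

#' Specificity (true negative rate)
#' @param cm A [confusion()] object.
#' @return TN / (TN + FP).
#' @export
specificity <- function(cm) metric_guard(cm$TN, cm$TN + cm$FP, "specificity")

#' F-measure
#'
#' Harmonic combination of precision and sensitivity,
#' \code{2 P S / (P + S)}. Accepts either a confusion matrix or the two
#' fractions directly (as printed in per-participant result tables).
#'
#' @param cm A [confusion()] object, or NULL if \code{precision_value} and
#'   \code{sensitivity_value} are given.
#' @param precision_value,sensitivity_value Fractions in [0, 1].
#' @return 2PS / (P + S).
#' @export
f_measure <- function(cm = NULL, precision_value = NULL,
                      sensitivity_value = NULL) {
  if (!is.null(cm)) {
    precision_value <- precision(cm)
    sensitivity_value <- sensitivity(cm)
  }
  if (is.null(precision_value) || is.null(sensitivity_value))
    stop("give either a confusion matrix or both precision and sensitivity")
  metric_guard(2 * precision_value * sensitivity_value,
               precision_value + sensitivity_value, "F-measure")
}

#' Shannon information transfer rate
#'
#' Bits per minute conveyed by an N-choice selection system with accuracy
#' P and T seconds per selection:
#' \deqn{ITR = 60 (P \log_2 P + (1-P) \log_2\frac{1-P}{N-1} + \log_2 N)/T}
#' with the convention 0 log 0 = 0, so P = 0 and P = 1 are handled. At
#' chance (P = 1/N) the rate is exactly zero.
#'
#' @param P Probability of a correct selection, in [0, 1].
#' @param N Number of classes (>= 2). 36 for the 6x6 speller.
#' @param T Seconds per selection (> 0); stimulation time only.
#' @return Bits per minute.
#' @examples
#' itr(0.8083, 36, 13.55)  # ~15.42, the online operating point
#' itr(0.9443, 36, 27.1)   # ~10.13, the offline operating point
#' @export
itr <- function(P, N, T) {
  if (!is.numeric(P) || any(P < 0) || any(P > 1)) stop("P must be in [0, 1]")
  if (!is.numeric(N) || any(N < 2)) stop("N must be >= 2")
  if (!is.numeric(T) || any(T <= 0)) stop("T must be > 0")
  xlog2 <- function(x) ifelse(x == 0, 0, x * log2(x))
  bits <- xlog2(P) + (1 - P) * ifelse(P == 1, 0, log2((1 - P) / (N - 1))) +
    log2(N)
  60 * bits / T
}

#' Column-wise mean and sample standard deviation of a metric table
#'
#' Aggregates per-participant metric rows the way results tables print
#' their Average row: column means with n-1 denominator standard
#' deviations, optionally rounded for display (4 decimals for fractions,
#' 2 for percentages).
#'
#' @param tab Numeric matrix or data.frame, one row per participant (>= 2).
#' @param digits Display rounding; NULL for none.
#' @return Data.frame with rows \code{mean} and \code{sd}.
#' @export
aggregate_report <- function(tab, digits = NULL) {
  tab <- as.matrix(tab)
  if (!nrow(tab)) stop("empty table")
  if (nrow(tab) < 2) stop("need at least 2 rows to aggregate")
  m <- colMeans(tab)
  s <- apply(tab, 2, stats::sd)
  out <- rbind(mean = m, sd = s)
  if (!is.null(digits)) out <- round(out, digits)
  as.data.frame(out)
}
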