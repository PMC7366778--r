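#' Decode one character from a table of flash scores
#'
#' Sums the classifier scores over repetitions for each of the 12 stimuli,
#' picks the best row among R0--R5 and the best column among C0--C5, and
#' returns the grid character at that (row, column). Ties are broken toward
#' the lowest index (with a message).
#'
#' @param table 12 x n_reps numeric matrix of scores with rownames
#'   \code{R0..R5, C0..C5}; no missing cells.
#' @param grid A [speller_grid()].
#' @return Single character.
#' @export
score_character <- function(table, grid) {
  stopifnot(inherits(grid, "speller_grid"))
  ids <- stim_ids()
  if (!is.matrix(table) || is.null(rownames(table)) ||
      !setequal(rownames(table), ids))
    stop("score table must be a matrix with rownames R0..R5, C0..C5")
  if (anyNA(table)) {
    bad <- which(is.na(table), arr.ind = TRUE)
    stop("incomplete score table; missing cells: ",
         paste(sprintf("%s/rep%d", rownames(table)[bad[, 1]], bad[, 2]),
               collapse = ", "))
  }
  total <- rowSums(table[ids, , drop = FALSE])
  row_sc <- total[1:6]; col_sc <- total[7:12]
  if (sum(row_sc == max(row_sc)) > 1 || sum(col_sc == max(col_sc)) > 1)
    message("score_character: tie broken toward the lowest index")
  r <- which.max(row_sc) - 1L
  c <- which.max(col_sc) - 1L
  grid$chars[r + 1L, c + 1L]
}

# Scores + epoch metadata -> one decoded character per trial.
decode_trials <- function(scores, meta, grid, n_reps_use = NULL) {
  ids <- stim_ids()
  out <- character(0)
  for (ci in sort(unique(meta$char_index))) {
    sel <- meta$char_index == ci
    if (!is.null(n_reps_use)) sel <- sel & meta$repetition <= n_reps_use
    tab <- matrix(NA_real_, 12, max(meta$repetition[sel]),
                  dimnames = list(ids, NULL))
    tab[cbind(match(meta$stim_id[sel], ids), meta$repetition[sel])] <-
      scores[sel]
    out <- c(out, score_character(tab, grid))
  }
  out
}

#' Offline end-to-end evaluation of a session
#'
#' Preprocesses the session's recording (bandpass, decimate, epoch),
#' projects the epochs through a fitted xDAWN model, scores them with a
#' fitted detector, and reports epoch-level accuracy, character-level
#' accuracy, and the epoch confusion matrix. Deterministic given its
#' inputs.
#'
#' @param session A [synthesize_session()] result, or any list with
#'   \code{recording} (markers attached) and \code{schedule}.
#' @param xdawn_model A fitted [fit_xdawn()] model.
#' @param clf_model A fitted detector ([fit_lda()], [fit_svm()],
#'   [fit_mlp()]).
#' @param grid A [speller_grid()] (defaults to the standard layout).
#' @param window_s Epoch length, seconds.
#' @return List: \code{epoch_accuracy}, \code{char_accuracy},
#'   \code{confusion} ([confusion()] object), \code{decoded},
#'   \code{targets}.
#' @export
run_offline <- function(session, xdawn_model, clf_model,
                        grid = speller_grid(), window_s = 0.5) {
  ep <- preprocess_session(session$recording, window_s = window_s)
  feats <- apply_xdawn(xdawn_model, ep)
  scores <- predict_score(clf_model, feats)
  pred <- factor(ifelse(scores > 0, "Target", "NoTarget"),
                 levels = levels(ep$labels))
  cm <- confusion(ep$labels, pred)
  decoded <- decode_trials(scores, ep$meta, grid)
  targets <- session$schedule$targets
  list(epoch_accuracy = mean(pred == ep$labels),
       char_accuracy = mean(decoded == targets),
       confusion = cm, decoded = decoded, targets = targets)
}

#' Simulated online decoding loop
#'
#' Replays a session causally: the recording is filtered forward-only (so
#' no epoch's samples depend on anything after it), and character trials
#' are decided strictly in order, each as soon as its last repetition's
#' epoch window has elapsed. Every decision carries the stimulation time
#' \code{T = n_reps * 12 * isi + (n_reps - 1) * inter_rep} seconds. Because
#' the whole pipeline is causal, decisions agree with [run_offline()] on
#' the same data.
#'
#' @param session A synthesized (or loaded) session recorded with online
#'   timing.
#' @param xdawn_model A fitted [fit_xdawn()] model.
#' @param clf_model A fitted detector.
#' @param grid A [speller_grid()].
#' @param n_reps_use Repetitions used per decision (defaults to all).
#' @param window_s Epoch length, seconds.
#' @return A data.frame with one row per decision: \code{char_index},
#'   \code{decoded}, \code{target}, \code{correct}, \code{T_s},
#'   \code{decided_at_s} (time of the last sample used).
#' @export
run_online_sim <- function(session, xdawn_model, clf_model,
                           grid = speller_grid(), n_reps_use = NULL,
                           window_s = 0.5) {
  timing <- session$schedule$timing
  n_reps <- if (is.null(n_reps_use)) timing$n_reps else as.integer(n_reps_use)
  if (n_reps < 1 || n_reps > timing$n_reps)
    stop("n_reps_use must be in 1..n_reps of the schedule")
  ep <- preprocess_session(session$recording, window_s = window_s)
  need <- count_epochs(timing, length(session$schedule$targets))$total
  if (dim(ep$epochs)[1] < need)
    stop(sprintf("stream underrun: %d of %d expected epochs available",
                 dim(ep$epochs)[1], need))
  feats <- apply_xdawn(xdawn_model, ep)
  scores <- predict_score(clf_model, feats)
  T_s <- decision_time(timing, n_reps)
  targets <- session$schedule$targets
  rows <- lapply(seq_along(targets), function(ci) {
    sel <- ep$meta$char_index == ci & ep$meta$repetition <= n_reps
    last_sample <- max(ep$meta$onset_sample[sel]) +
      floor(window_s * ep$fs_epoch)
    dec <- decode_trials(scores[sel], ep$meta[sel, , drop = FALSE], grid)
    data.frame(char_index = ci, decoded = dec, target = targets[ci],
               correct = dec == targets[ci], T_s = T_s,
               decided_at_s = last_sample / ep$fs_epoch,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stimulation time per decision
#'
#' \code{T = n_reps * 12 * isi_s + (n_reps - 1) * inter_rep_s}: the time
#' a user spends being stimulated for one character decision. With the
#' online timing (ISI 75 ms, 0.25 s between repetitions) and 12
#' repetitions, T = 13.55 s.
#'
#' @param timing A [timing_params()] object.
#' @param n_reps Repetitions per decision (defaults to the schedule's).
#' @return Seconds.
#' @export
decision_time <- function(timing, n_reps = timing$n_reps) {
  stopifnot(inherits(timing, "timing_params"), n_reps >= 1)
  n_reps * 12 * timing$isi_s + (n_reps - 1) * timing$inter_rep_s
}
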