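#' The 6x6 speller grid
#'
#' Builds the classic matrix-speller layout: 26 letters followed by the 10
#' digits, filled row-wise into a 6x6 grid. Rows and columns are indexed
#' 0--5, matching the stimulus identifiers \code{R0}--\code{R5} (rows) and
#' \code{C0}--\code{C5} (columns) used throughout the package.
#'
#' @param characters Character vector of exactly 36 distinct single symbols.
#'   Defaults to \code{A}--\code{Z}, \code{0}--\code{9}.
#' @return An object of class \code{speller_grid} with elements
#'   \code{chars} (6x6 character matrix), \code{row_of} and \code{col_of}
#'   (named integer vectors, 0-based).
#' @examples
#' g <- speller_grid()
#' g$chars[g$row_of["O"] + 1, g$col_of["O"] + 1]  # "O"
#' @export
speller_grid <- function(characters = c(LETTERS, as.character(0:9))) {
  characters <- as.character(characters)
  if (length(characters) != 36L || anyDuplicated(characters))
    stop("a speller grid needs exactly 36 distinct symbols")
  chars <- matrix(characters, nrow = 6L, ncol = 6L, byrow = TRUE)
  row_of <- rep(0:5, each = 6L)
  col_of <- rep(0:5, times = 6L)
  names(row_of) <- names(col_of) <- characters
  structure(list(chars = chars, row_of = row_of, col_of = col_of),
            class = "speller_grid")
}

#' @export
print.speller_grid <- function(x, ...) {
  cat("6x6 speller grid:\n")
  print(x$chars, quote = FALSE)
  invisible(x)
}

#' Flash-timing parameters of a speller session
#'
#' Encodes the oddball stimulation schedule: each repetition flashes all 6
#' rows and 6 columns once (12 stimuli), separated by the interstimulus
#' interval (ISI = flash + gap); repetitions within a character trial are
#' separated by \code{inter_rep_s}, and consecutive character trials by
#' \code{inter_char_s}. Both delays count the gaps *between* consecutive
#' units, so a trial of r repetitions lasts
#' \code{r * 12 * isi_s + (r - 1) * inter_rep_s}.
#'
#' @param flash_s Flash (stimulus on) duration in seconds.
#' @param gap_s No-flash duration in seconds.
#' @param inter_rep_s Delay between consecutive repetitions, seconds.
#' @param inter_char_s Delay between consecutive character trials, seconds.
#' @param n_reps Repetitions per character.
#' @return A \code{timing_params} object; \code{isi_s = flash_s + gap_s},
#'   \code{n_stim_per_rep = 12}.
#' @seealso [training_timing()], [online_timing()], [session_duration()]
#' @export
timing_params <- function(flash_s, gap_s, inter_rep_s, inter_char_s, n_reps = 12L) {
  stopifnot(flash_s > 0, gap_s > 0, inter_rep_s > 0, inter_char_s > 0,
            n_reps >= 1)
  structure(list(flash_s = flash_s, gap_s = gap_s, isi_s = flash_s + gap_s,
                 inter_rep_s = inter_rep_s, inter_char_s = inter_char_s,
                 n_reps = as.integer(n_reps), n_stim_per_rep = 12L),
            class = "timing_params")
}

#' Training-phase timing (ISI 150 ms)
#'
#' 100 ms flash + 50 ms gap, 0.5 s between repetitions, 5 s between
#' characters, 12 repetitions per character.
#' @param n_reps Repetitions per character.
#' @return A [timing_params()] object.
#' @export
training_timing <- function(n_reps = 12L)
  timing_params(0.100, 0.050, 0.5, 5, n_reps)

#' Online-phase timing (ISI 75 ms)
#'
#' 50 ms flash + 25 ms gap, 0.25 s between repetitions. The inter-character
#' delay is kept at 5 s (it does not enter the per-decision time).
#' @param n_reps Repetitions per character.
#' @return A [timing_params()] object.
#' @export
online_timing <- function(n_reps = 12L)
  timing_params(0.050, 0.025, 0.25, 5, n_reps)

stim_ids <- function() c(paste0("R", 0:5), paste0("C", 0:5))

#' Generate a randomized row/column flash schedule
#'
#' For every repetition of every target character, draws a fresh uniform
#' random permutation of the 12 stimuli (6 rows, 6 columns) and lays the
#' flash onsets out according to \code{timing}. Onsets are computed in exact
#' seconds and rounded to the nearest sample at \code{fs}; exactly 2 of the
#' 12 events per repetition (the target's own row and column) are flagged as
#' targets.
#'
#' @param grid A [speller_grid()].
#' @param targets Character vector of target symbols, one per trial; all
#'   must be in the grid.
#' @param timing A [timing_params()] object.
#' @param seed Integer seed fixing the permutation stream.
#' @param fs Sampling rate (Hz) used for \code{onset_sample} (0-based).
#' @return A \code{flash_schedule}: list with \code{events} (data.frame with
#'   columns \code{onset_s}, \code{onset_sample}, \code{stim_id},
#'   \code{is_target}, \code{char_index}, \code{repetition}),
#'   \code{timing}, \code{targets}, \code{fs}. \code{char_index} and
#'   \code{repetition} are 1-based.
#' @examples
#' sched <- generate_flash_schedule(speller_grid(), c("A", "7"),
#'                                  training_timing(), seed = 1)
#' nrow(sched$events)        # 2 * 12 * 12 = 288
#' sum(sched$events$is_target)  # 2 * 12 * 2 = 48
#' @export
generate_flash_schedule <- function(grid, targets, timing, seed, fs = 500) {
  stopifnot(inherits(grid, "speller_grid"), inherits(timing, "timing_params"))
  targets <- as.character(targets)
  bad <- setdiff(targets, names(grid$row_of))
  if (length(bad))
    stop("target symbol(s) not in grid: ", paste(bad, collapse = ", "))
  ids <- stim_ids()
  n_chars <- length(targets)
  n_reps <- timing$n_reps
  rep_span <- 12 * timing$isi_s + timing$inter_rep_s   # onset-to-onset, reps
  char_span <- n_reps * 12 * timing$isi_s + (n_reps - 1) * timing$inter_rep_s +
    timing$inter_char_s
  rng <- local({ set.seed(as.integer(seed)); function() sample.int(12L) })
  ev <- vector("list", n_chars * n_reps)
  for (c_i in seq_len(n_chars)) {
    tgt_ids <- c(paste0("R", grid$row_of[targets[c_i]]),
                 paste0("C", grid$col_of[targets[c_i]]))
    for (r_i in seq_len(n_reps)) {
      perm <- ids[rng()]
      onset <- (c_i - 1) * char_span + (r_i - 1) * rep_span +
        (0:11) * timing$isi_s
      ev[[(c_i - 1) * n_reps + r_i]] <- data.frame(
        onset_s = onset,
        onset_sample = as.integer(round(onset * fs)),
        stim_id = perm,
        is_target = perm %in% tgt_ids,
        char_index = c_i,
        repetition = r_i,
        stringsAsFactors = FALSE)
    }
  }
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  structure(list(events = events, timing = timing, targets = targets, fs = fs),
            class = "flash_schedule")
}

#' @export
print.flash_schedule <- function(x, ...) {
  cat(sprintf("flash_schedule: %d events, %d character trial(s), %d reps, ISI %g ms\n",
              nrow(x$events), length(x$targets), x$timing$n_reps,
              1000 * x$timing$isi_s))
  invisible(x)
}

#' Closed-form stimulation duration of a speller session
#'
#' Total time from the first flash onset to the end of the last ISI:
#' \code{n_chars * (n_reps * 12 * isi + (n_reps - 1) * inter_rep) +
#' (n_chars - 1) * inter_char}. Inter-repetition and inter-character delays
#' fall between consecutive units only; with the training timing (ISI
#' 150 ms, 12 reps) a 15-character session takes 476.5 s.
#'
#' @param timing A [timing_params()] object.
#' @param n_chars Number of character trials (>= 1).
#' @return Duration in seconds.
#' @export
session_duration <- function(timing, n_chars) {
  stopifnot(inherits(timing, "timing_params"))
  if (!is.numeric(n_chars) || n_chars < 1)
    stop("n_chars must be a positive count")
  n_chars * (timing$n_reps * 12 * timing$isi_s +
               (timing$n_reps - 1) * timing$inter_rep_s) +
    (n_chars - 1) * timing$inter_char_s
}

#' Epoch bookkeeping for a speller session
#'
#' @param timing A [timing_params()] object.
#' @param n_chars Number of character trials (>= 1).
#' @return Named list \code{total}, \code{target}, \code{nontarget}. A
#'   15-character, 12-repetition session yields 2160 / 360 / 1800.
#' @export
count_epochs <- function(timing, n_chars) {
  stopifnot(inherits(timing, "timing_params"))
  if (!is.numeric(n_chars) || n_chars < 1)
    stop("n_chars must be a positive count")
  total <- n_chars * timing$n_reps * 12L
  target <- n_chars * timing$n_reps * 2L
  list(total = total, target = target, nontarget = total - target)
}

#' Write a flash schedule as a delimited marker table
#'
#' Tab-separated columns \code{onset_sample} (0-based), \code{stim_id},
#' \code{is_target} (0/1), \code{char_index}, \code{repetition}, with a
#' header line; the sample-indexed analogue of a BrainVision marker file.
#'
#' @param schedule A [generate_flash_schedule()] result.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_marker_table <- function(schedule, path) {
  stopifnot(inherits(schedule, "flash_schedule"))
  ev <- schedule$events
  out <- data.frame(onset_sample = ev$onset_sample, stim_id = ev$stim_id,
                    is_target = as.integer(ev$is_target),
                    char_index = ev$char_index, repetition = ev$repetition)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
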