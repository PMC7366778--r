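#' Causal Butterworth bandpass filter
#'
#' Applies a forward-only (causal) Butterworth bandpass to every channel.
#' Causality matters because the same filter must run online, where future
#' samples do not exist; no zero-phase (forward-backward) filtering is used
#' anywhere in the pipeline.
#'
#' @param rec A \code{continuous_recording}.
#' @param low Lower cut-off, Hz.
#' @param high Upper cut-off, Hz.
#' @param order Butterworth design order (poles per band edge).
#' @return A filtered \code{continuous_recording}, same shape and sampling
#'   rate; markers carried through unchanged.
#' @export
bandpass <- function(rec, low = 1, high = 20, order = 4) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop("need 0 < low < high < fs/2")
  filt <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1, function(x)
    signal::filter(filt$b, filt$a, x)))
  dim(out$data) <- dim(rec$data)
  out
}

# Designed frequency response of the default band-pass, |H(f)|, for tests
# and diagnostics (analytic, from the digital filter coefficients).
bandpass_response <- function(freqs, fs, low = 1, high = 20, order = 4) {
  filt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  w <- 2 * pi * freqs / fs
  z <- exp(-1i * w)
  num <- vapply(z, function(zz) sum(filt$b * zz^(seq_along(filt$b) - 1)),
                complex(1))
  den <- vapply(z, function(zz) sum(filt$a * zz^(seq_along(filt$a) - 1)),
                complex(1))
  Mod(num / den)
}

#' Decimate a recording
#'
#' Reduces the sampling rate by an integer factor: a causal anti-aliasing
#' low-pass (Butterworth, cut-off at 80% of the new Nyquist) followed by
#' sample picking. With the standard pipeline the signal is already limited
#' to 20 Hz, far below the decimated Nyquist, so the anti-alias stage is a
#' safety net rather than a necessity. Marker onsets are rescaled by floor
#' division.
#'
#' @param rec A \code{continuous_recording}.
#' @param factor Integer decimation factor (>= 1).
#' @param antialias Apply the anti-aliasing low-pass first (default TRUE).
#' @return A \code{continuous_recording} at \code{fs / factor}.
#' @export
decimate <- function(rec, factor = 4, antialias = TRUE) {
  stopifnot(inherits(rec, "continuous_recording"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be a positive integer")
  out <- rec
  if (factor == 1L) return(out)
  data <- rec$data
  if (antialias) {
    lp <- signal::butter(4, 0.8 / factor, type = "low")
    data <- t(apply(data, 1, function(x) signal::filter(lp$b, lp$a, x)))
    dim(data) <- dim(rec$data)
  }
  keep <- seq(1L, ncol(data), by = factor)
  out$data <- data[, keep, drop = FALSE]
  out$fs <- rec$fs / factor
  if (!is.null(out$markers)) {
    out$markers$events$onset_sample <- out$markers$events$onset_sample %/% factor
    out$markers$fs <- out$fs
  }
  out
}

#' Cut stimulus-locked epochs
#'
#' Extracts one fixed-length window per flash event, samples
#' \code{[onset, onset + floor(window_s * fs))} (0-based, half-open), and
#' labels it Target or NoTarget from the event's target flag. At 125 Hz
#' with the default 500 ms window every epoch has 62 samples. Events whose
#' window overruns the recording are rejected and counted.
#'
#' @param rec A \code{continuous_recording} carrying markers.
#' @param window_s Epoch length, seconds.
#' @return An \code{epoch_set}: \code{epochs} (n x channels x samples
#'   array), \code{labels} (factor Target/NoTarget), \code{meta}
#'   (stim_id, char_index, repetition per epoch), \code{fs_epoch},
#'   \code{n_rejected}.
#' @export
epoch_recording <- function(rec, window_s = 0.5) {
  stopifnot(inherits(rec, "continuous_recording"))
  if (is.null(rec$markers)) stop("recording carries no markers")
  ev <- rec$markers$events
  len <- as.integer(floor(window_s * rec$fs))
  if (len < 1) stop("window_s too short for this sampling rate")
  ok <- ev$onset_sample + len <= ncol(rec$data)
  n_rej <- sum(!ok)
  if (n_rej > 0)
    message(sprintf("epoch_recording: rejected %d epoch(s) overrunning the recording", n_rej))
  ev <- ev[ok, , drop = FALSE]
  n <- nrow(ev)
  epochs <- array(0, dim = c(n, nrow(rec$data), len))
  for (i in seq_len(n)) {
    s0 <- ev$onset_sample[i]                 # 0-based onset
    epochs[i, , ] <- rec$data[, (s0 + 1):(s0 + len), drop = FALSE]
  }
  structure(list(
    epochs = epochs,
    labels = factor(ifelse(ev$is_target, "Target", "NoTarget"),
                    levels = c("NoTarget", "Target")),
    meta = data.frame(stim_id = ev$stim_id, char_index = ev$char_index,
                      repetition = ev$repetition,
                      onset_sample = ev$onset_sample,
                      stringsAsFactors = FALSE),
    fs_epoch = rec$fs, n_rejected = n_rej),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("epoch_set: %d epochs x %d channels x %d samples @ %g Hz (%d Target)\n",
              d[1], d[2], d[3], x$fs_epoch, sum(x$labels == "Target")))
  invisible(x)
}

#' Standard preprocessing chain
#'
#' Bandpass (1--20 Hz, causal Butterworth), decimate (factor 4; 500 to
#' 125 Hz), epoch (500 ms).
#'
#' @param rec A \code{continuous_recording} with markers.
#' @param low,high Band edges, Hz.
#' @param order Filter design order.
#' @param factor Decimation factor.
#' @param window_s Epoch length, seconds.
#' @return An \code{epoch_set}.
#' @export
preprocess_session <- function(rec, low = 1, high = 20, order = 4,
                               factor = 4, window_s = 0.5) {
  epoch_recording(decimate(bandpass(rec, low, high, order), factor), window_s)
}
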