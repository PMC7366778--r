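#' Configuration for synthetic speller sessions
#'
#' Describes the generative model used by [synthesize_session()]: a
#' stereotyped P300 deflection (Gaussian bump in time, fixed spatial
#' topography across channels) added on target flashes, on top of a
#' background of pink (1/f) noise, a 10 Hz alpha sinusoid with random phase
#' per channel, and white sensor noise. Amplitudes are in microvolts.
#'
#' @param n_channels Number of EEG channels.
#' @param fs Sampling rate, Hz.
#' @param p300_amp Peak amplitude of the planted P300, uV (at the channel
#'   where \code{spatial_pattern} is largest the deflection peaks at
#'   \code{p300_amp * max(spatial_pattern)}).
#' @param p300_latency Peak latency after flash onset, seconds.
#' @param p300_width Gaussian standard deviation of the bump, seconds.
#' @param latency_jitter_sd Per-event Gaussian jitter of the latency, seconds.
#' @param spatial_pattern Unit-norm channel weight vector; default is a
#'   smooth bump over a contiguous block of channels, emulating a
#'   centro-parietal topography.
#' @param pink_noise_sd Standard deviation of the 1/f background, uV.
#' @param alpha_amp Amplitude of the alpha sinusoid, uV.
#' @param alpha_freq Alpha frequency, Hz.
#' @param white_noise_sd Standard deviation of white sensor noise, uV.
#' @param seed Integer seed; the whole session is reproducible from it.
#' @return A \code{synth_config} object (validated list).
#' @export
synth_config <- function(n_channels = 64L, fs = 500, p300_amp = 5,
                         p300_latency = 0.30, p300_width = 0.06,
                         latency_jitter_sd = 0.01,
                         spatial_pattern = NULL,
                         pink_noise_sd = 2, alpha_amp = 1, alpha_freq = 10,
                         white_noise_sd = 0.5, seed = 1L) {
  n_channels <- as.integer(n_channels)
  if (is.null(spatial_pattern))
    spatial_pattern <- default_spatial_pattern(n_channels)
  cfg <- list(n_channels = n_channels, fs = fs, p300_amp = p300_amp,
              p300_latency = p300_latency, p300_width = p300_width,
              latency_jitter_sd = latency_jitter_sd,
              spatial_pattern = spatial_pattern,
              pink_noise_sd = pink_noise_sd, alpha_amp = alpha_amp,
              alpha_freq = alpha_freq, white_noise_sd = white_noise_sd,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_channels < 1) stop("n_channels must be >= 1")
  if (cfg$fs <= 2 * cfg$alpha_freq)
    stop("fs must exceed twice the highest modeled frequency")
  if (cfg$p300_width <= 0) stop("p300_width must be > 0")
  amps <- c(cfg$p300_amp, cfg$pink_noise_sd, cfg$alpha_amp, cfg$white_noise_sd,
            cfg$latency_jitter_sd)
  if (any(amps < 0)) stop("amplitudes and jitter must be >= 0")
  if (length(cfg$spatial_pattern) != cfg$n_channels)
    stop("spatial_pattern length must equal n_channels")
  if (abs(sqrt(sum(cfg$spatial_pattern^2)) - 1) > 1e-8)
    stop("spatial_pattern must have unit Euclidean norm")
  invisible(cfg)
}

# Smooth unit-norm bump centred at ~60% of the channel array, width ~n/8:
# a contiguous "centro-parietal" block that a spatial filter can recover.
default_spatial_pattern <- function(n_channels) {
  idx <- seq_len(n_channels)
  w <- exp(-(idx - 0.6 * n_channels)^2 / (2 * (n_channels / 8)^2))
  w / sqrt(sum(w^2))
}

#' P300 waveform template
#'
#' A smooth unimodal positive deflection: a Gaussian bump peaking at
#' \code{latency} with peak value \code{amp} and standard deviation
#' \code{width}; effectively zero beyond about three widths.
#'
#' @param t Time points, seconds (vectorized).
#' @param latency Peak latency, seconds.
#' @param width Gaussian SD, seconds (> 0).
#' @param amp Peak amplitude, uV.
#' @return Waveform values at \code{t}, uV.
#' @export
p300_waveform <- function(t, latency = 0.30, width = 0.06, amp = 5) {
  if (width <= 0) stop("width must be > 0")
  amp * exp(-(t - latency)^2 / (2 * width^2))
}

# Pink (1/f) noise by frequency-domain shaping: white complex spectrum with
# amplitude 1/sqrt(f), inverse FFT, rescaled to the requested sd.
pink_noise <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  n_fft <- n
  half <- floor(n_fft / 2)
  f <- seq_len(half)                       # positive frequency bins
  mag <- 1 / sqrt(f)
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = phase)
  full <- complex(length.out = n_fft)
  full[2:(half + 1)] <- spec
  # Hermitian symmetry for a real signal
  if (n_fft %% 2 == 0) {
    full[half + 1] <- complex(real = Re(full[half + 1]), imaginary = 0)
    full[(half + 2):n_fft] <- Conj(spec[(half - 1):1])
  } else {
    full[(half + 2):n_fft] <- Conj(spec[half:1])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n_fft
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

#' Synthesize a complete speller EEG session
#'
#' Generates a continuous multichannel recording realizing a flash schedule:
#' background noise (pink + alpha + white, independently drawn per channel)
#' plus, for every target flash, a [p300_waveform()] whose latency is
#' jittered by \code{Normal(0, latency_jitter_sd)} and whose amplitude is
#' distributed over channels by \code{spatial_pattern}. Overlapping evoked
#' responses from successive flashes add linearly. Everything is drawn from
#' \code{config$seed}, so the same configuration reproduces the recording
#' bit for bit.
#'
#' @param grid A [speller_grid()].
#' @param targets Character vector of target symbols (one per trial).
#' @param timing A [timing_params()] object.
#' @param config A [synth_config()].
#' @return List with \code{recording} (a \code{continuous_recording}:
#'   \code{data} channels x samples in uV, \code{fs}, \code{channel_labels},
#'   \code{markers}), \code{schedule} (the [generate_flash_schedule()]
#'   result) and \code{truth} (spatial pattern, targets, realized per-event
#'   latencies for target events).
#' @examples
#' s <- synthesize_session(speller_grid(), c("A", "B"), training_timing(),
#'                         synth_config(n_channels = 8, seed = 42))
#' dim(s$recording$data)
#' @export
synthesize_session <- function(grid, targets, timing, config) {
  validate_synth_config(config)
  if (!length(targets)) stop("targets must be nonempty")
  schedule <- generate_flash_schedule(grid, targets, timing,
                                      seed = config$seed, fs = config$fs)
  dur <- session_duration(timing, length(targets))
  n_samp <- as.integer(ceiling((dur + 1.0) * config$fs))  # 1 s tail pad
  n_ch <- config$n_channels
  set.seed(config$seed + 1L)
  data <- matrix(0, n_ch, n_samp)
  tt <- (seq_len(n_samp) - 1) / config$fs
  for (ch in seq_len(n_ch)) {
    bg <- pink_noise(n_samp, config$pink_noise_sd)
    if (config$alpha_amp > 0)
      bg <- bg + config$alpha_amp *
        sin(2 * pi * config$alpha_freq * tt + stats::runif(1, 0, 2 * pi))
    if (config$white_noise_sd > 0)
      bg <- bg + stats::rnorm(n_samp, 0, config$white_noise_sd)
    data[ch, ] <- bg
  }
  ev <- schedule$events
  tgt <- which(ev$is_target)
  latencies <- config$p300_latency +
    stats::rnorm(length(tgt), 0, config$latency_jitter_sd)
  if (config$p300_amp > 0 && length(tgt)) {
    half_span <- ceiling(4 * config$p300_width * config$fs)
    for (i in seq_along(tgt)) {
      onset <- ev$onset_sample[tgt[i]]              # 0-based
      centre <- onset + latencies[i] * config$fs
      lo <- max(0L, as.integer(floor(centre - half_span)))
      hi <- min(n_samp - 1L, as.integer(ceiling(centre + half_span)))
      if (hi < lo) next
      t_rel <- ((lo:hi) - onset) / config$fs
      bump <- p300_waveform(t_rel, latencies[i], config$p300_width,
                            config$p300_amp)
      data[, (lo + 1):(hi + 1)] <- data[, (lo + 1):(hi + 1)] +
        outer(config$spatial_pattern, bump)
    }
  }
  rec <- continuous_recording(data, config$fs,
                              channel_labels = sprintf("Ch%02d", seq_len(n_ch)),
                              markers = schedule)
  truth <- list(spatial_pattern = config$spatial_pattern, targets = targets,
                target_event_index = tgt, latency_s = latencies)
  list(recording = rec, schedule = schedule, truth = truth)
}

#' Construct a continuous multichannel recording
#'
#' @param data Channels x samples numeric matrix, uV.
#' @param fs Sampling rate, Hz.
#' @param channel_labels Character vector, one per channel.
#' @param markers A \code{flash_schedule}, or \code{NULL}.
#' @return A \code{continuous_recording} object.
#' @export
continuous_recording <- function(data, fs, channel_labels = NULL,
                                 markers = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  if (is.null(channel_labels))
    channel_labels <- sprintf("Ch%02d", seq_len(nrow(data)))
  stopifnot(length(channel_labels) == nrow(data))
  if (!is.null(markers)) {
    stopifnot(inherits(markers, "flash_schedule"))
    if (any(markers$events$onset_sample < 0) ||
        any(markers$events$onset_sample >= ncol(data)))
      stop("marker onset_sample outside recording bounds")
  }
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 markers = markers),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("continuous_recording: %d channels x %d samples @ %g Hz (%0.1f s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (is.null(x$markers)) "" else
                sprintf(", %d markers", nrow(x$markers$events))))
  invisible(x)
}
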