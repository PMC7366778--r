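# Shared fixtures, built in code and cached for the duration of the run.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_env))
    assign(name, force(expr), envir = fixture_env)
  get(name, envir = fixture_env)
}

# A small, fast session: 8 channels, 4 characters, high SNR.
small_session <- function(n_chars = 4, n_channels = 8, amp = 5, pink = 2,
                          seed = 7, timing = training_timing(),
                          jitter = 0.01, white = 0.5) {
  g <- speller_grid()
  set.seed(seed)
  targets <- sample(names(g$row_of), n_chars, replace = TRUE)
  cfg <- synth_config(n_channels = n_channels, p300_amp = amp,
                      pink_noise_sd = pink, latency_jitter_sd = jitter,
                      white_noise_sd = white, seed = seed)
  synthesize_session(g, targets, timing, cfg)
}

# Preprocess + fit xDAWN on a session; returns everything downstream
# stages need.
fitted_pipeline <- function(session, k = 3) {
  dec <- decimate(bandpass(session$recording), 4)
  ep <- epoch_recording(dec)
  xd <- fit_xdawn(t(dec$data), dec$markers, epoch_len = dim(ep$epochs)[3],
                  k = k)
  list(dec = dec, ep = ep, xd = xd, feats = apply_xdawn(xd, ep))
}

# The full-scale study session: 64 channels, 15 characters, generator
# defaults (amp 5 uV, pink 2 uV). Used by the xDAWN recovery and decoding
# acceptance checks.
full_session <- function() cached("full_session", {
  g <- speller_grid()
  set.seed(11)
  targets <- sample(names(g$row_of), 15, replace = TRUE)
  synthesize_session(g, targets, training_timing(), synth_config(seed = 5))
})

full_pipeline <- function() cached("full_pipeline", fitted_pipeline(full_session()))

small_pipeline <- function() cached("small_pipeline", {
  ses <- cached("small_ses", small_session(n_chars = 6, n_channels = 16,
                                           seed = 3))
  c(list(session = ses), fitted_pipeline(ses))
})

# Printed per-participant result rows used as aggregation inputs
# (sensitivity / precision / specificity / F for the two detectors, and
# the cross-validation accuracy rows).
published_rows <- function() {
  list(
    lda = data.frame(
      sensitivity = c(0.5170, 0.6560, 0.5140, 0.4940, 0.4780, 0.6560, 0.6250, 0.5690),
      precision   = c(0.9282, 0.9563, 0.9362, 0.9165, 0.8968, 0.9704, 0.9843, 0.9192),
      specificity = c(0.9920, 0.9940, 0.9930, 0.9910, 0.9890, 0.9960, 0.9980, 0.9900),
      f_measure   = c(0.6641, 0.7782, 0.6637, 0.6420, 0.6236, 0.7828, 0.7645, 0.7029)),
    svm = data.frame(
      sensitivity = c(0.6440, 0.8190, 0.7030, 0.6360, 0.8000, 0.8030, 0.7170, 0.6830),
      precision   = c(0.9083, 0.9010, 0.9336, 0.9550, 0.9816, 0.9305, 0.9111, 0.8723),
      specificity = c(0.9870, 0.9820, 0.9900, 0.9940, 0.9970, 0.9880, 0.9860, 0.9800),
      f_measure   = c(0.7537, 0.8580, 0.8021, 0.7635, 0.8815, 0.8621, 0.8025, 0.7661)),
    cv = rbind(
      lda = c(88.29, 92.27, 88.61, 86.94, 86.76, 92.27, 91.62, 89.68),
      svm = c(88.84, 93.70, 90.37, 89.07, 86.90, 92.22, 92.50, 90.97),
      mlp = c(16.67, 90.03, 17.33, 11.19, 12.25, 87.39, 86.75, 84.75)))
}

# Minimal BrainVision triplet written into dir; returns the .vhdr path.
# Sine + ramp test signal, 3 channels, 4 stimulus markers.
write_brainvision_fixture <- function(dir, binary_format = "INT_16",
                                      orientation = "MULTIPLEXED") {
  n_ch <- 3L; n_s <- 200L; fs <- 500
  data <- rbind(round(100 * sin(2 * pi * 5 * (0:(n_s - 1)) / fs)),
                seq_len(n_s),
                rep(-7L, n_s))
  vhdr <- file.path(dir, "fix.vhdr")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "DataFile=fix.eeg",
    "MarkerFile=fix.vmrk",
    "DataFormat=BINARY",
    paste0("DataOrientation=", orientation),
    paste0("NumberOfChannels=", n_ch),
    "SamplingInterval=2000",
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "[Channel Infos]",
    "Ch1=Cz,,1,uV",
    "Ch2=Pz,,0.5,uV",
    "Ch3=Oz,,1,uV"), vhdr)
  writeLines(c(
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0",
    "Mk2=Stimulus,S  1,11,1,0",
    "Mk3=Stimulus,S  2,51,1,0",
    "Mk4=Stimulus,S  1,101,1,0",
    "Mk5=Stimulus,S  3,151,1,0"), file.path(dir, "fix.vmrk"))
  con <- file(file.path(dir, "fix.eeg"), "wb")
  vals <- if (orientation == "MULTIPLEXED") as.vector(data) else
    as.vector(t(data))
  if (binary_format == "INT_16") {
    writeBin(as.integer(vals), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
  close(con)
  list(vhdr = vhdr, data = data, fs = fs)
}
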