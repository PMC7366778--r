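Package: p300speller
Title: Simulation and Decoding of P300 Speller Brain-Computer Interface Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for event-related-potential brain-computer interfaces built
    around the 6x6 P300 speller paradigm. Generates row/column flash schedules
    with the standard oddball timing, synthesizes 64-channel EEG sessions with
    a planted P300 response in structured (pink + alpha + white) noise,
    preprocesses recordings (causal Butterworth bandpass, decimation,
    stimulus-locked epoching), enhances evoked responses with xDAWN spatial
    filters obtained from the signal-to-signal-plus-noise-ratio generalized
    eigenproblem, detects target flashes with Fisher discriminant,
    polynomial-kernel support-vector, and multilayer-perceptron classifiers,
    decodes characters from aggregated row/column scores, and evaluates
    performance with confusion-matrix statistics and the Shannon information
    transfer rate. Includes a native session file format, a BrainVision
    importer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
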