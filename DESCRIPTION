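Package: eegfocus
Title: Seizure Detection and Epileptic-Focus Lateralization from Scalp EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage decision-support pipeline for temporal lobe epilepsy
    from multichannel scalp EEG on a bipolar 10-20 montage. Stage one detects
    ictal (seizure) epochs with a small LSTM classifier fed per-channel
    wavelet-subband energy features from a nine-level db4 decomposition.
    Stage two lateralizes the epileptic focus (left vs right hemisphere)
    through an energy asymmetry score over the eight symmetric bipolar
    channel pairs, with majority voting at the recording and patient level.
    Includes EDF and plain-matrix readers, Butterworth/notch preprocessing,
    a synthetic EEG cohort generator with known ictal intervals and focus
    side, and a band-sweep experiment harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
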