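Package: slowdrift
Title: Linking Prestimulus EEG Alpha Power to Slow Drift in Neuronal Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline relating scalp-EEG prestimulus alpha power to a
    low-dimensional "slow drift" in population spiking activity and to
    arousal-linked eye metrics (pupil diameter, microsaccade rate) over the
    course of long recording sessions. Provides a synthetic-session generator
    with a shared slow arousal latent; microsaccade detection with a
    median-based velocity threshold; Hanning-windowed prestimulus spectra with
    aperiodic (1/f) removal and band power; PCA extraction of slow drift from
    orientation-residualized spike counts; cross-validated Gaussian-smoothing
    timescale estimation; and session-level nonparametric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
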