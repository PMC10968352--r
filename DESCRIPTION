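Package: asymswb
Title: EEG Band-Power Asymmetry and Short-Term Subjective Well-Being
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate hemispheric asymmetries of electroencephalography
    (EEG) band power to short-term subjective well-being (SWB) ratings. The
    package computes per-epoch natural-log band-power asymmetries between
    contralateral channels or scalp quadrants from Welch power spectral
    densities, under the original or a posterior re-referenced montage, and
    runs a class-balanced regression group inference: per-participant SMOTE
    balancing of the SWB classes, repeated least-squares fits with averaged
    slopes, a one-sample t-test of the participant slopes, and
    Benjamini-Yekutieli false-discovery-rate control across the tested
    channel-pair x band family. A synthetic-data module generates band-limited
    EEG with a configurable, known asymmetry-SWB coupling so the full pipeline
    can be exercised and calibrated without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
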