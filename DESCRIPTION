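Package: BCGcar
Title: Hypertension Screening from Ballistocardiogram Signals with Class
    Association Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for identifying hypertensive subjects from
    single-channel mattress ballistocardiogram (BCG) recordings. Provides
    BCG signal conditioning (z-score normalization, elliptic bandpass
    filtering, undecimated db6 wavelet approximation) and heartbeat
    detection by overlapping sliding windows; extraction of fourteen
    features covering time-, frequency- and non-linear-domain heart rate
    variability (mean RR, SDNN, RMSSD, pNN50, vLF/LF/HF band powers,
    LF/HF ratio, sample entropy, detrended fluctuation analysis) together
    with four BCG fluctuation descriptors (zero crossing rate, average
    cumulative amplitude change, average number of extreme points,
    average signal turns count); an Apriori-style class association rule
    miner with equal-width discretization; a database-coverage rule
    classifier with precedence sorting and a default class; repeated
    stratified evaluation utilities; and a synthetic BCG generator with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
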