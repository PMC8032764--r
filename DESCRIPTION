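Package: neuropkpd
Title: Receptor Occupancy, PET Kinetics and Pharmaco-EEG Target-Engagement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for establishing CNS target engagement of a
    receptor-subtype-selective drug: four-parameter Hill concentration-response
    fitting with Cheng-Prusoff conversion and fold-selectivity ratios; ex vivo
    autoradiography receptor-occupancy quantification with exposure-occupancy
    Hill and Emax fits (profile-likelihood intervals); simplified reference
    tissue model (SRTM) forward simulation and basis-function fitting of framed
    PET time-activity curves with occupancy from binding-potential reduction;
    and a log-frequency Morlet-wavelet resting-EEG pipeline (alpha-peak
    alignment, relative power, drug-vs-baseline change) with cluster-based
    randomization tests, jackknife pseudo-value peak-frequency estimates and
    topography-similarity randomization. Includes synthetic-data generators
    with known ground truth for every stage and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm
Config/testthat/edition: 3
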