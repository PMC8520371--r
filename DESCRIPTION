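Package: fhrdoppler
Title: Fetal Heart Rate Detection from Ultrasound Doppler Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of ultrasound Doppler fetal heart rate
    (FHR) signals. Generates synthetic Doppler audio with known ground-truth
    heart rate from the reflected-wave Doppler shift relation, demodulates the
    echo to a beat envelope, and estimates heart rate by windowed
    autocorrelation sampled at precomputed lag serial numbers from a heart
    rate correspondence table (with an average magnitude difference
    alternative). Also classifies umbilical-artery end-diastolic flow
    waveforms into selective fetal growth restriction (sFGR) Doppler types
    I-III, applies the small-for-gestational-age 10th-percentile screening
    rule, and provides summary-statistics group comparisons (two-sample t
    from printed summaries, rank-sum Z, Fisher/chi-square) for twin cohort
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tools,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
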