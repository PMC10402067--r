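Package: ccturnover
Title: Residence-Time Inference from Competition ChIP Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating transcription-factor chromatin residence
    times from competition ChIP (CC) time-course data. Fits a Hill model to
    competitor-protein induction curves with integer Hill coefficients chosen
    by adjusted R-squared, normalizes per-site HA/Myc ChIP-seq count matrices
    into occupancy-ratio series, fits a coupled mass-action turnover model by
    numerical ODE integration to recover per-site off-rates and residence
    times, applies reliability filters and a reliably-fast classifier, assigns
    peak regions to promoters, and summarizes transcription efficiency
    (mRNA per binding event) across synthesis-rate quartiles. Includes a
    seeded synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
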