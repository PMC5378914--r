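Package: glomsep
Title: Odor Pattern Separation Analysis for Honeybee Antennal Lobe Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ratiometric (FURA-2) calcium-imaging studies
    of olfactory learning in the honeybee antennal lobe. Converts dual-wavelength
    fluorescence movies into baseline-normalized ratio signals with rigid movement
    correction, segments glomerular regions of interest by Z-scoring, Gaussian
    smoothing, PCA and convex-cone factorization, and extracts per-glomerulus
    time courses. Quantifies odor representations per bee: Euclidean-distance
    pattern separation traces, early-window separation, the 3x-SD distinct-pattern
    criterion, responsive-glomerulus percentages, dominant-glomerulus response
    strength, and extinction-trial stability. Scores M17 muscle recordings as
    baseline-normalized spike rates, and runs a normality-gated test-selection
    workflow (Shapiro-Wilk and F-test gates choosing t, Mann-Whitney U or
    Wilcoxon signed-rank tests) with Cohen's d effect sizes. A synthetic-data
    generator emulates the full recording and cohort structure with planted,
    calibrated treatment effects so that every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
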