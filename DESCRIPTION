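Package: cardiofunc
Title: Quantitative Phenotyping of iPSC-Derived Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative functional phenotyping of induced
    pluripotent stem cell derived cardiomyocytes (iPSC-CMs): Fourier-based
    scoring of sarcomere organization ("power" and "period") from
    immunofluorescence images, extraction of calcium-transient kinetics
    (beat rate, amplitude, rise time, decay tau, diastolic level) from
    single-channel and ratiometric Fura-2 traces, block-matching motion
    analysis of beating-monolayer videos (contraction and relaxation peak
    velocities, beating-area fraction), and the downstream group statistics
    used in such studies (one- and two-way ANOVA with Holm-Sidak step-down
    post hoc comparisons, and 2^-ddCt relative expression). A seed-controlled
    synthetic-data generator produces striation images, calcium traces and
    beating videos with known ground truth so that every analysis stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    withr,
    utils,
    ggplot2,
    generics,
    stats,
    pracma,
    minpack.lm,
    car,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
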