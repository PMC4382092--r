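Package: kdrfitness
Title: Selection and Dominance of the Kdr Resistance Allele from
    Wind-Tunnel Host-Seeking Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for wind-tunnel hole-penetration assays of
    Anopheles gambiae carrying the Kdr (L1014F) pyrethroid-resistance
    mutation. Tabulates per-trial outcomes (success, failure alive, failure
    knocked-down) by genotype and net treatment; computes Wilson score and
    Sison-Glaz simultaneous confidence intervals; fits saturated binomial
    and multinomial logistic outcome models with all pairwise odds ratios;
    and estimates selection (s) and dominance (h) coefficients of the
    resistance allele by a Monte-Carlo cloud profile likelihood with
    likelihood-ratio confidence intervals. Includes a seeded generator of
    synthetic trial data with the generative structure the analysis assumes,
    and a bundled reconstruction of a published genotype-by-treatment count
    table for worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
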