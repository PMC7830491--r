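Package: csiaa
Title: Compound-Specific Amino Acid Isotope Analysis for Coral Trophic Ecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compound-specific stable isotope analysis of amino
    acids (CSIA-AA) in the coral-dinoflagellate symbiosis. Simulates
    GC-C-IRMS peak tables for host and symbiont fractions under autotrophic,
    mixotrophic and heterotrophic nutrition; inverts the instrument layer
    (derivatization carbon correction, linear sequence drift, certified
    standard regression calibration of delta-15N); computes trophic position
    from the glutamic acid - phenylalanine delta-15N spread; and runs the
    accompanying statistical battery (Kruskal-Wallis with pairwise Wilcoxon
    and Benjamini-Hochberg adjustment, two-way ANOVA with Tukey HSD,
    Euclidean-distance PERMANOVA, and nMDS ordination). All results are
    returned as tibbles with broom-style tidy() and glance() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
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
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
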