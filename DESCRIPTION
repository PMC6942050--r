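Package: acrodj
Title: Comparative Structural Analysis of Acrocentric Distal-Junction Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the distal-junction (DJ) regions that lie
    immediately telomeric of the ribosomal DNA arrays on human acrocentric
    chromosome short arms. Provides windowed percent-identity profiling of
    long contigs via anchored unit-cost alignment, annotation of the DJ
    architecture (48-bp CER satellite arrays, long inverted repeats, foreign
    insertions embedded in satellite blocks), indel calling with
    left-normalised breakpoints, four-gamete inference of exchanges between
    heterologous chromosomes, distance-based grouping of contigs, and
    rDNA/DJ junction and far-distal homology-block analysis. A synthetic
    cohort generator with a full ground-truth manifest makes every stage
    testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    ape,
    stats,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
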