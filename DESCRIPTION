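Package: mpratile
Title: Tiling Motif-Shuffle MPRA Design and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis of tiling motif-shuffle massively parallel
    reporter assays (MPRA) for cis-regulatory elements, as applied to the
    X-linked MECP2 regulatory landscape. Builds saturation motif-shuffle
    libraries (overlapping 270 bp tiles, FIMO-style PWM scanning with exact
    dynamic-programming p-values, seeded linear motif shuffles, variant
    insertion), estimates per-element log2(RNA/DNA) activity from barcode
    count tables, tests shuffle effects against matched reference tiles with
    a Monte Carlo Dunnett many-to-one procedure, calls activator- and
    repressor-binding hotspots by a binned coverage-and-fraction rule,
    attributes activity to sequence k-mers with the Brunner-Munzel rank test
    and PWM matching, filters pedigrees for private maternally transmitted
    X-linked variants, and classifies proband variants against population
    control calibration. A seeded synthetic-data generator produces
    truth-annotated fixtures (planted motifs, negative-binomial and Poisson
    barcode counts, cohort VCF/PED) so the whole pipeline is testable
    without external data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    Biostrings,
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
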