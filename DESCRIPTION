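Package: dsrnaforge
Title: Design and Efficacy Analysis of dsRNA Insecticides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for species-specific double-stranded RNA (dsRNA)
    insecticide design and efficacy analysis. Enumerates all 21-mers of a
    target transcript, screens them for perfect 20/21-nt matches against
    non-target transcriptomes via a canonical k-mer index, selects the
    longest target-specific region and designs ranked long-dsRNA candidates
    with a per-siRNA rationality score. Companion efficacy statistics cover
    right-censored feeding-trial survival (Kaplan-Meier curves, Cox
    proportional-hazards regression with Efron/Breslow tie handling),
    Henderson-Tilton corrected field mortality, leaf-damage and emergence
    metrics, and standard-curve qPCR quantification of gene silencing with
    limit-of-quantification and inhibition checks. Seeded synthetic-data
    generators provide ground truth for every analysis path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
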