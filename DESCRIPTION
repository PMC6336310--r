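Package: igfactorial
Title: Factorial Analysis of Immunoglobulin Repertoires from Bulk AIRR-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterization of splenic B-cell receptor repertoires from
    annotated AIRR Rearrangement data under a 2x2x2 treatment design
    (skeletal unloading x tetanus toxoid x CpG adjuvant). Implements
    fractional gene-segment abundance with ambiguous-call weighting,
    CDR3 junction motif and class-switch classification, V(D)J pairing
    with undetermined-segment rules, percent-of-repertoire usage tables,
    CDR3 clonotype sharing and overlap analysis, per-animal repertoire
    variance, three-way factorial ANOVA with Tukey post-hoc contrasts,
    and a fold-change marker screen on TPM expression tables. Includes a
    seeded synthetic-repertoire generator emulating the study design so
    every analysis stage is testable without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
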