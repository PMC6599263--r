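Package: crcevo
Title: Longitudinal Mutational and Neoantigen Evolution in Colorectal
    Cancer Models
Version: 0.1.0
Authors@R:
    person("crcevo", "developers", email = "crcevo@example.org",
           role = c("aut", "cre"))
Description: Tools to track the longitudinal evolution of somatic mutations
    and predicted neoantigens in DNA-repair-deficient colorectal cancer
    models (cell lines and patient-derived xenografts). Implements a somatic
    variant filter cascade (strand support, allelic-frequency and exact
    binomial read-support tests, germline/artifact key lists),
    timepoint and lineage subtraction of variant catalogs, tumor mutational
    burden, 96-channel trinucleotide mutational spectra with nonnegative
    least-squares signature refitting and average-linkage clustering,
    mutant-peptide enumeration with pluggable MHC binding prediction and
    expression filtering, a two-step ploidy estimator (relative gene copy
    number, circular binary segmentation, allelic-frequency peak matching),
    doubling-time and per-day mutation-rate arithmetic with an
    evolving/stable classification, a differential-expression significance
    filter, and a seeded synthetic-data generator that emulates
    mismatch-repair-deficient, POLE-mutant, MUTYH-mutant and stable tumor
    genomes so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
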