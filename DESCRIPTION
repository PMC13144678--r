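Package: promrec
Title: Context-Aware Recombination of Promoters with Transcription
    Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for context-aware insertion of transcription factor
    binding sites (TFBSs) into native promoter sequences. Implements a
    two-stage neural system: self-supervised Place-Back models that
    localize where a query sequence fits within a 400 bp promoter as a
    per-base probability track, and a Determiner ensemble that selects
    the rewrite length (5 or 40 bp) and the 40 bp insertion region. A
    consensus screening engine turns the models' outputs into concrete,
    ranked promoter rewrite proposals. Includes promoter extraction from
    genome FASTA plus GFF annotation, a seeded synthetic-corpus
    generator, base-level precision/recall evaluation with an exact
    random-placement baseline, and luciferase/growth assay metrics for
    validating engineered promoters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
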