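Package: wgsmut
Title: Downstream Mutation-Landscape Analysis for Tumor/Normal Whole-Genome
    Sequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Offline downstream analysis of paired tumor/normal whole-genome
    sequencing variant calls: per-sample region and functional mutation
    tallies, six-class and 96-trinucleotide-context mutation spectra with
    non-negative matrix factorization (NMF) signature extraction,
    Fisher's-exact-test screening for significantly mutated genes,
    genome-binned copy-number recurrence scoring with a permutation null,
    and a five-step germline cancer-susceptibility filtering cascade with
    per-gene carrier frequencies. A fully seeded synthetic-cohort generator
    (reference sequence, gene models, signature-mixture somatic variants,
    population-frequency-annotated germline variants, and copy-number
    segments with planted recurrent regions) provides ground truth so the
    whole pipeline can be run and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
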