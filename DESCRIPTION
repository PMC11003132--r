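Package: ensemblevar
Title: Ensemble Structural-Variant Genotyping: VCF Merging, Consensus Calling and Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ensemble genotyping of SNPs, indels and structural
    variants from the outputs of multiple graph-based genotypers. Normalizes
    and filters population VCFs (symbolic-allele resolution, MAF and
    missing-rate filters), selects a genotyper panel from genome size, read
    length and sequencing depth, clusters per-genotyper calls against the
    input variant set with class-specific position and length-ratio
    thresholds, Z-score-normalizes per-tool read depths, and emits one
    consensus genotype per input variant. Includes a benchmarking evaluator
    (presence- and genotype-level matching with breakpoint and size
    tolerances, precision/recall/F-score, threshold-swept precision-recall
    curves, stratification by variant length or BED regions) and a synthetic
    data module that spikes variants into a random reference and emulates
    noisy genotyper outputs so the whole pipeline is testable without
    running any external genotyper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
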