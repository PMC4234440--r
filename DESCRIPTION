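Package: arrayforge
Title: Design and Evaluation of SNP Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing high-density SNP genotyping arrays from
    re-sequencing candidate pools and for evaluating the resulting arrays from
    genotype data. Implements the candidate-reduction cascade used in probe
    design (call-quality thresholds, flanking-sequence homopolymer and GC
    screens, k-mer uniqueness against the reference, close-proximity removal,
    probe conversion-score thresholding), category-prioritised greedy spacing
    selection with per-class minimum inter-marker distances, marker performance
    classification from call rates and genotype class counts, trio-based
    Mendelian consistency checking, linkage-disequilibrium decay estimation,
    and identity-by-state clustering via classical multidimensional scaling.
    A synthetic-data generator produces reference genomes, candidate variant
    pools with planted filter violations, and structured genotype matrices
    (populations, families, tunable LD decay) so that every pipeline stage can
    be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    jsonlite
Config/testthat/edition: 3
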