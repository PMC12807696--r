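Package: haploscore
Title: Haplotype-Resolved Proteoforms and Fitness Scores from Phased Cohort Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs haplotype-resolved protein-coding sequences from
    phased cohort genotypes and transcript annotations, translates them under
    explicit rules for disruptive variants (start-loss rescue at the next
    in-frame ATG, premature-stop truncation, frameshift readthrough),
    computes global and super-population haplotype frequencies with a
    retention filter, and scores each proteoform with pseudo-log-likelihood
    based fitness metrics (PLLR relative to the wild-type and most-frequent
    haplotypes, and a transcript-level max-minus-min PLL dispersion score)
    through a pluggable scorer interface. Includes logit-scale aggregation of
    per-variant pathogenicity probabilities, bootstrap-of-the-median group
    comparisons, and a synthetic cohort generator with exact ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
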