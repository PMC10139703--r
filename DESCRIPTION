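Package: methdiv
Title: Differential DNA Methylation and Pooled-Sequencing Nucleotide Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links differential CpG methylation between diverging populations
    to standing genetic variation estimated from pooled whole-genome
    sequencing. Reads per-CpG bisulfite coverage files, applies SNP masking
    and coverage/invariance site filters, classifies sites as differentially
    methylated (hypo/hyper) or environmentally inducible from treatment
    comparisons, parses pool-seq pileups into quality-filtered allele counts,
    and computes pool-size-corrected nucleotide diversity (pi, Watterson's
    theta, Tajima's D), pairwise Fst, and C-T/G-A transition attribution over
    methylation-defined site categories and ranks. Includes distance-matched
    non-DMC subsampling, paired per-chromosome statistics with a
    Shapiro-Wilk normality gate, linear trend fits over rank profiles, and a
    synthetic-data generator with exact ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
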