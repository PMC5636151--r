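Package: admixbench
Title: Simulated Admixed Tumor Genomes and SNV Caller Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds synthetic tumor sequencing experiments with exactly known
    ground truth and scores variant callers against it. Germline and somatic
    variants are implanted into a reference genome to produce maternal and
    paternal haplotypes and a set of subclonal cancer genomes; subclones are
    combined in randomized proportions and diluted with control material
    across an admixture series, giving every variant a closed-form expected
    allele frequency. A targeted paired-end read simulator with a
    substitution/insertion/deletion error model produces FASTQ and truth
    alignments, a minimal pileup-based binomial caller closes the loop, and
    an evaluator computes sensitivity, precision, harmonic-mean parameter
    selection, admixture response curves and multi-caller concordance for
    any VCF callset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
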