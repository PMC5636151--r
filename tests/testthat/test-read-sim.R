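# A one-genome pool over a plain reference (no variants) for basic checks.
plain_pool <- function(ref) {
  empty <- make_variants(character(0), integer(0), character(0),
                         character(0), character(0))
  hap <- implant_variants(ref, empty, label = "control")
  admixed_genome_pool(list(maternal = hap, paternal = hap))
}

test_that("fragment planning follows the coverage closed form", {
  t1 <- target_regions(tibble::tibble(contig = "chr1", start = 0,
                                      end = 10000))
  cfg <- read_sim_config("exome", coverage = 70)
  expect_identical(plan_fragment_count(cfg, t1), 3500L)
  t2 <- target_regions(tibble::tibble(contig = "chr1", start = 0,
                                      end = 2000))
  cfg2 <- read_sim_config("panel", coverage = 520)
  expect_identical(plan_fragment_count(cfg2, t2), 5200L)
  expect_error(plan_fragment_count(cfg, t1[0, ]), "empty")
})

test_that("config invariants are enforced", {
  expect_error(read_sim_config(read_length = 400), "insert_mean")
  expect_error(read_sim_config(sub_rate = 0.5), "error rates")
  expect_error(read_sim_config(coverage = 0), "coverage")
  p <- read_sim_config("panel")
  expect_equal(p$insert_mean, 200)
  expect_equal(p$coverage, 520)
})

test_that("realized median on-target coverage is close to the request", {
  # intervals long relative to the insert so capture-flank losses are small
  ref <- simulate_reference(1, 20000, seed = 1)
  targets <- target_regions(tibble::tibble(
    contig = "chr1", start = c(2000, 10000), end = c(7000, 15000)))
  cfg <- read_sim_config("exome", coverage = 60, sub_rate = 0, ins_rate = 0,
                         del_rate = 0, seed = 3)
  reads <- simulate_reads(plain_pool(ref), targets, cfg)
  med <- median_target_coverage(reads, targets)
  expect_gt(med, 0.9 * 60)
  expect_lt(med, 1.1 * 60)
})

test_that("simulation is deterministic under the seed, FASTQ byte-identical", {
  ref <- simulate_reference(1, 8000, seed = 5)
  targets <- simulate_targets(ref, 4, 400, seed = 6)
  cfg <- read_sim_config("exome", coverage = 20, seed = 42)
  r1 <- simulate_reads(plain_pool(ref), targets, cfg)
  r2 <- simulate_reads(plain_pool(ref), targets, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  d <- withr::local_tempdir()
  write_fastq(r1, file.path(d, "a"))
  write_fastq(r2, file.path(d, "b"))
  expect_identical(readLines(file.path(d, "a_1.fastq")),
                   readLines(file.path(d, "b_1.fastq")))
  cfg2 <- read_sim_config("exome", coverage = 20, seed = 43)
  r3 <- simulate_reads(plain_pool(ref), targets, cfg2)
  expect_false(identical(r1$seq, r3$seq))
})

test_that("a pure control pool shows no somatic allele above the error rate", {
  ref <- simulate_reference(1, 6000, seed = 7)
  targets <- target_regions(tibble::tibble(contig = "chr1", start = 2000,
                                           end = 4000))
  # somatic SNV exists only in the (absent) tumor; pool is pure control
  cfg <- read_sim_config("panel", coverage = 300, sub_rate = 0,
                         ins_rate = 0, del_rate = 0, seed = 8)
  reads <- simulate_reads(plain_pool(ref), targets, cfg)
  d <- withr::local_tempdir()
  sam <- file.path(d, "r.sam")
  write_truth_sam(reads, ref, sam)
  pu <- pileup_counts(sam)
  site <- pu[pu$pos == 3000, ]
  refb <- substring(ref[["chr1"]], 3000, 3000)
  expect_gt(site$depth, 100)
  expect_identical(sum(site[setdiff(c("A", "C", "G", "T"), refb)]), 0L)
})

test_that("het germline and diluted somatic alleles recover their expected AF", {
  ref <- simulate_reference(1, 6000, seed = 9)
  targets <- target_regions(tibble::tibble(contig = "chr1", start = 2000,
                                           end = 4000))
  het <- make_variants("chr1", 3000L, substring(ref[["chr1"]], 3000, 3000),
                       setdiff(c("A", "C", "G", "T"),
                               substring(ref[["chr1"]], 3000, 3000))[1],
                       "SNV", origin = "germline", id = "g1")
  empty <- make_variants(character(0), integer(0), character(0),
                         character(0), character(0))
  hap_mat <- implant_variants(ref, het, label = "maternal")
  hap_pat <- implant_variants(ref, empty, label = "paternal")
  cfg <- read_sim_config("panel", coverage = 1200, sub_rate = 0,
                         ins_rate = 0, del_rate = 0, seed = 10)
  pool <- admixed_genome_pool(list(maternal = hap_mat, paternal = hap_pat))
  reads <- simulate_reads(pool, targets, cfg)
  d <- withr::local_tempdir()
  write_truth_sam(reads, ref, file.path(d, "het.sam"))
  pu <- pileup_counts(file.path(d, "het.sam"))
  site <- pu[pu$pos == 3000, ]
  altb <- het$alt
  frac <- site[[altb]] / site$depth
  se <- sqrt(0.5 * 0.5 / site$depth)
  expect_lt(abs(frac - 0.5), 3 * se)

  # clonal somatic variant (in every cancer genome) at 90% admixture
  som <- make_variants("chr1", 3500L, substring(ref[["chr1"]], 3500, 3500),
                       setdiff(c("A", "C", "G", "T"),
                               substring(ref[["chr1"]], 3500, 3500))[1],
                       "SNV", origin = "somatic", id = "s1")
  cancer_hap <- implant_variants(ref, som, label = "tumor")
  control <- list(maternal = implant_variants(ref, empty, "cm"),
                  paternal = implant_variants(ref, empty, "cp"))
  cancer <- list(maternal = rep(list(cancer_hap), 2),
                 paternal = rep(list(cancer_hap), 2))
  mixture <- draw_mixture(2, seed = 11)
  cfg2 <- read_sim_config("panel", coverage = 2500, sub_rate = 0,
                          ins_rate = 0, del_rate = 0, seed = 12)
  pool2 <- admixed_genome_pool(control, cancer, mixture, admixture = 0.9)
  reads2 <- simulate_reads(pool2, targets, cfg2)
  write_truth_sam(reads2, ref, file.path(d, "som.sam"))
  pu2 <- pileup_counts(file.path(d, "som.sam"))
  site2 <- pu2[pu2$pos == 3500, ]
  frac2 <- site2[[som$alt]] / site2$depth
  expect_gt(site2$depth, 2000)
  se2 <- sqrt(0.1 * 0.9 / site2$depth)
  expect_lt(abs(frac2 - 0.10), 3 * se2)
})

test_that("sequencing mismatch rate recovers the configured sub_rate", {
  ref <- simulate_reference(1, 10000, seed = 13)
  targets <- simulate_targets(ref, 5, 800, seed = 14)
  cfg <- read_sim_config("exome", coverage = 120, sub_rate = 5e-3,
                         ins_rate = 0, del_rate = 0, seed = 15)
  reads <- simulate_reads(plain_pool(ref), targets, cfg)
  # compare each read (genome orientation) with the reference
  mism <- 0L; tot <- 0L
  for (i in seq_len(nrow(reads))) {
    rseq <- strsplit(reads$seq[i], "")[[1]]
    tseq <- strsplit(substring(ref[["chr1"]], reads$ref_pos[i],
                               reads$ref_pos[i] + length(rseq) - 1L),
                     "")[[1]]
    mism <- mism + sum(rseq != tseq)
    tot <- tot + length(rseq)
  }
  rate <- mism / tot
  expect_lt(abs(rate - 5e-3) / 5e-3, 0.1)
})

test_that("truth alignments carry correct CIGARs and pairing flags", {
  ref <- c(chr1 = strrep("ACGT", 2500))
  targets <- target_regions(tibble::tibble(contig = "chr1", start = 4000,
                                           end = 6000))
  empty <- make_variants(character(0), integer(0), character(0),
                         character(0), character(0))
  cfg <- read_sim_config("exome", coverage = 30, sub_rate = 0,
                         ins_rate = 0, del_rate = 0, seed = 16)
  reads <- simulate_reads(plain_pool(ref), targets, cfg)
  expect_true(all(reads$cigar == "100M"))
  d <- withr::local_tempdir()
  sam <- file.path(d, "t.sam")
  write_truth_sam(reads, ref, sam)
  lines <- grep("^@", readLines(sam), value = TRUE, invert = TRUE)
  f <- as.integer(vapply(strsplit(lines, "\t"), `[[`, character(1), 2))
  qn <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  rev_by_pair <- tapply(bitwAnd(f, 16L) > 0, sub(":[12]$", "", qn), sum)
  expect_true(all(rev_by_pair == 1)) # exactly one reverse mate per pair
  # reads spanning an implanted insertion contain an I operation
  ins <- make_variants("chr1", 5000L, "", "TTT", "INS", id = "i1")
  hap <- implant_variants(ref, ins, label = "ins")
  pool <- admixed_genome_pool(list(maternal = hap, paternal = hap))
  reads2 <- simulate_reads(pool, targets, cfg)
  span <- reads2$mapped & reads2$ref_pos < 4990 &
    reads2$ref_pos + 99 > 5010
  expect_gt(sum(span), 0)
  expect_true(all(grepl("3I", reads2$cigar[span])))
  # and the SAM round-trips through samtools-based pileup without error
  write_truth_sam(reads2, ref, file.path(d, "ins.sam"))
  pu <- pileup_counts(file.path(d, "ins.sam"))
  expect_gt(nrow(pu), 0)
})
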