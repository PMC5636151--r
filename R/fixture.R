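#' Simulate a random reference genome
#'
#' Uniform-random contigs at a configurable GC fraction — a small stand-in
#' for a real reference on which the whole pipeline can run end to end.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bases.
#' @param gc GC fraction.
#' @param seed Integer seed.
#' @return Named character vector (`chr1`, `chr2`, ...).
#' @export
simulate_reference <- function(n_contigs = 1, contig_length = 5e4,
                               gc = 0.41, seed = 1L) {
  stopifnot(n_contigs >= 1, contig_length >= 1, gc >= 0, gc <= 1)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seq_len(n_contigs), function(i) {
      paste(sample(DNA_BASES, contig_length, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    stats::setNames(seqs, paste0("chr", seq_len(n_contigs)))
  })
}

#' Simulate a capture target design
#'
#' Non-overlapping intervals of roughly constant length placed uniformly
#' along each contig, emulating exon- or panel-style capture targets.
#'
#' @param reference Named character vector.
#' @param n_intervals Total intervals across the genome.
#' @param interval_length Mean interval length (each drawn uniform in
#'   `[0.5, 1.5] *` this value).
#' @param seed Integer seed.
#' @return A [target_regions()] tibble.
#' @export
simulate_targets <- function(reference, n_intervals = 20,
                             interval_length = 400, seed = 1L) {
  with_seed(seed, {
    rows <- list()
    clen <- nchar(reference)
    per <- diff(round(seq(0, n_intervals, length.out = length(clen) + 1)))
    for (ci in seq_along(clen)) {
      n <- per[ci]
      if (n == 0) next
      len <- pmax(20L, as.integer(round(stats::runif(n, 0.5, 1.5) *
                                          interval_length)))
      # anchor intervals on an even grid with jitter, then merge overlaps
      grid <- round(seq(1, clen[ci] - max(len), length.out = n))
      start0 <- pmax(0L, as.integer(grid +
                                      round(stats::runif(n, -0.2, 0.2) *
                                              interval_length)) - 1L)
      end0 <- pmin(clen[ci], start0 + len)
      rows[[ci]] <- tibble(contig = names(clen)[ci], start = start0,
                           end = end0)
    }
    target_regions(bind_rows(rows))
  })
}

#' Simulate germline and somatic variant lists over a reference
#'
#' Variants are placed uniformly within target regions plus flanks,
#' non-overlapping, with reference-consistent alleles and never on an N.
#' Germline variants carry a `lineage` column: heterozygous variants sit on
#' one parental haplotype (maternal or paternal, equal odds), homozygous
#' ones on both, with the heterozygous fraction set by `het_hom_ratio`.
#' Somatic records emulate known cancer SNVs spiked into the tumor; in
#' hypermutation mode their count inside targets is multiplied to keep
#' false-negative analyses statistically reliable on small panels.
#'
#' @param reference Named character vector.
#' @param targets A [target_regions()] tibble.
#' @param n_germline Germline variant count.
#' @param germline_indel_fraction Fraction of germline variants that are
#'   indels (split evenly INS/DEL, lengths 1-6).
#' @param het_hom_ratio Ratio het:hom among germline variants (e.g. 2 means
#'   two het for every hom).
#' @param n_somatic Somatic SNV count (before any multiplier).
#' @param hypermutation_multiplier Multiplies `n_somatic`.
#' @param flank Bases around each target interval eligible for placement.
#' @param seed Integer seed.
#' @return A [variant_table()] tibble with the extra `lineage` column.
#' @export
simulate_variant_table <- function(reference, targets, n_germline = 100,
                                   germline_indel_fraction = 0.1,
                                   het_hom_ratio = 2, n_somatic = 50,
                                   hypermutation_multiplier = 1,
                                   flank = 100, seed = 1L) {
  stopifnot(het_hom_ratio >= 0, germline_indel_fraction >= 0,
            germline_indel_fraction <= 1, hypermutation_multiplier >= 1)
  n_somatic <- as.integer(round(n_somatic * hypermutation_multiplier))
  with_seed(seed, {
    # eligible 1-based positions: targets +/- flank
    elig <- list()
    for (ctg in unique(targets$contig)) {
      t <- targets[targets$contig == ctg, , drop = FALSE]
      lo <- pmax(1L, t$start + 1L - flank)
      hi <- pmin(nchar(reference[[ctg]]) - 8L, t$end + flank)
      pos <- unique(unlist(mapply(seq, lo, hi, SIMPLIFY = FALSE)))
      elig[[ctg]] <- sort(pos)
    }
    n_total <- n_germline + n_somatic
    avail <- sum(lengths(elig))
    if (n_total * 8 > avail) {
      abort("requested variant count exceeds placeable sites in targets")
    }
    ctg_of <- rep(names(elig), lengths(elig))
    pos_all <- unlist(elig, use.names = FALSE)
    # enforce >= 8 bp spacing so indels up to length 6 cannot collide
    picked <- sample.int(length(pos_all), min(4L * n_total,
                                              length(pos_all)))
    ord <- order(ctg_of[picked], pos_all[picked])
    picked <- picked[ord]
    keep <- logical(length(picked))
    last_ctg <- ""; last_pos <- -1e9
    for (i in seq_along(picked)) {
      ctg <- ctg_of[picked[i]]; p <- pos_all[picked[i]]
      if (ctg != last_ctg || p - last_pos >= 8L) {
        keep[i] <- TRUE; last_ctg <- ctg; last_pos <- p
      }
    }
    picked <- picked[keep]
    if (length(picked) < n_total) {
      abort("requested variant count exceeds placeable sites in targets")
    }
    picked <- picked[sample.int(length(picked), n_total)]
    ctgs <- ctg_of[picked]; poss <- pos_all[picked]
    ref_base <- vapply(seq_along(picked), function(i) {
      substring(reference[[ctgs[i]]], poss[i], poss[i])
    }, character(1))
    ok <- ref_base %in% DNA_BASES
    ctgs <- ctgs[ok]; poss <- poss[ok]; ref_base <- ref_base[ok]
    org <- c(rep("germline", n_germline), rep("somatic", n_somatic))
    org <- org[seq_along(ctgs)]

    is_g <- org == "germline"
    indel <- is_g & stats::runif(length(org)) < germline_indel_fraction
    vclass <- ifelse(!indel, "SNV",
                     ifelse(stats::runif(length(org)) < 0.5, "INS", "DEL"))
    ref <- ref_base; alt <- character(length(org))
    for (i in seq_along(org)) {
      if (vclass[i] == "SNV") {
        alt[i] <- sub_base(ref_base[i])
      } else if (vclass[i] == "INS") {
        ref[i] <- ""
        alt[i] <- paste(sample(DNA_BASES, sample(1:6, 1), replace = TRUE),
                        collapse = "")
      } else {
        len <- sample(1:6, 1)
        ref[i] <- substring(reference[[ctgs[i]]], poss[i],
                            poss[i] + len - 1L)
        alt[i] <- ""
        if (grepl("N", ref[i])) { vclass[i] <- "SNV"; ref[i] <- ref_base[i]
                                  alt[i] <- sub_base(ref_base[i]) }
      }
    }
    p_het <- if (is.finite(het_hom_ratio)) {
      het_hom_ratio / (het_hom_ratio + 1)
    } else 1
    het <- stats::runif(length(org)) < p_het
    lineage <- ifelse(!is_g, NA_character_,
                      ifelse(!het, "both",
                             ifelse(stats::runif(length(org)) < 0.5,
                                    "maternal", "paternal")))
    v <- variant_table(tibble(
      id = paste0(ifelse(is_g, "g", "s"), seq_along(org)),
      contig = ctgs, pos = poss, ref = ref, alt = alt, vclass = vclass,
      origin = org))
    key <- paste0(ifelse(is_g, "g", "s"), seq_along(org))
    v$lineage <- lineage[match(v$id, key)]
    v
  })
}

#' Forge the diploid control genome from germline variants
#'
#' @param reference Named character vector.
#' @param germline Germline [variant_table()] with a `lineage` column.
#' @return List with `maternal` and `paternal` [implant_variants()]
#'   haplotypes.
#' @export
forge_control_genome <- function(reference, germline) {
  list(
    maternal = implant_variants(
      reference, germline[germline$lineage %in% c("maternal", "both"), ],
      label = "control.maternal"),
    paternal = implant_variants(
      reference, germline[germline$lineage %in% c("paternal", "both"), ],
      label = "control.paternal"))
}

#' Forge the subclonal cancer genomes
#'
#' Each cancer genome carries its lineage's full germline haplotype plus
#' the somatic subset assigned to it.
#'
#' @param reference Named character vector.
#' @param germline Germline [variant_table()] with `lineage`.
#' @param somatic Somatic [variant_table()].
#' @param assignment An [assign_subclones()] result.
#' @return List with `maternal` and `paternal` lists of haplotypes.
#' @export
forge_cancer_genomes <- function(reference, germline, somatic, assignment) {
  n <- assignment$n_per_lineage
  memb <- assignment$membership
  out <- list(maternal = vector("list", n), paternal = vector("list", n))
  for (lin in c("maternal", "paternal")) {
    g <- germline[germline$lineage %in% c(lin, "both"), ]
    for (k in seq_len(n)) {
      ids <- memb$id[memb$lineage == lin & memb$genome == k]
      v <- bind_rows(g, somatic[somatic$id %in% ids, ])
      out[[lin]][[k]] <- implant_variants(
        reference, v, label = paste0("tumor.", lin, ".", k))
    }
  }
  out
}
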