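# Truth alignments: reference position and CIGAR for each simulated read,
# obtained by composing the haplotype->reference alignment blocks with the
# read's error walk. Reads fully inside a single matched block (the vast
# majority) take a vectorized fast path.
truth_alignment <- function(map, reads, walks) {
  n <- nrow(reads)
  ref_pos <- integer(n); cigar <- character(n); mapped <- logical(n)
  ref_span <- integer(n)
  for (ctg in unique(reads$contig)) {
    cm <- map_contig(map, ctg)
    i <- which(reads$contig == ctg)
    blocks <- cm$blocks
    mb <- blocks[blocks$op == "M", , drop = FALSE]
    hs <- reads$hap_start[i]
    he <- hs + reads$n_template[i] - 1L
    bi <- findInterval(hs, mb$hap_start)
    simple <- bi > 0 & he <= mb$hap_start[pmax(bi, 1)] + mb$len[pmax(bi, 1)] - 1L &
      vapply(i, function(k) is.null(walks[[k]]), logical(1))
    ii <- i[simple]
    if (length(ii) > 0) {
      b <- bi[simple]
      ref_pos[ii] <- mb$ref_start[b] + hs[simple] - mb$hap_start[b]
      cigar[ii] <- paste0(reads$n_template[ii], "M")
      mapped[ii] <- TRUE
      ref_span[ii] <- reads$n_template[ii]
    }
    for (k in i[!simple]) {
      w <- walks[[k]] %||% rep("M", reads$n_template[k])
      al <- compose_cigar(blocks, reads$hap_start[k], w)
      ref_pos[k] <- al$pos; cigar[k] <- al$cigar
      mapped[k] <- al$mapped; ref_span[k] <- al$ref_span
    }
  }
  tibble(ref_pos = ref_pos, cigar = cigar, mapped = mapped,
         ref_span = ref_span)
}

# Expand the haplotype->reference alignment over hap positions [h1, h2]:
# per-position label ("M" aligned / "I" inserted relative to reference),
# the reference coordinate of aligned positions, and the number of
# reference bases deleted immediately before each position.
hap2ref_expanded <- function(blocks, h1, h2) {
  n <- h2 - h1 + 1L
  lab <- character(n); refpos <- rep(NA_integer_, n); dbefore <- integer(n)
  pend <- 0L
  for (j in seq_len(nrow(blocks))) {
    op <- blocks$op[j]
    if (op == "D") { pend <- pend + blocks$len[j]; next }
    bs <- blocks$hap_start[j]; be <- bs + blocks$len[j] - 1L
    if (be < h1) { pend <- 0L; next }
    if (bs > h2) break
    s <- max(bs, h1); e <- min(be, h2)
    lab[(s - h1 + 1L):(e - h1 + 1L)] <- op
    if (op == "M") {
      refpos[(s - h1 + 1L):(e - h1 + 1L)] <-
        blocks$ref_start[j] + (s:e) - bs
    }
    if (pend > 0L && bs >= h1 + 1L && bs <= h2) {
      dbefore[bs - h1 + 1L] <- dbefore[bs - h1 + 1L] + pend
    }
    pend <- 0L
  }
  list(lab = lab, refpos = refpos, dbefore = dbefore)
}

# Compose the read's error walk (over template positions) with the
# haplotype->reference expansion into a reference CIGAR. Leading/trailing
# insertions become soft clips; flanking deletions are trimmed.
compose_cigar <- function(blocks, hap_start, walk) {
  n_template <- sum(walk != "I")
  exp <- hap2ref_expanded(blocks, hap_start, hap_start + n_template - 1L)
  ops <- character(length(walk) + sum(exp$dbefore))
  k <- 0L; t <- 0L
  pos <- NA_integer_
  push <- function(o) { k <<- k + 1L; ops[k] <<- o }
  for (w in walk) {
    if (w == "I") { push("I"); next }
    t <- t + 1L
    if (exp$dbefore[t] > 0L) for (z in seq_len(exp$dbefore[t])) push("D")
    if (w == "M") {
      if (exp$lab[t] == "M") {
        push("M")
        if (is.na(pos)) pos <- exp$refpos[t]
      } else push("I")
    } else { # walk "D": template base absent from the read
      if (exp$lab[t] == "M") push("D")
    }
  }
  ops <- ops[seq_len(k)]
  if (!any(ops == "M")) {
    return(list(pos = 0L, cigar = "*", mapped = FALSE, ref_span = 0L))
  }
  # trim deletions outside the aligned core; clip flanking insertions
  first_m <- match("M", ops); last_m <- length(ops) + 1L - match("M", rev(ops))
  lead <- ops[seq_len(first_m - 1L)]
  tail_ops <- if (last_m < length(ops)) ops[(last_m + 1L):length(ops)] else character(0)
  core <- ops[first_m:last_m]
  n_lead_s <- sum(lead == "I"); n_tail_s <- sum(tail_ops == "I")
  r <- rle(core)
  cig <- paste0(r$lengths, r$values, collapse = "")
  if (n_lead_s > 0) cig <- paste0(n_lead_s, "S", cig)
  if (n_tail_s > 0) cig <- paste0(cig, n_tail_s, "S")
  list(pos = pos, cigar = cig, mapped = TRUE,
       ref_span = sum(core %in% c("M", "D")))
}

#' Write simulated reads as a coordinate-sorted truth SAM
#'
#' Each read is placed at its known reference coordinate with a CIGAR
#' derived from the source haplotype's coordinate map plus injected read
#' errors, replacing an external alignment step for self-contained testing.
#'
#' @param reads A [simulate_reads()] `read_set`.
#' @param reference Named character vector (for `@SQ` header lengths).
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(reads, reference, path) {
  cfg <- attr(reads, "config")
  rl <- cfg$read_length
  qual <- quality_string(rl, cfg)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                      nchar(reference)),
              "@PG\tID:admixbench\tPN:admixbench")
  mates <- reads |>
    select("fragment", "mate", "ref_pos", "ref_span", "mapped") |>
    tidyr::pivot_wider(names_from = "mate",
                       values_from = c("ref_pos", "ref_span", "mapped"))
  rd <- left_join(reads, mates, by = "fragment")
  mate_pos <- ifelse(rd$mate == 1L, rd$ref_pos_2, rd$ref_pos_1)
  mate_mapped <- ifelse(rd$mate == 1L, rd$mapped_2, rd$mapped_1)
  mate_rev <- !rd$is_reverse # mates are always on opposite strands
  lo <- pmin(rd$ref_pos, mate_pos)
  hi <- pmax(rd$ref_pos + rd$ref_span, mate_pos +
               ifelse(rd$mate == 1L, rd$ref_span_2, rd$ref_span_1))
  tlen <- ifelse(!rd$mapped | !mate_mapped, 0L,
                 ifelse(rd$ref_pos == lo, hi - lo, -(hi - lo)))
  flag <- 1L + 2L +
    ifelse(rd$mapped, 0L, 4L) + ifelse(mate_mapped, 0L, 8L) +
    ifelse(rd$is_reverse, 16L, 0L) + ifelse(mate_rev, 32L, 0L) +
    ifelse(rd$mate == 1L, 64L, 128L)
  qlen <- nchar(rd$seq)
  quals <- ifelse(qlen == rl, qual,
                  substr(strrep(qual, 2L), 1L, qlen))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                   rd$qname, flag,
                   ifelse(rd$mapped, rd$contig, "*"),
                   ifelse(rd$mapped, rd$ref_pos, 0L),
                   ifelse(rd$mapped, 60L, 0L), rd$cigar, "=",
                   ifelse(mate_mapped, mate_pos, 0L), tlen, rd$seq, quals)
  o <- order(!rd$mapped, rd$contig, rd$ref_pos)
  writeLines(c(header, lines[o]), path)
  invisible(path)
}

#' Write simulated reads as paired FASTQ
#'
#' Reads are emitted in sequencing orientation (reverse-strand reads are
#' reverse-complemented relative to the genome) with Phred+33 qualities
#' from the configured linear decay model.
#'
#' @param reads A [simulate_reads()] `read_set`.
#' @param prefix Output prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written (`.gz` appended when `gzip = TRUE`).
#' @param gzip Compress output.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix, gzip = FALSE) {
  cfg <- attr(reads, "config")
  qual <- quality_string(cfg$read_length, cfg)
  paths <- paste0(prefix, "_", 1:2, ".fastq", if (gzip) ".gz" else "")
  for (m in 1:2) {
    rd <- reads[reads$mate == m, , drop = FALSE]
    s <- rd$seq
    if (any(rd$is_reverse)) s[rd$is_reverse] <- revcomp(s[rd$is_reverse])
    qlen <- nchar(s)
    quals <- ifelse(qlen == cfg$read_length, qual,
                    substr(strrep(qual, 2L), 1L, qlen))
    rec <- paste0("@", rd$qname, "\n", s, "\n+\n", quals)
    con <- if (gzip) gzfile(paths[m], "w") else file(paths[m], "w")
    writeLines(rec, con)
    close(con)
  }
  invisible(paths)
}

# Phred+33 quality string: linear decay q_start -> q_end over the read.
quality_string <- function(rl, cfg) {
  q <- round(cfg$q_start - (cfg$q_start - cfg$q_end) *
               (seq_len(rl) - 1) / max(rl - 1, 1))
  intToUtf8(as.integer(q) + 33L)
}

#' Median coverage of target bases from truth alignments
#'
#' Piles up the reference spans of mapped reads and reports the median
#' per-base depth over all targeted positions.
#'
#' @param reads A [simulate_reads()] `read_set`.
#' @param targets A [target_regions()] tibble.
#' @return Median on-target depth (numeric).
#' @export
median_target_coverage <- function(reads, targets) {
  rd <- reads[reads$mapped, , drop = FALSE]
  gr <- GenomicRanges::GRanges(rd$contig,
                               IRanges::IRanges(rd$ref_pos,
                                                rd$ref_pos + rd$ref_span - 1L))
  cov <- GenomicRanges::coverage(gr)
  depths <- integer(0)
  for (i in seq_len(nrow(targets))) {
    ctg <- targets$contig[i]
    if (!ctg %in% names(cov)) next
    v <- as.integer(IRanges::Views(
      cov[[ctg]],
      IRanges::IRanges(targets$start[i] + 1L,
                       min(targets$end[i], length(cov[[ctg]]))))[[1]])
    depths <- c(depths, v)
    extra <- targets$end[i] - length(cov[[ctg]])
    if (extra > 0) depths <- c(depths, integer(extra))
  }
  stats::median(depths)
}
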