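#' Caller thresholds for the baseline binomial SNV caller
#'
#' A site is reported when depth, alternate-allele count and fraction clear
#' their thresholds and the one-sided binomial tail probability
#' `P(X >= alt_count | depth, max_error_rate)` falls below `p_cutoff`.
#' Binomial-tail scoring is the simplest member of the count-test family of
#' callers; it is deliberately not a re-implementation of any published
#' tool. Base qualities are ignored (counts only).
#'
#' @param min_depth Minimum site depth.
#' @param min_alt_count Minimum alternate-allele read count.
#' @param min_alt_fraction Minimum alternate-allele fraction.
#' @param max_error_rate Assumed per-base error rate for the binomial test;
#'   `NULL` disables the test.
#' @param p_cutoff One-sided p-value cutoff; `NULL` disables the test.
#' @param id Optional short identifier used in parameter sweeps.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_depth = 10, min_alt_count = 2,
                          min_alt_fraction = 0.05, max_error_rate = 1e-3,
                          p_cutoff = 0.01, id = NULL) {
  stopifnot(min_depth >= 0, min_alt_count >= 0,
            min_alt_fraction >= 0, min_alt_fraction <= 1)
  if (!is.null(max_error_rate)) {
    stopifnot(max_error_rate >= 0, max_error_rate <= 1)
  }
  p <- list(min_depth = min_depth, min_alt_count = min_alt_count,
            min_alt_fraction = min_alt_fraction,
            max_error_rate = max_error_rate, p_cutoff = p_cutoff)
  p$id <- id %||% paste0("d", min_depth, "_c", min_alt_count, "_f",
                         min_alt_fraction, "_p",
                         if (is.null(p_cutoff)) "off" else p_cutoff)
  structure(p, class = "caller_params")
}

#' Nucleotide pileup from alignments
#'
#' Converts a SAM/BAM file to per-position A/C/G/T counts using
#' [Rsamtools::pileup()] (SAM input is converted to BAM in a temporary
#' directory first).
#'
#' @param alignments Path to a coordinate-sorted SAM or BAM file.
#' @param min_depth Positions below this total depth are dropped early.
#' @return A tibble with `contig`, `pos` and `A`, `C`, `G`, `T` count
#'   columns plus `depth` (sum of the four).
#' @export
pileup_counts <- function(alignments, min_depth = 1) {
  bam <- as_bam(alignments)
  p <- Rsamtools::pileup(
    bam,
    pileupParam = Rsamtools::PileupParam(
      max_depth = 1000000L, min_base_quality = 0L, min_mapq = 0L,
      min_nucleotide_depth = 1L, distinguish_strands = FALSE,
      distinguish_nucleotides = TRUE, ignore_query_Ns = TRUE,
      include_deletions = FALSE, include_insertions = FALSE))
  if (nrow(p) == 0) {
    return(tibble(contig = character(0), pos = integer(0), A = integer(0),
                  C = integer(0), G = integer(0), T = integer(0),
                  depth = integer(0)))
  }
  wide <- p |>
    as_tibble() |>
    filter(.data$nucleotide %in% DNA_BASES) |>
    transmute(contig = as.character(.data$seqnames), pos = .data$pos,
              nucleotide = as.character(.data$nucleotide),
              count = .data$count) |>
    tidyr::pivot_wider(names_from = "nucleotide", values_from = "count",
                       values_fill = 0L)
  for (b in setdiff(DNA_BASES, names(wide))) wide[[b]] <- 0L
  wide$depth <- wide$A + wide$C + wide$G + wide$T
  wide |>
    filter(.data$depth >= min_depth) |>
    select("contig", "pos", "A", "C", "G", "T", "depth") |>
    arrange(.data$contig, .data$pos)
}

as_bam <- function(alignments) {
  if (grepl("\\.bam$", alignments)) return(alignments)
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(alignments, destination = dest, overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

#' Call SNVs from a pileup with binomial-tail scoring
#'
#' The alternate allele at each site is the highest-count non-reference
#' base (ties broken lexicographically). See [caller_params()] for the
#' filtering and scoring rules.
#'
#' @param pileup A [pileup_counts()] tibble.
#' @param reference Named character vector of contig sequences.
#' @param params A [caller_params()].
#' @return A callset tibble: `contig`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_count`, `af`, `p`.
#' @export
call_from_pileup <- function(pileup, reference, params) {
  stopifnot(inherits(params, "caller_params"))
  unknown <- setdiff(unique(pileup$contig), names(reference))
  if (length(unknown) > 0) {
    abort(paste0("pileup contig(s) absent from reference: ",
                 paste(unknown, collapse = ", ")))
  }
  if (nrow(pileup) == 0) return(empty_callset())
  ref_base <- character(nrow(pileup))
  for (ctg in unique(pileup$contig)) {
    i <- pileup$contig == ctg
    ref_base[i] <- substring(reference[[ctg]], pileup$pos[i], pileup$pos[i])
  }
  valid <- !is.na(match(ref_base, DNA_BASES)) # skip N reference positions
  pileup <- pileup[valid, , drop = FALSE]
  ref_base <- ref_base[valid]
  if (nrow(pileup) == 0) return(empty_callset())
  cnt <- as.matrix(pileup[DNA_BASES])
  # mask the reference allele, take the max remaining count
  cnt[cbind(seq_len(nrow(cnt)), match(ref_base, DNA_BASES))] <- -1L
  alt_i <- max.col(cnt, ties.method = "first") # columns in A<C<G<T order
  alt_count <- cnt[cbind(seq_len(nrow(cnt)), alt_i)]
  out <- tibble(contig = pileup$contig, pos = pileup$pos, ref = ref_base,
                alt = DNA_BASES[alt_i], depth = pileup$depth,
                alt_count = as.integer(alt_count))
  out <- out[out$alt_count > 0, , drop = FALSE]
  out$af <- out$alt_count / out$depth
  keep <- out$depth >= params$min_depth &
    out$alt_count >= params$min_alt_count &
    out$af >= params$min_alt_fraction
  if (!is.null(params$max_error_rate) && !is.null(params$p_cutoff)) {
    out$p <- stats::pbinom(out$alt_count - 1L, out$depth,
                           params$max_error_rate, lower.tail = FALSE)
    keep <- keep & out$p < params$p_cutoff
  } else {
    out$p <- NA_real_
  }
  out <- out[keep, , drop = FALSE]
  arrange(out, .data$contig, .data$pos)
}

empty_callset <- function() {
  tibble(contig = character(0), pos = integer(0), ref = character(0),
         alt = character(0), depth = integer(0), alt_count = integer(0),
         af = numeric(0), p = numeric(0))
}

#' Call SNVs from truth alignments
#'
#' Convenience wrapper: [pileup_counts()] then [call_from_pileup()].
#'
#' @param alignments SAM/BAM path (coordinate-sorted).
#' @param reference Named character vector or FASTA path.
#' @param params A [caller_params()].
#' @return A callset tibble (see [call_from_pileup()]).
#' @export
call_snvs <- function(alignments, reference, params = caller_params()) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_reference_fasta(reference)
  }
  call_from_pileup(pileup_counts(alignments), reference, params)
}

#' Run the baseline caller over a parameter grid
#'
#' The pileup is computed once and every parameter set is applied to it, so
#' a sweep costs little more than a single call.
#'
#' @param alignments SAM/BAM path.
#' @param reference Named character vector or FASTA path.
#' @param grid A list of [caller_params()].
#' @return A tibble with `params_id`, `params` (list-column) and `callset`
#'   (list-column of callset tibbles).
#' @export
sweep_params <- function(alignments, reference, grid) {
  if (length(grid) == 0) abort("parameter grid is empty")
  if (inherits(grid, "caller_params")) grid <- list(grid)
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_reference_fasta(reference)
  }
  pu <- pileup_counts(alignments)
  tibble(
    params_id = vapply(grid, function(p) p$id, character(1)),
    params = grid,
    callset = lapply(grid, function(p) call_from_pileup(pu, reference, p)))
}

#' Write a callset as VCF 4.2
#' @param calls A callset tibble from [call_from_pileup()].
#' @param path Output path.
#' @param reference Optional named character vector for contig headers.
#' @return `path`, invisibly.
#' @export
write_callset_vcf <- function(calls, path, reference = NULL) {
  header <- c("##fileformat=VCFv4.2",
              "##source=admixbench baseline caller",
              '##INFO=<ID=AF,Number=1,Type=Float,Description="Alternate allele fraction">',
              '##INFO=<ID=DP,Number=1,Type=Integer,Description="Site depth">',
              '##INFO=<ID=P,Number=1,Type=Float,Description="Binomial tail p-value">')
  if (!is.null(reference)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(reference), nchar(reference)))
  }
  header <- c(header, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO", sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%s;DP=%d;P=%s",
                  calls$contig, calls$pos, calls$ref, calls$alt,
                  formatC(calls$af, digits = 6, format = "g"), calls$depth,
                  formatC(calls$p, digits = 4, format = "g"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read any VCF callset into the evaluator's tabular form
#'
#' Multi-allelic records are split into one row per ALT; non-SNV rows are
#' kept but flagged by `vclass` so the evaluator can restrict to SNVs.
#'
#' @param path VCF path.
#' @return A tibble with `contig`, `pos`, `ref`, `alt`, `vclass`.
#' @export
read_callset_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(contig = character(0), pos = integer(0),
                  ref = character(0), alt = character(0),
                  vclass = character(0)))
  }
  rows <- tibble(contig = fix$CHROM, pos = as.integer(fix$POS),
                 ref = fix$REF, alt = fix$ALT)
  rows <- tidyr::separate_rows(rows, "alt", sep = ",")
  rows$vclass <- dplyr::case_when(
    nchar(rows$ref) == 1 & nchar(rows$alt) == 1 ~ "SNV",
    nchar(rows$ref) < nchar(rows$alt) ~ "INS",
    nchar(rows$ref) > nchar(rows$alt) ~ "DEL",
    TRUE ~ "MNV")
  rows
}
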