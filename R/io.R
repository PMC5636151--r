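#' Read a reference genome from FASTA
#' @param path FASTA path (may be multi-contig).
#' @return Named uppercase character vector of contig sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x)) # drop description after first token
  as_reference(x)
}

#' Write sequences to FASTA
#' @param sequences Named character vector or `haplotype_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "haplotype_genome")) sequences <- sequences$sequences
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read variants from VCF into a variant table
#'
#' Accepts plain or bgzipped VCF. Multi-allelic records are split into one
#' row per ALT allele; symbolic alleles (`<DEL>`, breakends) are rejected.
#' Indels in VCF's anchored-base notation are converted to this package's
#' anchor-free convention (insertion after `pos`, deletion of the bases
#' following the anchor).
#'
#' @param path VCF path.
#' @param origin Origin label applied to records lacking an `ORIGIN` INFO
#'   key; `NULL` keeps only what the file declares.
#' @return A [variant_table()] tibble; expected allele frequencies are
#'   recovered from the `TAF` INFO key when present (column `expected_af`).
#' @export
read_vcf_variants <- function(path, origin = "germline") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(variant_table(tibble(id = character(0), contig = character(0),
                                pos = integer(0), ref = character(0),
                                alt = character(0), vclass = character(0),
                                origin = character(0))))
  }
  info <- fix$INFO %||% rep(NA_character_, nrow(fix))
  rows <- tibble(contig = fix$CHROM, pos = as.integer(fix$POS),
                 vcf_ref = fix$REF, alt_field = fix$ALT, info = info,
                 vcf_id = fix$ID)
  rows <- tidyr::separate_rows(rows, "alt_field", sep = ",")
  if (any(grepl("[<>\\[\\]]", rows$alt_field))) {
    abort("symbolic or breakend ALT alleles are not supported")
  }
  info_get <- function(info, key) {
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(?:^|;)", key, "="), info, perl = TRUE)
    out[hit] <- sub(paste0("^.*?(?:^|;)", key, "=([^;]*).*$"), "\\1",
                    info[hit], perl = TRUE)
    out
  }
  rl <- nchar(rows$vcf_ref); al <- nchar(rows$alt_field)
  vclass <- dplyr::case_when(
    rl == 1 & al == 1 ~ "SNV",
    rl < al ~ "INS",
    rl > al ~ "DEL",
    TRUE ~ "MNV")
  if (any(vclass == "MNV")) abort("multi-nucleotide substitutions are not supported")
  # strip the VCF anchor base for indels
  ref <- ifelse(vclass == "SNV", rows$vcf_ref,
                substr(rows$vcf_ref, 2L, rl))
  alt <- ifelse(vclass == "SNV", rows$alt_field,
                substr(rows$alt_field, 2L, al))
  pos <- ifelse(vclass == "SNV", rows$pos,
                ifelse(vclass == "INS", rows$pos, rows$pos + 1L))
  anchor_ok <- vclass == "SNV" |
    substr(rows$vcf_ref, 1L, 1L) == substr(rows$alt_field, 1L, 1L)
  if (!all(anchor_ok)) abort("indel records must share the VCF anchor base")
  org <- info_get(rows$info, "ORIGIN")
  org[is.na(org)] <- origin %||% NA_character_
  taf <- suppressWarnings(as.numeric(info_get(rows$info, "TAF")))
  id <- ifelse(is.na(rows$vcf_id) | rows$vcf_id == ".",
               paste0(rows$contig, ":", pos, ":", ref, ">", alt),
               rows$vcf_id)
  out <- variant_table(tibble(id = id, contig = rows$contig,
                              pos = as.integer(pos), ref = ref, alt = alt,
                              vclass = vclass, origin = org))
  key <- paste(rows$contig, pos, ref, alt)
  out$expected_af <- taf[match(paste(out$contig, out$pos, out$ref, out$alt),
                               key)]
  if (all(is.na(out$expected_af))) out$expected_af <- NULL
  out
}

#' Read variants from a 6-column TSV
#'
#' Columns: `id`, `contig`, `pos`, `ref`, `alt`, `vclass`, `origin`
#' (header required; empty alleles written as `.`).
#' @param path TSV path.
#' @return A [variant_table()] tibble.
#' @export
read_variants_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  d$pos <- as.integer(d$pos)
  d$ref[d$ref == "."] <- ""
  d$alt[d$alt == "."] <- ""
  variant_table(d)
}

#' Write variants to a 6-column TSV
#' @param variants A [variant_table()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  d <- as.data.frame(variants[c("id", "contig", "pos", "ref", "alt",
                                "vclass", "origin")])
  d$ref[d$ref == ""] <- "."
  d$alt[d$alt == ""] <- "."
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# VCF 4.2 representation: indels regain an anchor base from the reference.
vcf_records <- function(variants, reference) {
  v <- variants
  vcf_pos <- v$pos
  vcf_ref <- v$ref
  vcf_alt <- v$alt
  idx_ins <- which(v$vclass == "INS")
  for (i in idx_ins) {
    anchor <- substr(reference[[v$contig[i]]], v$pos[i], v$pos[i])
    vcf_ref[i] <- anchor
    vcf_alt[i] <- paste0(anchor, v$alt[i])
  }
  idx_del <- which(v$vclass == "DEL")
  for (i in idx_del) {
    p <- v$pos[i] - 1L
    if (p < 1L) abort("cannot write a deletion starting at contig position 1")
    anchor <- substr(reference[[v$contig[i]]], p, p)
    vcf_pos[i] <- p
    vcf_ref[i] <- paste0(anchor, v$ref[i])
    vcf_alt[i] <- anchor
  }
  tibble(contig = v$contig, pos = vcf_pos, id = v$id, ref = vcf_ref,
         alt = vcf_alt)
}
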