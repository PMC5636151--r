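#' Build and validate a variant table
#'
#' The central exchange format for germline and somatic variants is a plain
#' tibble with one row per reference-anchored edit. Positions are VCF-style
#' 1-based. For SNVs `ref` and `alt` are single differing bases; insertions
#' have an empty `ref` (sequence inserted immediately AFTER `pos`); deletions
#' have an empty `alt` and delete `nchar(ref)` bases starting at `pos`.
#'
#' @param df A data frame with columns `id`, `contig`, `pos`, `ref`, `alt`,
#'   `vclass` (one of `"SNV"`, `"INS"`, `"DEL"`) and `origin` (`"germline"`
#'   or `"somatic"`). An optional `lineage` column (`"maternal"`,
#'   `"paternal"` or `"both"`) records which parental haplotype(s) carry a
#'   germline variant.
#' @return A validated tibble sorted by `(contig, pos)`.
#' @export
variant_table <- function(df) {
  need <- c("id", "contig", "pos", "ref", "alt", "vclass", "origin")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("variant table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  v <- as_tibble(df)
  v$pos <- as.integer(v$pos)
  v$ref <- toupper(v$ref)
  v$alt <- toupper(v$alt)
  if (anyDuplicated(v$id)) abort("variant ids must be unique")
  if (!all(v$vclass %in% c("SNV", "INS", "DEL"))) {
    abort("vclass must be one of SNV, INS, DEL")
  }
  if (!all(v$origin %in% c("germline", "somatic"))) {
    abort("origin must be germline or somatic")
  }
  is_snv <- v$vclass == "SNV"
  bad <- is_snv & !(nchar(v$ref) == 1 & nchar(v$alt) == 1 & v$ref != v$alt)
  if (any(bad)) abort(paste0("malformed SNV record(s): ",
                             paste(v$id[bad], collapse = ", ")))
  bad <- v$vclass == "INS" & !(v$ref == "" & nchar(v$alt) >= 1)
  if (any(bad)) abort("INS records must have empty ref and non-empty alt")
  bad <- v$vclass == "DEL" & !(v$alt == "" & nchar(v$ref) >= 1)
  if (any(bad)) abort("DEL records must have empty alt and non-empty ref")
  ok_chars <- grepl("^[ACGT]*$", v$ref) & grepl("^[ACGT]*$", v$alt)
  if (!all(ok_chars)) abort("alleles must be over the alphabet {A,C,G,T}")
  arrange(v, .data$contig, .data$pos)
}

# Reference span of each variant on [start, end], 1-based inclusive.
# Insertions occupy a zero-length point anchored after `pos` (span
# [pos+1, pos] conceptually); for overlap checks they claim the anchor base.
variant_ref_span <- function(v) {
  len <- ifelse(v$vclass == "DEL", nchar(v$ref), 1L)
  tibble(contig = v$contig, start = v$pos, end = v$pos + len - 1L, id = v$id)
}
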