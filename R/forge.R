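#' Implant variants into a reference to forge a personal haplotype
#'
#' Applies a set of non-overlapping SNVs, insertions and deletions to a
#' reference genome by string surgery and records a coordinate map between
#' reference and haplotype positions. This is the building block for both
#' the diploid control genome (maternal/paternal germline haplotypes) and
#' the subclonal cancer genomes (germline plus a somatic subset).
#'
#' @param reference Named character vector of contig sequences, or a
#'   [Biostrings::DNAStringSet]. Read case-insensitively; output uppercase.
#' @param variants A [variant_table()] tibble. Variants must not overlap the
#'   same reference base, SNV/DEL `ref` alleles must match the reference and
#'   no variant may sit on an ambiguous (N) base.
#' @param label Label for the haplotype (e.g. `"maternal"`, `"paternal.3"`).
#' @return An object of class `haplotype_genome`: a list with `label`,
#'   `sequences` (named uppercase character vector), `variants_applied`
#'   (ids in application order) and `coord_map` (see [lift_position()]).
#' @examples
#' ref <- c(chr1 = "ACGTACGT")
#' v <- variant_table(data.frame(
#'   id = c("s1", "d1"), contig = "chr1", pos = c(2L, 5L),
#'   ref = c("C", "A"), alt = c("T", ""), vclass = c("SNV", "DEL"),
#'   origin = "germline"))
#' hap <- implant_variants(ref, v)
#' hap$sequences[["chr1"]] # "ATGTCGT"
#' @export
implant_variants <- function(reference, variants, label = "haplotype") {
  reference <- as_reference(reference)
  v <- variant_table(variants)
  check_variants_against_reference(reference, v)

  seqs <- character(0)
  for (ctg in names(reference)) {
    refseq <- reference[[ctg]]
    vc <- v[v$contig == ctg, , drop = FALSE]
    if (nrow(vc) == 0) {
      seqs[[ctg]] <- refseq
      next
    }
    # one-pass chunked rebuild, edits already sorted by pos
    chunks <- character(2L * nrow(vc) + 1L)
    cursor <- 1L # next unread reference base
    k <- 0L
    for (i in seq_len(nrow(vc))) {
      pos <- vc$pos[i]
      cls <- vc$vclass[i]
      if (cls == "INS") {
        # copy through the anchor base, then splice in the insertion
        k <- k + 1L; chunks[k] <- substr(refseq, cursor, pos)
        k <- k + 1L; chunks[k] <- vc$alt[i]
        cursor <- pos + 1L
      } else if (cls == "SNV") {
        k <- k + 1L; chunks[k] <- substr(refseq, cursor, pos - 1L)
        k <- k + 1L; chunks[k] <- vc$alt[i]
        cursor <- pos + 1L
      } else { # DEL
        k <- k + 1L; chunks[k] <- substr(refseq, cursor, pos - 1L)
        cursor <- pos + nchar(vc$ref[i])
      }
    }
    k <- k + 1L; chunks[k] <- substr(refseq, cursor, nchar(refseq))
    seqs[[ctg]] <- paste(chunks[seq_len(k)], collapse = "")
  }

  map <- build_coord_map(reference, v)
  structure(
    list(label = label, sequences = seqs, variants_applied = v$id,
         coord_map = map),
    class = "haplotype_genome")
}

#' @export
print.haplotype_genome <- function(x, ...) {
  cat("<haplotype_genome> ", x$label, ": ", length(x$sequences),
      " contig(s), ", length(x$variants_applied), " variant(s) applied\n",
      sep = "")
  invisible(x)
}

as_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  if (is.null(names(reference)) || any(names(reference) == "")) {
    abort("reference contigs must be named")
  }
  toupper(reference)
}

check_variants_against_reference <- function(reference, v) {
  unknown <- setdiff(unique(v$contig), names(reference))
  if (length(unknown) > 0) {
    abort(paste0("variant contig(s) absent from reference: ",
                 paste(unknown, collapse = ", ")))
  }
  spans <- variant_ref_span(v)
  clens <- nchar(reference)[v$contig]
  out <- v$pos < 1L | spans$end > clens |
    (v$vclass == "INS" & v$pos > clens)
  if (any(out)) {
    abort(paste0("variant(s) outside contig bounds: ",
                 paste(v$id[out], collapse = ", ")))
  }
  # overlap check per contig on reference spans
  for (ctg in unique(spans$contig)) {
    s <- spans[spans$contig == ctg, , drop = FALSE]
    if (nrow(s) < 2) next
    prev_end <- cummax(c(-1L, s$end[-nrow(s)]))
    hit <- which(s$start <= prev_end)
    if (length(hit) > 0) {
      i <- hit[1]
      abort(paste0("overlapping variants on ", ctg, ": ", s$id[i - 1],
                   " and ", s$id[i], " share reference base(s)"))
    }
  }
  # ref-allele / N checks
  for (i in seq_len(nrow(v))) {
    ctg <- v$contig[i]
    pos <- v$pos[i]
    if (v$vclass[i] == "INS") {
      base <- substr(reference[[ctg]], pos, pos)
      if (base == "N") abort(paste0("variant ", v$id[i],
                                    " anchored on an N base at ", ctg, ":", pos))
      next
    }
    span <- substr(reference[[ctg]], pos, pos + nchar(v$ref[i]) - 1L)
    if (grepl("N", span, fixed = TRUE)) {
      abort(paste0("variant ", v$id[i], " overlaps an N base at ",
                   ctg, ":", pos))
    }
    if (span != v$ref[i]) {
      abort(paste0("ref allele mismatch for ", v$id[i], " at ", ctg, ":",
                   pos, " (expected ", v$ref[i], ", reference has ",
                   span, ")"))
    }
  }
  invisible(TRUE)
}

# A coord_map holds, per contig, the indel ledger needed to translate
# reference positions/intervals to haplotype coordinates, plus the
# reference <-> haplotype alignment blocks used for truth CIGARs.
build_coord_map <- function(reference, v) {
  per_contig <- list()
  for (ctg in names(reference)) {
    rlen <- nchar(reference[[ctg]])
    ind <- v[v$contig == ctg & v$vclass != "SNV", , drop = FALSE]
    events <- tibble(
      pos = ind$pos,
      vclass = ind$vclass,
      ref_len = ifelse(ind$vclass == "DEL", nchar(ind$ref), 0L),
      alt_len = ifelse(ind$vclass == "INS", nchar(ind$alt), 0L)
    )
    # offset ledger: offset applies to reference positions >= threshold
    thr <- ifelse(events$vclass == "INS", events$pos + 1L,
                  events$pos + events$ref_len)
    delta <- ifelse(events$vclass == "INS", events$alt_len, -events$ref_len)
    o <- order(thr)
    ledger <- tibble(threshold = thr[o], cum_offset = cumsum(delta[o]))
    # deletion spans [pos, pos + ref_len)
    dels <- events[events$vclass == "DEL", , drop = FALSE]
    dels <- dels[order(dels$pos), , drop = FALSE]
    per_contig[[ctg]] <- list(
      ref_length = rlen,
      hap_length = rlen + sum(delta),
      events = events[order(events$pos), , drop = FALSE],
      ledger = ledger,
      del_start = dels$pos,
      del_end = dels$pos + dels$ref_len, # exclusive
      blocks = build_alignment_blocks(rlen, events[order(events$pos), ,
                                                   drop = FALSE])
    )
  }
  structure(per_contig, class = "coord_map")
}

# Alignment of the haplotype to the reference as M/I/D blocks with 1-based
# start coordinates on both sequences (NA where a block consumes only one).
build_alignment_blocks <- function(rlen, events) {
  op <- character(0); len <- integer(0); rs <- integer(0); hs <- integer(0)
  r <- 1L; h <- 1L
  push <- function(o, l, rstart, hstart) {
    op[[length(op) + 1L]] <<- o
    len[[length(len) + 1L]] <<- as.integer(l)
    rs[[length(rs) + 1L]] <<- rstart
    hs[[length(hs) + 1L]] <<- hstart
  }
  for (i in seq_len(nrow(events))) {
    p <- events$pos[i]
    if (events$vclass[i] == "INS") {
      mlen <- p - r + 1L # match through the anchor base
      if (mlen > 0) { push("M", mlen, r, h); r <- r + mlen; h <- h + mlen }
      push("I", events$alt_len[i], NA_integer_, h)
      h <- h + events$alt_len[i]
    } else { # DEL
      mlen <- p - r
      if (mlen > 0) { push("M", mlen, r, h); r <- r + mlen; h <- h + mlen }
      push("D", events$ref_len[i], r, NA_integer_)
      r <- r + events$ref_len[i]
    }
  }
  if (r <= rlen) push("M", rlen - r + 1L, r, h)
  tibble(op = op, len = len, ref_start = rs, hap_start = hs)
}

#' Translate reference positions to haplotype positions
#'
#' @param map A `coord_map` from [implant_variants()].
#' @param contig Contig name (scalar).
#' @param pos Integer vector of 1-based reference positions.
#' @return Integer vector of 1-based haplotype positions; `NA` where the
#'   reference base was deleted in this haplotype.
#' @export
lift_position <- function(map, contig, pos) {
  cm <- map_contig(map, contig)
  if (any(pos < 1L | pos > cm$ref_length)) {
    abort("position outside reference contig bounds")
  }
  off <- rep(0, length(pos))
  if (nrow(cm$ledger) > 0) {
    idx <- findInterval(pos, cm$ledger$threshold)
    off[idx > 0] <- cm$ledger$cum_offset[idx[idx > 0]]
  }
  out <- as.integer(pos + off)
  if (length(cm$del_start) > 0) {
    di <- findInterval(pos, cm$del_start)
    deleted <- di > 0 & pos < c(0L, cm$del_end)[di + 1L]
    out[deleted] <- NA_integer_
  }
  out
}

#' Translate a reference interval to haplotype coordinates
#'
#' Intervals are BED-style 0-based half-open. The returned haplotype
#' interval covers exactly the surviving images of the input bases plus any
#' sequence inserted strictly inside the interval; an interval that falls
#' entirely within a deletion maps to an empty interval.
#'
#' @param map A `coord_map`.
#' @param contig Contig name.
#' @param start,end 0-based half-open reference interval bounds (scalars).
#' @return Integer vector `c(start, end)`, 0-based half-open on the
#'   haplotype (zero-length if every input base was deleted).
#' @export
lift_interval <- function(map, contig, start, end) {
  cm <- map_contig(map, contig)
  if (start < 0 || end > cm$ref_length || start > end) {
    abort("invalid reference interval")
  }
  if (start == end) return(c(first_surviving_lift(cm, start + 1L) - 1L,
                             first_surviving_lift(cm, start + 1L) - 1L))
  p1 <- start + 1L # first base, 1-based
  p2 <- as.integer(end) # last base, 1-based
  first <- first_surviving(cm, p1, p2)
  if (is.na(first)) {
    h <- first_surviving_lift(cm, p1)
    return(c(h - 1L, h - 1L))
  }
  last <- last_surviving(cm, p1, p2)
  h1 <- lift_position_one(cm, first)
  h2 <- lift_position_one(cm, last)
  c(h1 - 1L, h2)
}

map_contig <- function(map, contig) {
  cm <- map[[contig]]
  if (is.null(cm)) abort(paste0("unknown contig: ", contig))
  cm
}

lift_position_one <- function(cm, pos) {
  off <- 0
  if (nrow(cm$ledger) > 0) {
    idx <- findInterval(pos, cm$ledger$threshold)
    if (idx > 0) off <- cm$ledger$cum_offset[idx]
  }
  as.integer(pos + off)
}

is_deleted_one <- function(cm, pos) {
  if (length(cm$del_start) == 0) return(FALSE)
  di <- findInterval(pos, cm$del_start)
  di > 0 && pos < cm$del_end[di]
}

first_surviving <- function(cm, p1, p2) {
  p <- p1
  while (p <= p2) {
    if (!is_deleted_one(cm, p)) return(p)
    di <- findInterval(p, cm$del_start)
    p <- cm$del_end[di] # jump past the deletion
  }
  NA_integer_
}

last_surviving <- function(cm, p1, p2) {
  p <- p2
  while (p >= p1) {
    if (!is_deleted_one(cm, p)) return(p)
    di <- findInterval(p, cm$del_start)
    p <- cm$del_start[di] - 1L
  }
  NA_integer_
}

# haplotype position of the first surviving base at or after pos (used to
# anchor empty intervals); falls back to hap_length + 1 past the contig end.
first_surviving_lift <- function(cm, pos) {
  p <- pos
  while (p <= cm$ref_length && is_deleted_one(cm, p)) {
    di <- findInterval(p, cm$del_start)
    p <- cm$del_end[di]
  }
  if (p > cm$ref_length) return(cm$hap_length + 1L)
  lift_position_one(cm, p)
}
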