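#' Build a target-regions table
#'
#' Capture designs (exome or gene panel) are sets of reference intervals in
#' BED convention: 0-based half-open. Overlapping or book-ended intervals
#' are merged and the result sorted by contig and start.
#'
#' @param df Data frame with columns `contig`, `start`, `end` (0-based
#'   half-open), or a [GenomicRanges::GRanges].
#' @return A tibble of merged intervals with attribute `total_bases`.
#' @export
target_regions <- function(df) {
  if (inherits(df, "GRanges")) {
    df <- tibble(contig = as.character(GenomicRanges::seqnames(df)),
                 start = GenomicRanges::start(df) - 1L,
                 end = GenomicRanges::end(df))
  }
  stopifnot(all(c("contig", "start", "end") %in% names(df)))
  if (any(df$end <= df$start)) abort("target intervals must have end > start")
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    df$contig, IRanges::IRanges(df$start + 1L, df$end)))
  gr <- GenomicRanges::sort(gr)
  out <- tibble(contig = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr))
  attr(out, "total_bases") <- sum(out$end - out$start)
  out
}

#' Total bases covered by a target set
#' @param targets A [target_regions()] tibble.
#' @return Integer total of interval lengths.
#' @export
target_total_bases <- function(targets) {
  attr(targets, "total_bases") %||% sum(targets$end - targets$start)
}

#' Read target regions from a BED file
#' @param path BED file path.
#' @return A [target_regions()] tibble.
#' @export
read_targets_bed <- function(path) {
  target_regions(rtracklayer::import(path, format = "BED"))
}

#' Write target regions to a BED file
#' @param targets A [target_regions()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets_bed <- function(targets, path) {
  gr <- GenomicRanges::GRanges(targets$contig,
                               IRanges::IRanges(targets$start + 1L,
                                                targets$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# TRUE for 1-based positions falling inside any target interval
in_targets <- function(targets, contig, pos) {
  if (is.null(targets)) return(rep(TRUE, length(pos)))
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(targets$contig,
                              IRanges::IRanges(targets$start + 1L,
                                               targets$end))
  IRanges::overlapsAny(q, s)
}
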