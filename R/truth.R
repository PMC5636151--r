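#' Assemble a gold-standard truth set
#'
#' A truth set is the list of implanted variants with their expected allele
#' frequencies in one sample, optionally restricted to capture target
#' regions (evaluation happens within captured regions only).
#'
#' @param variants Tibble from [expected_af()] (needs `expected_af`).
#' @param label Sample label.
#' @param targets Optional [target_regions()] tibble; records whose
#'   position falls outside the targets are dropped.
#' @return A tibble of class `truth_set` with columns `id`, `contig`,
#'   `pos`, `ref`, `alt`, `vclass`, `origin`, `expected_af`, carrying
#'   `label` and `targets` attributes.
#' @export
truth_set <- function(variants, label = "sample", targets = NULL) {
  v <- as_tibble(variants)
  stopifnot("expected_af" %in% names(v))
  keep <- c("id", "contig", "pos", "ref", "alt", "vclass", "origin",
            "expected_af")
  v <- v[intersect(keep, names(v))]
  if (any(v$expected_af <= 0 | v$expected_af > 1)) {
    abort("truth-set allele frequencies must lie in (0, 1]")
  }
  if (!is.null(targets)) {
    v <- v[in_targets(targets, v$contig, v$pos), , drop = FALSE]
  }
  key <- paste(v$contig, v$pos, v$ref, v$alt)
  if (anyDuplicated(key)) abort("duplicate truth records at the same site")
  v <- arrange(v, .data$contig, .data$pos, .data$alt)
  structure(v, class = c("truth_set", class(tibble())),
            label = label, targets = targets)
}

#' Write a truth set as VCF 4.2
#'
#' Emits a coordinate-sorted VCF with contig headers and INFO keys
#' `ORIGIN` (germline/somatic), `TAF` (expected allele frequency) and
#' `VCLASS` (SNV/INS/DEL). Indels are written in standard anchored
#' notation, which requires the reference; they are flagged by `VCLASS`
#' because downstream evaluation is SNV-only.
#'
#' @param truth A [truth_set()].
#' @param path Output `.vcf` path.
#' @param reference Named character vector (needed when the set contains
#'   indels, to recover VCF anchor bases; also used for contig headers).
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, path, reference = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=admixbench",
    '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="Variant origin (germline or somatic)">',
    '##INFO=<ID=TAF,Number=1,Type=Float,Description="True (expected) allele frequency">',
    '##INFO=<ID=VCLASS,Number=1,Type=String,Description="Variant class (SNV, INS or DEL)">')
  if (!is.null(reference)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(reference), nchar(reference)))
  }
  header <- c(header,
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  if (nrow(truth) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  if (any(truth$vclass != "SNV") && is.null(reference)) {
    abort("writing indel truth records requires the reference")
  }
  rec <- vcf_records(truth, reference)
  o <- order(rec$contig, rec$pos)
  info <- sprintf("ORIGIN=%s;TAF=%s;VCLASS=%s", truth$origin,
                  formatC(truth$expected_af, digits = 6, format = "g"),
                  truth$vclass)
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                  rec$contig[o], rec$pos[o], rec$id[o], rec$ref[o],
                  rec$alt[o], info[o])
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a truth-set VCF written by [write_truth_vcf()]
#' @param path VCF path.
#' @param label Sample label for the reconstructed set.
#' @return A [truth_set()] tibble.
#' @export
read_truth_vcf <- function(path, label = "sample") {
  v <- read_vcf_variants(path, origin = NULL)
  if (!"expected_af" %in% names(v)) v$expected_af <- NA_real_
  truth_set(v, label = label)
}

#' Histogram of true allele frequencies
#'
#' Bins expected allele frequencies into left-open right-closed bins on
#' (0, 1] (so AF = 1 lands in the last bin), separately for somatic and
#' germline records. Across an admixture series, the somatic mass shifts
#' into the low-frequency bins as admixture grows.
#'
#' @param truth A [truth_set()], or a tibble with `origin` and
#'   `expected_af` columns.
#' @param bins Number of equal-width bins on (0, 1].
#' @return Tibble with `bin`, `af_low`, `af_high`, `somatic`, `germline`.
#' @export
af_histogram <- function(truth, bins = 10) {
  stopifnot(bins >= 1)
  brk <- seq(0, 1, length.out = bins + 1)
  cut_idx <- function(af) {
    if (length(af) == 0) return(integer(0))
    pmin(pmax(ceiling(af * bins), 1L), bins)
  }
  tab <- function(af) tabulate(cut_idx(af), nbins = bins)
  tibble(bin = seq_len(bins),
         af_low = brk[-length(brk)], af_high = brk[-1],
         somatic = tab(truth$expected_af[truth$origin == "somatic"]),
         germline = tab(truth$expected_af[truth$origin == "germline"]))
}

#' Per-bin variant density along the genome
#'
#' Counts truth records in fixed-width genomic bins, split by origin and by
#' SNV/indel class — the tabular form of a circular variant-density plot.
#'
#' @param truth A [truth_set()] (or variant tibble with `contig`, `pos`,
#'   `vclass`, `origin`).
#' @param bin_size Bin width in bases (e.g. `1e6`).
#' @return Tibble with `contig`, `bin` (1-based index), `bin_start`
#'   (0-based), `origin`, `class` (`"SNV"` or `"indel"`) and `n`.
#' @export
variant_density <- function(truth, bin_size = 1e6) {
  stopifnot(bin_size > 0)
  as_tibble(truth) |>
    mutate(bin = as.integer(ceiling(.data$pos / bin_size)),
           class = ifelse(.data$vclass == "SNV", "SNV", "indel")) |>
    count(.data$contig, .data$bin, .data$origin, .data$class, name = "n") |>
    mutate(bin_start = (.data$bin - 1L) * as.integer(bin_size)) |>
    select("contig", "bin", "bin_start", "origin", "class", "n") |>
    arrange(.data$contig, .data$bin, .data$origin, .data$class)
}
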