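# Independent oracles and tiny fixture builders used across the suite.

# Marker-based string-surgery oracle: the reference is a vector of single
# bases each tagged with its reference position; edits are applied one at a
# time directly on that vector (insertions carry NA tags). Gives both the
# edited sequence and the exact reference -> haplotype position map without
# any ledger arithmetic.
oracle_surgery <- function(refseq, variants) {
  bases <- strsplit(refseq, "")[[1]]
  tags <- seq_along(bases)
  v <- variants[order(-variants$pos), , drop = FALSE] # right-to-left
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    at <- match(p, tags)
    if (v$vclass[i] == "SNV") {
      bases[at] <- v$alt[i]
    } else if (v$vclass[i] == "DEL") {
      span <- at:(at + nchar(v$ref[i]) - 1L)
      bases <- bases[-span]; tags <- tags[-span]
    } else { # INS after p
      ins <- strsplit(v$alt[i], "")[[1]]
      bases <- append(bases, ins, after = at)
      tags <- append(tags, rep(NA_integer_, length(ins)), after = at)
    }
  }
  list(seq = paste(bases, collapse = ""),
       # haplotype position of each reference base (NA if deleted)
       map = match(seq_len(nchar(refseq)), tags))
}

make_variants <- function(contig, pos, ref, alt, vclass,
                          origin = "somatic", id = NULL) {
  variant_table(tibble::tibble(
    id = id %||% paste0("v", seq_along(pos)), contig = contig, pos = pos,
    ref = ref, alt = alt, vclass = vclass, origin = origin))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_reference <- function(len, seed) {
  admixbench::simulate_reference(1, len, seed = seed)
}

# Random non-overlapping edit set (mixture of SNV/INS/DEL) on one contig.
random_edit_set <- function(refseq, n_edits, seed) {
  set.seed(seed)
  L <- nchar(refseq)
  pos <- sort(sample.int(L - 10L, n_edits))
  keep <- c(TRUE, diff(pos) >= 8L)
  pos <- pos[keep]
  cls <- sample(c("SNV", "INS", "DEL"), length(pos), replace = TRUE,
                prob = c(0.6, 0.2, 0.2))
  ref <- character(length(pos)); alt <- character(length(pos))
  for (i in seq_along(pos)) {
    b <- substring(refseq, pos[i], pos[i])
    if (cls[i] == "SNV") {
      ref[i] <- b
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    } else if (cls[i] == "INS") {
      ref[i] <- ""
      alt[i] <- paste(sample(c("A", "C", "G", "T"), sample(1:5, 1),
                             replace = TRUE), collapse = "")
    } else {
      len <- sample(1:5, 1)
      ref[i] <- substring(refseq, pos[i], pos[i] + len - 1L)
      alt[i] <- ""
    }
  }
  make_variants("chr1", pos, ref, alt, cls)
}

# Tiny end-to-end fixture shared by caller / readsim tests.
small_run_config <- function(master_seed = 11, levels = c(0, 0.5),
                             coverage = 40, n_germline = 30,
                             n_somatic = 30, contig_length = 15000,
                             ...) {
  admixbench::run_config(
    master_seed = master_seed, contig_length = contig_length,
    n_targets = 8, target_length = 500, n_germline = n_germline,
    n_somatic = n_somatic, admixture_levels = levels,
    read_sim = admixbench::read_sim_config("exome", coverage = coverage,
                                           seed = 1),
    ...)
}
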