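#' Read-simulation configuration
#'
#' Presets mirror common targeted designs: whole-exome capture (100 bp
#' reads, insert 300 +/- 100, median coverage 70x) and a high-coverage gene
#' panel (insert 200 +/- 50, median coverage 520x). The error model injects
#' substitutions, insertions and deletions at independent per-base rates;
#' base qualities follow a linear decay from `q_start` at the first cycle
#' to `q_end` at the last and are cosmetic (the bundled caller uses counts).
#'
#' @param preset `"exome"` or `"panel"`; sets insert size and coverage
#'   defaults, all overridable.
#' @param read_length Read length in bases.
#' @param insert_mean,insert_sd Fragment (insert) size distribution;
#'   truncated below at `read_length`.
#' @param coverage Target median on-target coverage (fold).
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities, each in
#'   `[0, 0.1]`.
#' @param q_start,q_end Phred qualities at first/last cycle.
#' @param seed Integer seed; one seed drives the whole simulation.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(preset = c("exome", "panel"),
                            read_length = 100,
                            insert_mean = NULL, insert_sd = NULL,
                            coverage = NULL,
                            sub_rate = 1e-3, ins_rate = 1e-4,
                            del_rate = 1e-4,
                            q_start = 37, q_end = 30, seed = 1L) {
  preset <- match.arg(preset)
  defaults <- list(exome = list(im = 300, is = 100, cov = 70),
                   panel = list(im = 200, is = 50, cov = 520))[[preset]]
  cfg <- list(preset = preset,
              read_length = as.integer(read_length),
              insert_mean = insert_mean %||% defaults$im,
              insert_sd = insert_sd %||% defaults$is,
              coverage = coverage %||% defaults$cov,
              sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
              q_start = q_start, q_end = q_end, seed = as.integer(seed))
  if (cfg$insert_mean < cfg$read_length) {
    abort("insert_mean must be at least read_length")
  }
  if (any(c(cfg$sub_rate, cfg$ins_rate, cfg$del_rate) < 0) ||
      any(c(cfg$sub_rate, cfg$ins_rate, cfg$del_rate) > 0.1)) {
    abort("error rates must lie in [0, 0.1]")
  }
  if (cfg$coverage <= 0) abort("coverage must be positive")
  structure(cfg, class = "read_sim_config")
}

#' Number of fragments needed for a target coverage
#'
#' `N = coverage * total_target_bases / (2 * read_length)`: each fragment
#' contributes two reads, and only read bases count toward coverage.
#'
#' @param cfg A [read_sim_config()].
#' @param targets A [target_regions()] tibble.
#' @return Integer fragment count.
#' @export
plan_fragment_count <- function(cfg, targets) {
  tb <- target_total_bases(targets)
  if (nrow(targets) == 0 || tb == 0) abort("target set is empty")
  as.integer(round(cfg$coverage * tb / (2 * cfg$read_length)))
}

#' Build the genome pool of an admixed tumor sample
#'
#' Encodes the fragment-source model: a fragment is drawn from the control
#' genome with probability `admixture`; otherwise it picks a parental
#' lineage with probability 1/2 and then one cancer genome by that
#' lineage's mixture weights.
#'
#' @param control List with `maternal` and `paternal` control
#'   [implant_variants()] haplotypes.
#' @param cancer List with `maternal` and `paternal` lists of cancer
#'   haplotypes (one per subclone), or `NULL` for a pure control sample.
#' @param mixture A [draw_mixture()] result (ignored when `cancer` is NULL).
#' @param admixture Fraction of control material in `[0, 1]`.
#' @return A list of class `genome_pool` with `genomes`, `prob`, `labels`.
#' @export
admixed_genome_pool <- function(control, cancer = NULL, mixture = NULL,
                                admixture = 0) {
  stopifnot(admixture >= 0, admixture <= 1)
  if (is.null(cancer)) admixture <- 1
  genomes <- list(control$maternal, control$paternal)
  labels <- c("control.maternal", "control.paternal")
  prob <- c(admixture / 2, admixture / 2)
  if (!is.null(cancer)) {
    stopifnot(inherits(mixture, "clone_mixture"),
              length(cancer$maternal) == length(mixture$maternal),
              length(cancer$paternal) == length(mixture$paternal))
    genomes <- c(genomes, cancer$maternal, cancer$paternal)
    labels <- c(labels,
                paste0("tumor.maternal.", seq_along(cancer$maternal)),
                paste0("tumor.paternal.", seq_along(cancer$paternal)))
    prob <- c(prob, (1 - admixture) / 2 * mixture$maternal,
              (1 - admixture) / 2 * mixture$paternal)
  }
  structure(list(genomes = genomes, prob = prob, labels = labels),
            class = "genome_pool")
}

#' Simulate targeted paired-end reads from a genome pool
#'
#' Fragments are placed uniformly over lifted target intervals (any overlap
#' of at least one base counts, emulating capture flanks), read inward
#' `read_length` bases from both ends, and pushed through the error model.
#' Probe hybridization is not modeled. Every read also carries its truth
#' alignment: reference position and CIGAR derived from the source
#' haplotype's coordinate map composed with injected read errors.
#'
#' @param pool An [admixed_genome_pool()].
#' @param targets A [target_regions()] tibble (reference coordinates).
#' @param cfg A [read_sim_config()].
#' @param runid Run identifier used in read names
#'   (`"<runid>:<fragment>:<1|2>"`).
#' @param n_fragments Override the planned fragment count (default
#'   [plan_fragment_count()]).
#' @return A tibble of class `read_set` with one row per read: `qname`,
#'   `fragment`, `mate`, `genome` (pool label), `contig`, `hap_start`,
#'   `is_reverse`, `seq` (genome orientation), `ref_pos`, `cigar`,
#'   `mapped`, `ref_span`.
#' @export
simulate_reads <- function(pool, targets, cfg, runid = "run",
                           n_fragments = NULL) {
  stopifnot(inherits(pool, "genome_pool"), inherits(cfg, "read_sim_config"))
  n_fragments <- n_fragments %||% plan_fragment_count(cfg, targets)
  rl <- cfg$read_length
  with_seed(cfg$seed, {
    gidx <- sample.int(length(pool$genomes), n_fragments, replace = TRUE,
                       prob = pool$prob)
    rev1 <- stats::runif(n_fragments) < 0.5 # fragment strand
    pieces <- list()
    for (g in sort(unique(gidx))) {
      idx <- which(gidx == g)
      hap <- pool$genomes[[g]]
      frag <- place_fragments(hap, targets, cfg, length(idx))
      if (nrow(frag) == 0) next
      frag$fragment <- idx[frag$slot]
      frag$rev1 <- rev1[frag$fragment]
      frag$genome <- pool$labels[g]
      reads <- extract_reads(hap, frag, cfg)
      pieces[[length(pieces) + 1L]] <- reads
    }
    reads <- bind_rows(pieces)
    reads <- arrange(reads, .data$fragment, .data$mate)
    reads$qname <- paste0(runid, ":", reads$fragment, ":", reads$mate)
    class(reads) <- c("read_set", class(reads))
    attr(reads, "config") <- cfg
    reads
  })
}

# Sample fragment placements for one haplotype: target by length, insert
# length truncated-normal, uniform placement overlapping the lifted target.
place_fragments <- function(hap, targets, cfg, n) {
  rl <- cfg$read_length
  lt <- lifted_targets(hap, targets)
  if (nrow(lt) == 0) abort("no target interval survives on the haplotype")
  hap_len <- vapply(hap$sequences, nchar, integer(1))
  draw <- function(n, slot) {
    tsel <- sample.int(nrow(lt), n, replace = TRUE, prob = lt$len)
    L <- as.integer(round(stats::rnorm(n, cfg$insert_mean, cfg$insert_sd)))
    while (any(short <- L < rl)) {
      L[short] <- as.integer(round(stats::rnorm(sum(short), cfg$insert_mean,
                                                cfg$insert_sd)))
    }
    lo <- lt$hstart1[tsel] - L + 1L
    hi <- lt$hend1[tsel]
    f <- lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
    tibble(slot = slot, contig = lt$contig[tsel], start = f, len = L)
  }
  out <- draw(n, seq_len(n))
  for (try in 1:10) {
    bad <- out$start < 1L | out$start + out$len - 1L > hap_len[out$contig]
    if (!any(bad)) break
    out[bad, c("contig", "start", "len")] <-
      draw(sum(bad), out$slot[bad])[c("contig", "start", "len")]
  }
  bad <- out$start < 1L | out$start + out$len - 1L > hap_len[out$contig]
  if (any(bad)) {
    warn(paste0(sum(bad), " fragment(s) could not be placed within a ",
                "contig and were skipped"))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

lifted_targets <- function(hap, targets) {
  n <- nrow(targets)
  hs <- integer(n); he <- integer(n)
  for (i in seq_len(n)) {
    iv <- lift_interval(hap$coord_map, targets$contig[i], targets$start[i],
                        targets$end[i])
    hs[i] <- iv[1]; he[i] <- iv[2]
  }
  out <- tibble(contig = targets$contig, hstart1 = hs + 1L, hend1 = he,
                len = he - hs)
  out[out$len > 0, , drop = FALSE]
}

# Cut both mates out of the haplotype, inject errors, derive truth CIGARs.
extract_reads <- function(hap, frag, cfg) {
  rl <- cfg$read_length
  r1 <- tibble(fragment = frag$fragment, mate = 1L, contig = frag$contig,
               genome = frag$genome, hap_start = frag$start,
               is_reverse = frag$rev1)
  r2 <- tibble(fragment = frag$fragment, mate = 2L, contig = frag$contig,
               genome = frag$genome,
               hap_start = frag$start + frag$len - rl,
               is_reverse = !frag$rev1)
  reads <- bind_rows(r1, r2)
  n <- nrow(reads)
  seqs <- character(n)
  for (ctg in unique(reads$contig)) {
    i <- reads$contig == ctg
    seqs[i] <- substring(hap$sequences[[ctg]], reads$hap_start[i],
                         reads$hap_start[i] + rl - 1L)
  }
  reads$seq <- seqs
  reads$n_template <- rep(rl, n)
  walks <- vector("list", n) # NULL = plain rl-base match walk

  # error injection: substitutions in place, indel errors via per-base walk
  if (cfg$ins_rate > 0 || cfg$del_rate > 0) {
    k_indel <- stats::rbinom(n, rl, cfg$ins_rate + cfg$del_rate)
    for (i in which(k_indel > 0)) {
      err <- walk_with_errors(hap$sequences[[reads$contig[i]]],
                              reads$hap_start[i], rl, cfg)
      reads$seq[i] <- err$seq
      reads$n_template[i] <- err$n_template
      walks[[i]] <- err$walk
    }
    plain <- which(k_indel == 0)
  } else {
    plain <- seq_len(n)
  }
  if (cfg$sub_rate > 0 && length(plain) > 0) {
    k_sub <- stats::rbinom(length(plain), rl, cfg$sub_rate)
    for (j in which(k_sub > 0)) {
      i <- plain[j]
      s <- strsplit(reads$seq[i], "")[[1]]
      at <- sample.int(length(s), min(k_sub[j], length(s)))
      s[at] <- vapply(s[at], sub_base, character(1))
      reads$seq[i] <- paste(s, collapse = "")
    }
  }
  truth <- truth_alignment(hap$coord_map, reads, walks)
  bind_cols(reads, truth)
}

sub_base <- function(b) {
  alt <- setdiff(DNA_BASES, b)
  alt[sample.int(length(alt), 1)]
}

# Per-base error walk over the template: each template base is dropped with
# del_rate, otherwise emitted (substituted with sub_rate) and followed by an
# inserted random base with ins_rate, until read_length bases are emitted.
walk_with_errors <- function(contig_seq, start, rl, cfg) {
  clen <- nchar(contig_seq)
  tmpl <- strsplit(substring(contig_seq, start,
                             min(start + rl + 8L - 1L, clen)), "")[[1]]
  out <- character(rl + 8L); walk <- character(2L * (rl + 8L))
  no <- 0L; nw <- 0L; t <- 0L
  while (no < rl && t < length(tmpl)) {
    t <- t + 1L
    if (stats::runif(1) < cfg$del_rate) {
      nw <- nw + 1L; walk[nw] <- "D"
      next
    }
    b <- tmpl[t]
    if (stats::runif(1) < cfg$sub_rate) b <- sub_base(b)
    no <- no + 1L; out[no] <- b
    nw <- nw + 1L; walk[nw] <- "M"
    if (no < rl && stats::runif(1) < cfg$ins_rate) {
      no <- no + 1L; out[no] <- DNA_BASES[sample.int(4L, 1L)]
      nw <- nw + 1L; walk[nw] <- "I"
    }
  }
  list(seq = paste(out[seq_len(no)], collapse = ""), n_template = t,
       walk = walk[seq_len(nw)])
}
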