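#' Assign somatic variants to subclonal cancer genomes
#'
#' Each somatic variant independently enters each of the `2 * n_per_lineage`
#' cancer genomes (maternal and paternal pools) with probability
#' `inclusion_prob`; variants drawn into zero genomes are re-drawn until
#' they land in at least one, so every somatic variant is present somewhere
#' in the tumor. Germline variants are not assigned here: they ride along on
#' their carrier haplotype(s) into every cancer genome of that lineage.
#'
#' @param somatic_variants A [variant_table()] tibble of somatic variants
#'   (or anything with an `id` column).
#' @param n_per_lineage Number of cancer genomes per parental lineage.
#' @param inclusion_prob Per-genome inclusion probability in (0, 1].
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return An object of class `subclone_assignment`: a list with
#'   `membership` (tibble `id`, `lineage`, `genome`), `n_per_lineage` and
#'   `n_redrawn` (variants that needed at least one re-draw).
#' @export
assign_subclones <- function(somatic_variants, n_per_lineage = 5,
                             inclusion_prob = 0.5, seed = 1L) {
  stopifnot(n_per_lineage >= 1, inclusion_prob > 0, inclusion_prob <= 1)
  ids <- somatic_variants$id
  n_genomes <- 2L * as.integer(n_per_lineage)
  if (length(ids) == 0) {
    return(structure(list(
      membership = tibble(id = character(0), lineage = character(0),
                          genome = integer(0)),
      n_per_lineage = as.integer(n_per_lineage), n_redrawn = 0L),
      class = "subclone_assignment"))
  }
  memb <- with_seed(seed, {
    m <- matrix(stats::runif(length(ids) * n_genomes) < inclusion_prob,
                nrow = length(ids))
    n_redrawn <- 0L
    empty <- which(rowSums(m) == 0)
    n_redrawn <- length(empty)
    while (length(empty) > 0) {
      m[empty, ] <- matrix(stats::runif(length(empty) * n_genomes) <
                             inclusion_prob, nrow = length(empty))
      empty <- empty[rowSums(m[empty, , drop = FALSE]) == 0]
    }
    list(m = m, n_redrawn = n_redrawn)
  })
  hit <- which(memb$m, arr.ind = TRUE)
  lineage <- ifelse(hit[, 2] <= n_per_lineage, "maternal", "paternal")
  genome <- ifelse(hit[, 2] <= n_per_lineage, hit[, 2],
                   hit[, 2] - n_per_lineage)
  membership <- tibble(id = ids[hit[, 1]], lineage = lineage,
                       genome = as.integer(genome)) |>
    arrange(.data$id, .data$lineage, .data$genome)
  structure(list(membership = membership,
                 n_per_lineage = as.integer(n_per_lineage),
                 n_redrawn = memb$n_redrawn),
            class = "subclone_assignment")
}

#' @export
print.subclone_assignment <- function(x, ...) {
  cat("<subclone_assignment> ", length(unique(x$membership$id)),
      " somatic variant(s) across 2 x ", x$n_per_lineage,
      " cancer genomes\n", sep = "")
  invisible(x)
}

#' Draw randomized subclone mixture proportions
#'
#' Maternal and paternal genome pools are weighted independently; each
#' lineage's weights come from a flat (symmetric, concentration 1)
#' Dirichlet, i.e. uniform on the simplex, and sum to one.
#'
#' @param n_per_lineage Genomes per lineage.
#' @param seed Integer seed.
#' @return An object of class `clone_mixture`: list with numeric vectors
#'   `maternal` and `paternal`, each of length `n_per_lineage` summing to 1.
#' @export
draw_mixture <- function(n_per_lineage = 5, seed = 1L) {
  stopifnot(n_per_lineage >= 1)
  w <- with_seed(seed, {
    g <- matrix(stats::rexp(2L * n_per_lineage), nrow = 2)
    g / rowSums(g)
  })
  structure(list(maternal = w[1, ], paternal = w[2, ]),
            class = "clone_mixture")
}

#' @export
print.clone_mixture <- function(x, ...) {
  cat("<clone_mixture>\n  maternal:",
      paste(sprintf("%.3f", x$maternal), collapse = " "),
      "\n  paternal:", paste(sprintf("%.3f", x$paternal), collapse = " "),
      "\n")
  invisible(x)
}

#' Linear dilution of a tumor allele frequency by normal admixture
#'
#' A sample containing a fraction `admixture` of normal (control) material
#' shows a variant at `(1 - admixture) * af_tumor + admixture * control_af`.
#' A clonal somatic variant at 30% allele frequency in the tumor drops to a
#' 3% observed frequency at 90% admixture.
#'
#' @param af_tumor Allele frequency in the pure tumor.
#' @param admixture Fraction of normal material in `[0, 0.95]`.
#' @param control_af Allele frequency in the control genome (0 for somatic,
#'   0.5 heterozygous / 1 homozygous for germline).
#' @return Expected allele frequency in the admixed sample.
#' @export
dilute_af <- function(af_tumor, admixture, control_af = 0) {
  stopifnot(all(af_tumor >= 0 & af_tumor <= 1),
            all(admixture >= 0 & admixture <= 0.95),
            all(control_af >= 0 & control_af <= 1))
  (1 - admixture) * af_tumor + admixture * control_af
}

#' Expected allele frequency of every variant in an admixed sample
#'
#' A sequenced fragment comes from the control genome with probability
#' `admixture`; otherwise it picks a parental lineage with probability 1/2
#' and then a cancer genome by that lineage's mixture weights. The expected
#' allele frequency of a variant is therefore
#' `AF_tumor = 1/2 * sum(w_maternal[members]) + 1/2 * sum(w_paternal[members])`
#' diluted linearly with the control allele frequency via [dilute_af()].
#' Germline variants are carried by every cancer genome of their lineage(s),
#' so their AF is admixture-invariant (0.5 het, 1 hom).
#'
#' @param variants Variant tibble; somatic rows need membership in
#'   `assignment`, germline rows need a `lineage` column (`"maternal"`,
#'   `"paternal"` or `"both"`).
#' @param assignment A [assign_subclones()] result.
#' @param mixture A [draw_mixture()] result.
#' @param admixture Fraction of normal material in `[0, 0.95]`.
#' @return The input tibble with `af_tumor`, `control_af` and `expected_af`
#'   columns added.
#' @export
expected_af <- function(variants, assignment, mixture, admixture) {
  stopifnot(inherits(assignment, "subclone_assignment"),
            inherits(mixture, "clone_mixture"),
            admixture >= 0, admixture <= 0.95)
  v <- as_tibble(variants)
  memb <- assignment$membership
  wsum <- memb |>
    mutate(w = ifelse(.data$lineage == "maternal",
                      mixture$maternal[.data$genome],
                      mixture$paternal[.data$genome])) |>
    group_by(.data$id) |>
    summarise(af_tumor = sum(.data$w) / 2, .groups = "drop")
  v <- left_join(v, wsum, by = "id")

  is_g <- v$origin == "germline"
  if (any(is_g)) {
    if (!"lineage" %in% names(v)) {
      abort("germline variants need a `lineage` column (maternal/paternal/both)")
    }
    glin <- v$lineage[is_g]
    v$af_tumor[is_g] <- ifelse(glin == "both", 1, 0.5)
  }
  if (any(is.na(v$af_tumor))) {
    abort(paste0("variant(s) not in subclone assignment: ",
                 paste(utils::head(v$id[is.na(v$af_tumor)], 5),
                       collapse = ", ")))
  }
  v$control_af <- ifelse(is_g, v$af_tumor, 0)
  v$expected_af <- dilute_af(v$af_tumor, admixture, v$control_af)
  v
}

#' Build the admixture series of tumor samples
#'
#' One tumor sample per admixture level sharing a single subclone mixture,
#' emulating a dilution series of the same heterogeneous tumor with control
#' material. The default levels 0, 0.1, ..., 0.9 give ten tumor samples.
#'
#' @param mixture A [draw_mixture()] result.
#' @param levels Strictly increasing admixture fractions in `[0, 0.95]`.
#' @return A tibble with columns `label` and `admixture`, carrying the
#'   mixture in attribute `"mixture"`.
#' @export
admixture_series <- function(mixture, levels = seq(0, 0.9, by = 0.1)) {
  stopifnot(inherits(mixture, "clone_mixture"))
  if (anyDuplicated(levels)) abort("duplicate admixture level")
  if (is.unsorted(levels, strictly = TRUE)) {
    abort("admixture levels must be strictly increasing")
  }
  if (any(levels < 0 | levels > 0.95)) {
    abort("admixture levels must lie in [0, 0.95]")
  }
  out <- tibble(label = sprintf("tumor_a%02.0f", 100 * levels),
                admixture = levels)
  attr(out, "mixture") <- mixture
  out
}

#' Combine two diploid genotype sets into a mixed-sample truth set
#'
#' Models wet-lab mixing of DNA from two individuals at a given ratio (as in
#' two-reference-sample validation designs, e.g. a 1:7 mixture). Every
#' variant present in either sample enters the union truth set with allele
#' frequency `(1 - ratio) * AF_a + ratio * AF_b`, where a heterozygous
#' genotype contributes 0.5 and a homozygous one 1. The resulting
#' frequencies are discrete multiples of `ratio / 2` and `(1 - ratio) / 2`.
#'
#' @param sample_a,sample_b Tibbles with columns `contig`, `pos`, `ref`,
#'   `alt`, `gt` (`"het"` or `"hom"`).
#' @param ratio Fraction of `sample_b` material, in (0, 1).
#' @return A tibble with columns `contig`, `pos`, `ref`, `alt`, `af_a`,
#'   `af_b`, `expected_af`.
#' @export
mix_two_genomes <- function(sample_a, sample_b, ratio) {
  stopifnot(ratio > 0, ratio < 1)
  gt_af <- function(s, col) {
    stopifnot(all(s$gt %in% c("het", "hom")))
    s |>
      transmute(.data$contig, .data$pos, .data$ref, .data$alt,
                af = ifelse(.data$gt == "hom", 1, 0.5)) |>
      stats::setNames(c("contig", "pos", "ref", "alt", col))
  }
  a <- gt_af(as_tibble(sample_a), "af_a")
  b <- gt_af(as_tibble(sample_b), "af_b")
  merged <- full_join(a, b, by = c("contig", "pos", "alt"),
                      suffix = c("_a", "_b"))
  conflict <- !is.na(merged$ref_a) & !is.na(merged$ref_b) &
    merged$ref_a != merged$ref_b
  # a ref conflict at the same site is also visible across alt alleles
  site_ref <- bind_rows(
    a |> select("contig", "pos", ref = "ref"),
    b |> select("contig", "pos", ref = "ref")) |> distinct()
  multi_ref <- site_ref |> count(.data$contig, .data$pos) |>
    filter(.data$n > 1)
  if (any(conflict) || nrow(multi_ref) > 0) {
    abort("conflicting ref alleles between the two samples at a shared site")
  }
  merged |>
    transmute(.data$contig, .data$pos,
              ref = coalesce(.data$ref_a, .data$ref_b), .data$alt,
              af_a = coalesce(.data$af_a, 0),
              af_b = coalesce(.data$af_b, 0),
              expected_af = (1 - ratio) * .data$af_a + ratio * .data$af_b) |>
    arrange(.data$contig, .data$pos, .data$alt)
}
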