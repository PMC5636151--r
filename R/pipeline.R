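#' Configuration for a full simulation-and-evaluation run
#'
#' Bundles every stage's parameters around one master seed. Each stochastic
#' stage derives its own seed from the master via [derive_seed()] with a
#' stage label, so any stage can be replayed independently and a run is
#' byte-reproducible from the master seed alone.
#'
#' @param master_seed Master seed (integer).
#' @param n_contigs,contig_length,gc Synthetic reference shape, or give
#'   `reference_fasta` to use a file instead.
#' @param reference_fasta Optional path to a reference FASTA.
#' @param n_targets,target_length Synthetic capture design, or give
#'   `targets_bed`.
#' @param targets_bed Optional BED path.
#' @param n_germline,germline_indel_fraction,het_hom_ratio Germline model.
#' @param n_somatic,hypermutation_multiplier Somatic model.
#' @param n_per_lineage,inclusion_prob Subclone structure.
#' @param admixture_levels Admixture series (strictly increasing, in
#'   `[0, 0.95]`).
#' @param read_sim A [read_sim_config()] (its `seed` is overridden per
#'   sample from the master seed).
#' @param caller_grid List of [caller_params()] swept at each level.
#' @param match_mode Evaluation matching mode.
#' @return A list of class `run_config`.
#' @export
run_config <- function(master_seed = 1L,
                       n_contigs = 1, contig_length = 5e4, gc = 0.41,
                       reference_fasta = NULL,
                       n_targets = 20, target_length = 400,
                       targets_bed = NULL,
                       n_germline = 80, germline_indel_fraction = 0.1,
                       het_hom_ratio = 2,
                       n_somatic = 60, hypermutation_multiplier = 1,
                       n_per_lineage = 5, inclusion_prob = 0.5,
                       admixture_levels = seq(0, 0.9, by = 0.1),
                       read_sim = read_sim_config("exome", coverage = 60),
                       caller_grid = list(caller_params()),
                       match_mode = "position_allele") {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Generate the synthetic inputs of a run
#'
#' Reference, capture targets and germline/somatic variant lists, each from
#' its own derived seed. Deterministic given the master seed.
#'
#' @param cfg A [run_config()].
#' @return List with `reference`, `targets`, `germline`, `somatic`.
#' @export
generate_fixture <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  reference <- if (!is.null(cfg$reference_fasta)) {
    read_reference_fasta(cfg$reference_fasta)
  } else {
    simulate_reference(cfg$n_contigs, cfg$contig_length, cfg$gc,
                       seed = derive_seed(cfg$master_seed, "reference"))
  }
  targets <- if (!is.null(cfg$targets_bed)) {
    read_targets_bed(cfg$targets_bed)
  } else {
    simulate_targets(reference, cfg$n_targets, cfg$target_length,
                     seed = derive_seed(cfg$master_seed, "targets"))
  }
  variants <- simulate_variant_table(
    reference, targets, n_germline = cfg$n_germline,
    germline_indel_fraction = cfg$germline_indel_fraction,
    het_hom_ratio = cfg$het_hom_ratio, n_somatic = cfg$n_somatic,
    hypermutation_multiplier = cfg$hypermutation_multiplier,
    seed = derive_seed(cfg$master_seed, "variants"))
  list(reference = reference, targets = targets,
       germline = variants[variants$origin == "germline", ],
       somatic = variants[variants$origin == "somatic", ])
}

#' Run the full pipeline: fixture, genomes, reads, calls, evaluation
#'
#' One sub-run per admixture level: simulate reads from the admixed genome
#' pool, write FASTQ plus truth alignments and truth VCF, sweep the caller
#' grid, and score every callset against the somatic truth. Control reads
#' are simulated once and reused across levels, as one control sample
#' serves all tumors.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created). `NULL` keeps everything in
#'   memory and writes nothing.
#' @return A list of class `run_result`: `fixture`, `truth` (per-level
#'   truth sets), `results` (evaluation tibble, one row per level x
#'   parameter set), `best` (best row per level), `curve`
#'   ([admixture_curve()] of the best rows), `manifest`.
#' @export
run_all <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  log_msg <- function(stage, ...) {
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", stage, "] ", ...)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  fx <- generate_fixture(cfg)
  log_msg("fixture", length(fx$reference), " contig(s), ",
          nrow(fx$germline), " germline + ", nrow(fx$somatic),
          " somatic variants, ", nrow(fx$targets), " target intervals")
  control <- forge_control_genome(fx$reference, fx$germline)
  assignment <- assign_subclones(
    fx$somatic, n_per_lineage = cfg$n_per_lineage,
    inclusion_prob = cfg$inclusion_prob,
    seed = derive_seed(cfg$master_seed, "subclones"))
  cancer <- forge_cancer_genomes(fx$reference, fx$germline, fx$somatic,
                                 assignment)
  mixture <- draw_mixture(cfg$n_per_lineage,
                          seed = derive_seed(cfg$master_seed, "mixture"))
  series <- admixture_series(mixture, cfg$admixture_levels)
  log_msg("genomes", "forged 2 control + ", 2 * cfg$n_per_lineage,
          " cancer haplotypes; ", nrow(series), " tumor sample(s)")

  if (!is.null(out_dir)) {
    write_fasta(fx$reference, file.path(out_dir, "reference.fa"))
    write_targets_bed(fx$targets, file.path(out_dir, "targets.bed"))
    write_variants_tsv(bind_rows(fx$germline, fx$somatic),
                       file.path(out_dir, "variants.tsv"))
    jsonlite::write_json(
      list(seed = cfg$master_seed,
           maternal_weights = mixture$maternal,
           paternal_weights = mixture$paternal,
           membership = assignment$membership,
           n_redrawn = assignment$n_redrawn),
      file.path(out_dir, "mixture.json"), auto_unbox = TRUE, digits = NA)
  }

  # control sample: pure control pool, simulated once
  ctrl_cfg <- cfg$read_sim
  ctrl_cfg$seed <- derive_seed(cfg$master_seed, "reads:control")
  ctrl_pool <- admixed_genome_pool(control)
  ctrl_reads <- simulate_reads(ctrl_pool, fx$targets, ctrl_cfg,
                               runid = "control")
  log_msg("reads", "control: ", nrow(ctrl_reads), " reads")
  if (!is.null(out_dir)) {
    write_fastq(ctrl_reads, file.path(out_dir, "control"))
    write_truth_sam(ctrl_reads, fx$reference,
                    file.path(out_dir, "control.sam"))
  }

  results <- list(); truths <- list(); files <- list()
  for (i in seq_len(nrow(series))) {
    a <- series$admixture[i]
    lab <- series$label[i]
    af <- expected_af(bind_rows(fx$germline, fx$somatic), assignment,
                      mixture, a)
    truth <- truth_set(af, label = lab, targets = fx$targets)
    truths[[lab]] <- truth
    pool <- admixed_genome_pool(control, cancer, mixture, a)
    rs_cfg <- cfg$read_sim
    rs_cfg$seed <- derive_seed(cfg$master_seed, paste0("reads:", lab))
    reads <- simulate_reads(pool, fx$targets, rs_cfg, runid = lab)
    sam <- file.path(if (is.null(out_dir)) tempdir() else out_dir,
                     paste0(lab, ".sam"))
    write_truth_sam(reads, fx$reference, sam)
    if (!is.null(out_dir)) {
      write_fastq(reads, file.path(out_dir, lab))
      write_truth_vcf(truth, file.path(out_dir, paste0(lab, ".truth.vcf")),
                      fx$reference)
    }
    sw <- sweep_params(sam, fx$reference, cfg$caller_grid)
    ev <- purrr::pmap(sw, function(params_id, params, callset) {
      e <- compare_calls(callset, truth[truth$origin == "somatic", ],
                         match_mode = cfg$match_mode, regions = fx$targets,
                         labels = list(tool = "baseline",
                                       params_id = params_id,
                                       admixture = a, sample = lab))
      if (!is.null(out_dir)) {
        write_callset_vcf(callset,
                          file.path(out_dir, paste0(lab, ".", params_id,
                                                    ".vcf")),
                          fx$reference)
      }
      glance(e)
    })
    results[[lab]] <- bind_rows(ev)
    log_msg("eval", lab, ": ", nrow(reads), " reads, best sensitivity ",
            sprintf("%.3f", max(results[[lab]]$sensitivity)))
  }
  results <- bind_rows(results)
  best <- select_best_params(results)
  curve <- admixture_curve(best)
  manifest <- list(
    master_seed = cfg$master_seed,
    config_hash = derive_seed(cfg$master_seed,
                              paste(deparse(cfg[setdiff(names(cfg),
                                                        "caller_grid")]),
                                    collapse = "")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S"),
    admixture_levels = cfg$admixture_levels,
    n_tumor_samples = nrow(series), n_control_samples = 1L,
    stage_seeds = c(
      list(reference = derive_seed(cfg$master_seed, "reference"),
           targets = derive_seed(cfg$master_seed, "targets"),
           variants = derive_seed(cfg$master_seed, "variants"),
           subclones = derive_seed(cfg$master_seed, "subclones"),
           mixture = derive_seed(cfg$master_seed, "mixture"))))
  if (!is.null(out_dir)) {
    utils::write.table(results, file.path(out_dir, "eval_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(curve, file.path(out_dir, "admixture_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(fixture = fx, assignment = assignment, mixture = mixture,
                 series = series, truth = truths, results = results,
                 best = best, curve = curve, manifest = manifest),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> ", nrow(x$series), " tumor sample(s) + 1 control, ",
      nrow(x$results), " evaluation(s)\n", sep = "")
  print(x$curve)
  invisible(x)
}
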