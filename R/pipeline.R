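#' Simulate a complete introgression-breeding study
#'
#' Builds the desk-scale genome and founder panel, constructs the recurrent
#' cultivar and the synthetic hexaploid donor (tetraploid founder on A/B,
#' diploid on D), runs the backcross-and-self plan with heading-date
#' selection, and simulates RNA-seq-like allele counts for the cultivar,
#' the two donor parents (each covering only its own subgenomes) and every
#' selected line.
#'
#' @param config Configuration list, see [default_run_config()].
#' @return List with `genome`, `panel`, `recurrent`, `donor`,
#'   `donor_founders`, `lines`, `truth` and `counts` (named list of
#'   `allele_counts`; donor parents under their founder labels).
#' @export
simulate_study <- function(config = default_run_config()) {
  seed <- config$seed
  genome <- make_default_genome(config$genome$scale_factor,
                                config$genome$genetic_length_cm)
  roles <- c(recurrent = config$founders$recurrent,
             donor_ab = config$founders$donor_ab,
             donor_d = config$founders$donor_d)
  panel <- sample_founder_panel(
    genome, config$genome$sites_per_chromosome, seed = derive_seed(seed, "panel"),
    roles = roles,
    recurrent_alt_fraction = config$founders$recurrent_alt_fraction,
    donor_alt_fraction = config$founders$donor_alt_fraction)

  recurrent <- founder_individual(genome, roles[["recurrent"]])
  donor <- founder_individual(
    genome, c(A = roles[["donor_ab"]], B = roles[["donor_ab"]], D = roles[["donor_d"]]),
    id = paste(roles[["donor_ab"]], roles[["donor_d"]], sep = "/"))

  qtl <- do.call(rbind, lapply(config$heading$qtl, function(q) {
    data.frame(chrom = q$chrom,
               pos = round((q$pos_frac %||% 0.5) * chrom_length(genome, q$chrom)),
               effect_days = q$effect_days)
  })) %||% data.frame(chrom = character(), pos = numeric(), effect_days = numeric())
  heading <- heading_model(config$heading$baseline_days, qtl, config$heading$noise_sd)
  plan <- cross_plan(config$plan$n_backcrosses, config$plan$n_selfings,
                     config$plan$population_size, config$plan$n_selected)
  ped <- run_cross_plan(plan, recurrent, donor, heading, genome,
                        seed = derive_seed(seed, "pedigree"))

  obs <- observation_model(config$observation$mean_depth,
                           config$observation$error_rate)
  obs_dip <- observation_model(config$observation$mean_depth,
                               config$observation$error_rate,
                               config$observation$diploid_coverage_scale %||% 1)
  ab_chroms <- genome$chrom[genome$subgenome %in% c("A", "B")]
  d_chroms <- genome$chrom[genome$subgenome == "D"]
  counts <- list()
  counts[[roles[["recurrent"]]]] <- simulate_allele_counts(
    recurrent, panel, obs, sample_id = roles[["recurrent"]],
    seed = derive_seed(seed, "obs_recurrent"))
  counts[[roles[["donor_ab"]]]] <- simulate_allele_counts(
    donor, panel, obs, sample_id = roles[["donor_ab"]], chromosomes = ab_chroms,
    seed = derive_seed(seed, "obs_donor_ab"))
  counts[[roles[["donor_d"]]]] <- simulate_allele_counts(
    donor, panel, obs_dip, sample_id = roles[["donor_d"]], chromosomes = d_chroms,
    seed = derive_seed(seed, "obs_donor_d"))
  for (ind in ped$lines) {
    counts[[ind$id]] <- simulate_allele_counts(
      ind, panel, obs, seed = derive_seed(seed, paste0("obs_", ind$id)))
  }
  list(genome = genome, panel = panel, recurrent = recurrent, donor = donor,
       donor_founders = ped$donor_founders, lines = ped$lines,
       truth = ped$truth, counts = counts)
}

#' Scan one line against its cultivar and the donor SNP set
#'
#' Chains [diff_snps()], [assign_origin()], [count_by_chromosome()] and
#' [segment_blocks()] for one selected line.
#'
#' @param line_calls,cultivar_calls `call_set`s on the shared panel.
#' @param donor_snps The donor `snp_set` from [build_donor_snpset()].
#' @param genome A [genome_spec()].
#' @param seg_params A [segmentation_params()].
#' @return List with `diff`, `assignment`, `counts_all`, `counts_donor`,
#'   `blocks`.
#' @export
scan_line <- function(line_calls, cultivar_calls, donor_snps, genome,
                      seg_params = segmentation_params()) {
  diff <- diff_snps(line_calls, cultivar_calls)
  assignment <- assign_origin(diff, donor_snps)
  list(diff = diff,
       assignment = assignment,
       counts_all = count_by_chromosome(assignment, genome),
       counts_donor = count_by_chromosome(assignment, genome, donor_only = TRUE),
       blocks = segment_blocks(assignment, seg_params, genome))
}

#' Run the full simulate-call-scan-report pipeline
#'
#' Simulates the study, writes per-sample VCFs and count TSVs, scans every
#' selected line, and writes per-line chromosome count tables (all diff
#' SNPs and donor-assigned only), introgression-block BED, ground-truth
#' BED, a graphical-genotype figure and a metrics JSON. All outputs are
#' reproducible bit-for-bit from (config, seed).
#'
#' @param config Configuration list, see [default_run_config()].
#' @param out_dir Output directory (defaults to `config$out_dir`).
#' @param plot Also write the graphical-genotype figure.
#' @return The metrics list, invisibly; side effect: files under `out_dir`.
#' @export
run_full_pipeline <- function(config = default_run_config(),
                              out_dir = config$out_dir, plot = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(config)
  rule <- call_rule(config$rule$min_depth, config$rule$min_fraction,
                    config$rule$strict %||% FALSE)
  seg <- segmentation_params(config$segmentation$max_gap_bp,
                             config$segmentation$min_markers)
  roles <- c(recurrent = config$founders$recurrent,
             donor_ab = config$founders$donor_ab,
             donor_d = config$founders$donor_d)

  calls <- lapply(study$counts, call_genotypes, rule = rule)
  for (sid in names(study$counts)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", sid)
    write_allele_counts_tsv(study$counts[[sid]],
                            file.path(out_dir, paste0("counts_", safe, ".tsv")))
    write_calls_vcf(calls[[sid]], file.path(out_dir, paste0("calls_", safe, ".vcf")))
  }
  donor_snps <- build_donor_snpset(study$counts[[roles[["donor_ab"]]]],
                                   study$counts[[roles[["donor_d"]]]], rule)
  cultivar_calls <- calls[[roles[["recurrent"]]]]

  metrics <- list(seed = config$seed, n_sites = nrow(study$panel$sites),
                  n_donor_snps = nrow(donor_snps), lines = list())
  assignments <- list()
  truth_bed <- file.path(out_dir, "truth_segments.bed")
  if (file.exists(truth_bed)) unlink(truth_bed)
  all_blocks <- NULL
  for (ind in study$lines) {
    res <- scan_line(calls[[ind$id]], cultivar_calls, donor_snps, study$genome, seg)
    assignments[[ind$id]] <- res$assignment
    safe <- gsub("[^A-Za-z0-9._-]", "_", ind$id)
    write_chrom_counts_tsv(res$counts_all,
                           file.path(out_dir, paste0("snp_counts_", safe, ".tsv")))
    write_chrom_counts_tsv(res$counts_donor,
                           file.path(out_dir, paste0("donor_snp_counts_", safe, ".tsv")))
    truth <- study$truth[[ind$id]]
    write_truth_bed(truth, ind$id, truth_bed, append = file.exists(truth_bed))
    rec <- evaluate_recovery(truth, res$blocks)
    blocks <- res$blocks
    if (nrow(blocks) > 0L) blocks$line <- ind$id
    all_blocks <- rbind(all_blocks, blocks)
    metrics$lines[[ind$id]] <- list(
      n_diff_snps = nrow(res$diff),
      n_donor_snps = sum(res$assignment$origin == "donor"),
      n_blocks = nrow(res$blocks),
      true_donor_fraction = donor_genome_fraction(ind, study$donor_founders,
                                                  study$genome),
      precision_bp = rec$precision_bp, recall_bp = rec$recall_bp,
      jaccard = rec$jaccard)
  }
  if (is.null(all_blocks)) {
    all_blocks <- data.frame(chrom = character(), start = numeric(),
                             end = numeric(), n_markers = integer(),
                             donor = character(), line = character())
  }
  bed_blocks <- all_blocks
  if (nrow(bed_blocks) > 0L) {
    bed_blocks$donor <- paste(bed_blocks$line, bed_blocks$donor, sep = "|")
  }
  class(bed_blocks) <- c("introgression_blocks", "data.frame")
  write_blocks_bed(bed_blocks, file.path(out_dir, "introgression_blocks.bed"),
                   header_comment = sprintf("intrograph blocks; seed=%s", config$seed))
  if (plot) {
    plot_graphical_genotype(assignments, study$genome,
                            file.path(out_dir, "graphical_genotypes.png"))
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(metrics)
}
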