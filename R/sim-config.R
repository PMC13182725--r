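#' Simulation configuration for the synthetic editome generator
#'
#' Describes a complete synthetic study: a toy genome with multi-exon genes, a
#' set of true A-to-I editing sites whose per-sample levels are driven by a
#' latent per-sample ADAR activity, germline variants, and planted
#' artifact-prone contaminant sites (homopolymer-embedded, splice-junction
#' proximal, read-end biased). The defaults describe the standard fixture used
#' throughout the package: two 100 kb chromosomes plus a small mitochondrial
#' chromosome, two groups of three samples, 200 true sites with beta(2, 5)
#' base levels, 100 heterozygous and 50 homozygous SNPs, 30 contaminants,
#' 50x mean exonic coverage and a 0.1% per-base error rate.
#'
#' @param n_samples_per_group samples per group.
#' @param group_labels character vector of group names.
#' @param coverage_mean target mean read depth over exonic bases.
#' @param read_length simulated read length (bases).
#' @param error_rate independent per-base sequencing error probability.
#' @param n_true_sites number of true A-to-I editing sites to plant.
#' @param editing_level_shape length-2 numeric, the beta(alpha, beta)
#'   parameters of the across-site base editing-level distribution.
#' @param adar_activity per-sample scalar in (0, 1] scaling all true levels;
#'   defaults to an evenly graded ramp from 0.5 to 0.95 across samples.
#' @param n_het_snps,n_hom_snps numbers of heterozygous / homozygous germline
#'   SNPs planted in expressed exons.
#' @param n_contaminant_sites number of artifact sites planted, split evenly
#'   across the classes `homopolymer`, `splice_junction` and `read_end`.
#' @param n_differential_sites number of true sites whose level is shifted in
#'   the last group (for differential-editing experiments).
#' @param differential_effect multiplicative level shift applied to
#'   differential sites in the last group (levels capped at 1).
#' @param chrom_sizes named integer vector of non-mitochondrial chromosome
#'   lengths.
#' @param mito_size length of the mitochondrial chromosome.
#' @param mito_chrom name of the mitochondrial chromosome.
#' @param genes_per_chrom genes simulated per non-mitochondrial chromosome.
#' @param expression_sdlog log-normal sd of per-gene relative expression.
#' @param seed integer seed; a fixed seed makes every emitted file
#'   byte-identical across runs.
#'
#' @return an object of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 7)
#' cfg$n_true_sites
simulation_config <- function(n_samples_per_group = 3L,
                              group_labels = c("control", "model"),
                              coverage_mean = 50,
                              read_length = 100L,
                              error_rate = 0.001,
                              n_true_sites = 200L,
                              editing_level_shape = c(2, 5),
                              adar_activity = NULL,
                              n_het_snps = 100L,
                              n_hom_snps = 50L,
                              n_contaminant_sites = 30L,
                              n_differential_sites = 0L,
                              differential_effect = 1,
                              chrom_sizes = c(chr1 = 100000L, chr2 = 100000L),
                              mito_size = 5000L,
                              mito_chrom = "chrM",
                              genes_per_chrom = 6L,
                              expression_sdlog = 0.3,
                              seed = 1L) {
  cfg <- list(
    n_samples_per_group = as.integer(n_samples_per_group),
    group_labels = as.character(group_labels),
    coverage_mean = as.numeric(coverage_mean),
    read_length = as.integer(read_length),
    error_rate = as.numeric(error_rate),
    n_true_sites = as.integer(n_true_sites),
    editing_level_shape = as.numeric(editing_level_shape),
    adar_activity = if (is.null(adar_activity)) NULL else as.numeric(adar_activity),
    n_het_snps = as.integer(n_het_snps),
    n_hom_snps = as.integer(n_hom_snps),
    n_contaminant_sites = as.integer(n_contaminant_sites),
    n_differential_sites = as.integer(n_differential_sites),
    differential_effect = as.numeric(differential_effect),
    chrom_sizes = chrom_sizes,
    mito_size = as.integer(mito_size),
    mito_chrom = as.character(mito_chrom),
    genes_per_chrom = as.integer(genes_per_chrom),
    expression_sdlog = as.numeric(expression_sdlog),
    seed = as.integer(seed)
  )
  n_samples <- cfg$n_samples_per_group * length(cfg$group_labels)
  if (is.null(cfg$adar_activity)) {
    cfg$adar_activity <- seq(0.5, 0.95, length.out = n_samples)
  }

  if (cfg$n_samples_per_group < 1L)
    stop_config("n_samples_per_group", "must be >= 1")
  if (length(cfg$group_labels) < 1L || anyDuplicated(cfg$group_labels))
    stop_config("group_labels", "must be a non-empty set of unique labels")
  if (cfg$coverage_mean <= 0) stop_config("coverage_mean", "must be positive")
  if (cfg$read_length < 20L) stop_config("read_length", "must be >= 20")
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    stop_config("error_rate", "must be a probability in [0, 1]")
  for (f in c("n_true_sites", "n_het_snps", "n_hom_snps",
              "n_contaminant_sites", "n_differential_sites")) {
    if (cfg[[f]] < 0L) stop_config(f, "must be >= 0")
  }
  if (cfg$n_differential_sites > cfg$n_true_sites)
    stop_config("n_differential_sites", "cannot exceed n_true_sites")
  if (length(cfg$editing_level_shape) != 2L || any(cfg$editing_level_shape <= 0))
    stop_config("editing_level_shape", "must be two positive beta parameters")
  if (length(cfg$adar_activity) != n_samples)
    stop_config("adar_activity", sprintf("must have one value per sample (%d)", n_samples))
  if (any(cfg$adar_activity <= 0) || any(cfg$adar_activity > 1))
    stop_config("adar_activity", "values must lie in (0, 1]")
  if (is.null(names(cfg$chrom_sizes)) || any(!nzchar(names(cfg$chrom_sizes))) ||
      anyDuplicated(names(cfg$chrom_sizes)))
    stop_config("chrom_sizes", "must be a uniquely named vector")
  if (any(cfg$chrom_sizes < 20000L))
    stop_config("chrom_sizes", "chromosomes must be >= 20 kb to host genes")
  if (cfg$mito_chrom %in% names(cfg$chrom_sizes))
    stop_config("mito_chrom", "must not collide with chrom_sizes names")
  if (cfg$mito_size < 1000L) stop_config("mito_size", "must be >= 1 kb")
  if (cfg$genes_per_chrom < 2L)
    stop_config("genes_per_chrom", "must be >= 2 (one gene per strand)")
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    stop_config("seed", "must be a single integer")

  structure(cfg, class = "simulation_config")
}

#' Sample sheet implied by a simulation configuration
#'
#' @param config a [simulation_config()].
#' @return data.table with columns `sample_id`, `group`, `adar_activity`.
#' @export
sim_design <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  groups <- rep(config$group_labels, each = config$n_samples_per_group)
  data.table(
    sample_id = paste0(groups, "_", rep(seq_len(config$n_samples_per_group),
                                        times = length(config$group_labels))),
    group = groups,
    adar_activity = config$adar_activity
  )
}
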