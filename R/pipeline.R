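#' Pipeline configuration
#'
#' A single object drives an end-to-end run: input paths (or a simulation
#' request), discovery thresholds, statistical settings and the seed. It
#' round-trips losslessly through JSON via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param out_dir output directory for all tables.
#' @param sam named character vector of per-sample SAM paths (ignored when
#'   `simulate` is given).
#' @param fasta,gtf,design,counts input paths (genome, annotation, sample
#'   design TSV, per-gene count TSV).
#' @param dbsnp,whitelist,repeat_bed optional resource paths (VCF/BED/BED).
#' @param mito_chrom mitochondrial chromosome name.
#' @param thresholds a [discovery_thresholds()].
#' @param alpha significance level for flags.
#' @param min_pairs minimum covered samples per correlation pair.
#' @param simulate optional [simulation_config()]; when present the inputs
#'   are generated under `out_dir/sim` first.
#' @param seed integer seed recorded in the run provenance.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sam = NULL, fasta = NULL, gtf = NULL,
                            design = NULL, counts = NULL,
                            dbsnp = NULL, whitelist = NULL, repeat_bed = NULL,
                            mito_chrom = "chrM",
                            thresholds = discovery_thresholds(),
                            alpha = 0.05, min_pairs = 5L,
                            simulate = NULL, seed = 1L) {
  structure(list(out_dir = out_dir, sam = sam, fasta = fasta, gtf = gtf,
                 design = design, counts = counts, dbsnp = dbsnp,
                 whitelist = whitelist, repeat_bed = repeat_bed,
                 mito_chrom = mito_chrom, thresholds = thresholds,
                 alpha = alpha, min_pairs = as.integer(min_pairs),
                 simulate = simulate, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$sam)) x$sam <- as.list(x$sam)  # keep sample names in JSON
  x$thresholds <- unclass(x$thresholds)
  if (!is.null(x$simulate)) {
    x$simulate <- unclass(x$simulate)
    x$simulate$chrom_sizes <- as.list(x$simulate$chrom_sizes)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- do.call(discovery_thresholds, x$thresholds)
  sim <- NULL
  if (!is.null(x$simulate)) {
    sims <- x$simulate
    sims$chrom_sizes <- unlist(sims$chrom_sizes)
    sim <- do.call(simulation_config, sims)
  }
  pipeline_config(out_dir = x$out_dir, sam = unlist(x$sam), fasta = x$fasta,
                  gtf = x$gtf, design = x$design, counts = x$counts,
                  dbsnp = x$dbsnp, whitelist = x$whitelist,
                  repeat_bed = x$repeat_bed, mito_chrom = x$mito_chrom,
                  thresholds = th, alpha = x$alpha, min_pairs = x$min_pairs,
                  simulate = sim, seed = x$seed)
}

#' Run the editome pipeline end to end
#'
#' Executes call, filter, quantify, annotate, differential test, correlation
#' and summary stages, writing every output table (tab-separated with a
#' `#`-prefixed provenance comment) under `config$out_dir`. Deterministic for
#' a fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @param verbose log progress.
#' @return a `run_report`: per-stage record counts, per-rule attrition, the
#'   thresholds used, and provenance (config path/hash, seed), plus the main
#'   result objects.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (verbose) message(sprintf(...))

  if (!is.null(config$simulate)) {
    note("simulating study under %s/sim", config$out_dir)
    man <- write_simulation(config$simulate, file.path(config$out_dir, "sim"))
    config$sam <- man$sam
    config$fasta <- man$fasta
    config$gtf <- man$gtf
    config$design <- man$design
    config$counts <- man$counts
    config$repeat_bed <- config$repeat_bed %||% man$repeats_bed
    # the simulated germline VCF stands in for the known-SNP exclusion list
    # (the role dbSNP plays on real data); the cross-sample germline-pattern
    # rule remains the backstop for variants absent from any catalogue
    config$dbsnp <- config$dbsnp %||% man$germline_vcf
    config$mito_chrom <- config$simulate$mito_chrom
  }
  for (f in c("sam", "fasta", "gtf", "design", "counts")) {
    if (is.null(config[[f]]))
      stop(sprintf("pipeline stage 'inputs' failed: '%s' not configured", f),
           call. = FALSE)
    missing <- !file.exists(unlist(config[[f]]))
    if (any(missing))
      stop(sprintf("pipeline stage 'inputs' failed: missing file(s) %s",
                   paste(unlist(config[[f]])[missing], collapse = ", ")),
           call. = FALSE)
  }

  seqs <- read_genome_fasta(config$fasta)
  annotation <- read_annotation_gtf(config$gtf)
  design <- read_pipeline_tsv(config$design)
  counts_dt <- read_pipeline_tsv(config$counts)
  alignments <- lapply(unlist(config$sam), read_sam)
  names(alignments) <- names(config$sam) %||%
    tools::file_path_sans_ext(basename(unlist(config$sam)))
  dbsnp <- if (!is.null(config$dbsnp)) read_vcf_positions(config$dbsnp)
  whitelist <- if (!is.null(config$whitelist)) read_bed(config$whitelist)
  repeats <- if (!is.null(config$repeat_bed)) read_bed(config$repeat_bed)

  prov <- sprintf("editome run seed=%d thresholds=%s", config$seed,
                  paste(names(config$thresholds),
                        vapply(config$thresholds, function(v)
                          paste(v, collapse = ":"), character(1)),
                        sep = "=", collapse = ","))

  note("discovering editing sites from %d samples", length(alignments))
  disc <- discover_editing_sites(alignments, seqs, annotation,
                                 mito_chrom = config$mito_chrom,
                                 thresholds = config$thresholds,
                                 dbsnp = dbsnp, whitelist = whitelist,
                                 repeat_mask = repeats, verbose = verbose)
  write_calls_vcf(disc$calls, file.path(config$out_dir, "candidate_calls.vcf"))
  write_bed(disc$sites, file.path(config$out_dir, "sites.bed"),
            name = paste0(disc$sites$chrom, ":", disc$sites$pos),
            strand = disc$sites$strand)
  lvl <- data.table(site_id = rownames(disc$matrix$levels),
                    as.data.table(disc$matrix$levels))
  write_pipeline_tsv(lvl, file.path(config$out_dir, "site_levels.tsv"), prov)
  cov <- data.table(site_id = rownames(disc$matrix$total),
                    as.data.table(disc$matrix$total))
  write_pipeline_tsv(cov, file.path(config$out_dir, "site_coverage.tsv"), prov)
  write_pipeline_tsv(disc$attrition, file.path(config$out_dir, "attrition.tsv"),
                     prov)

  note("quantifying expression (TPM)")
  cmat <- as.matrix(counts_dt[, -1])
  rownames(cmat) <- counts_dt[[1]]
  glen <- gene_exonic_lengths(annotation)
  tpm <- compute_tpm(cmat, glen)
  tpm_dt <- data.table(gene_id = rownames(tpm), as.data.table(tpm))
  write_pipeline_tsv(tpm_dt, file.path(config$out_dir, "expression_tpm.tsv"),
                     prov)

  note("annotating %d sites", nrow(disc$sites))
  ann <- annotate_sites(disc$sites, annotation, seqs)
  write_pipeline_tsv(ann, file.path(config$out_dir, "sites_annotated.tsv"),
                     prov)
  if (nrow(ann) > 0L) {
    dist <- annotation_distribution(ann)
    write_pipeline_tsv(data.table(region = names(dist), fraction = dist),
                       file.path(config$out_dir, "region_distribution.tsv"),
                       prov)
  }

  mat <- disc$matrix
  mat$groups <- design$group[match(mat$sample_ids, design$sample_id)]

  des <- NULL
  if (length(unique(mat$groups)) >= 2L && nrow(mat$levels) > 0L) {
    note("differential editing (binomial GLM + LRT)")
    des <- lrt_differential(mat)
    write_pipeline_tsv(des, file.path(config$out_dir, "differential_sites.tsv"),
                       prov)
  } else {
    note("differential stage skipped: fewer than two groups or no sites")
  }

  corr <- NULL
  if (nrow(disc$sites) > 0L) {
    note("editing-expression correlation")
    s2g <- data.table(site_id = paste0(ann$chrom, ":", ann$pos),
                      gene_id = ann$gene_id)
    corr <- editing_expression_correlation(mat, tpm, s2g,
                                           min_pairs = config$min_pairs,
                                           alpha = config$alpha,
                                           verbose = verbose)
    write_pipeline_tsv(corr, file.path(config$out_dir, "correlation.tsv"), prov)
  }

  note("summaries")
  overall <- overall_editing_level(mat)
  write_pipeline_tsv(overall, file.path(config$out_dir, "overall_editing.tsv"),
                     prov)
  pca <- NULL
  if (nrow(mat$levels) >= 2L && ncol(mat$levels) >= 2L) {
    pca <- pca_editing(mat, verbose = verbose)
    sc <- data.table(sample_id = mat$sample_ids,
                     as.data.table(pca$scores))
    sc[, variance_fraction := pca$variance_fraction[seq_len(.N)]]
    write_pipeline_tsv(sc, file.path(config$out_dir, "pca_scores.tsv"), prov)
  }
  ovl <- NULL
  groups <- unique(mat$groups)
  if (length(groups) >= 2L && length(groups) <= 4L && nrow(mat$levels) > 0L) {
    sets <- lapply(groups, function(g) {
      sel <- mat$groups == g
      rows <- which(rowSums(mat$levels[, sel, drop = FALSE] >=
                              config$thresholds$min_level &
                              mat$mask[, sel, drop = FALSE], na.rm = TRUE) >= 1L)
      rownames(mat$levels)[rows]
    })
    names(sets) <- groups
    ovl <- overlap_sets(sets)
    write_pipeline_tsv(data.table(region = names(ovl$regions),
                                  n = as.integer(ovl$regions)),
                       file.path(config$out_dir, "overlap_regions.tsv"), prov)
  }

  report <- structure(list(
    counts = data.table(
      stage = c("samples", "candidates", "a_to_i", "filtered_pass",
                "retained_sites", "annotated", "differential_tested"),
      n = c(length(alignments),
            disc$attrition$n[disc$attrition$stage == "candidates"],
            disc$attrition$n[disc$attrition$stage == "candidates"] -
              sum(disc$attrition$n[disc$attrition$stage %in%
                                     c("non_A_to_I", "ambiguous_strand")]),
            sum(disc$verdicts$status == "pass"),
            nrow(disc$sites), nrow(ann),
            if (is.null(des)) 0L else sum(!is.na(des$p_value)))),
    attrition = disc$attrition,
    thresholds = config$thresholds,
    seed = config$seed,
    out_dir = config$out_dir,
    sites = disc$sites, matrix = mat, annotation_records = ann,
    differential = des, correlation = corr, overall = overall,
    pca = pca, overlaps = ovl, tpm = tpm, discovery = disc
  ), class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("editome run report (seed", x$seed, ")\n")
  print(x$counts)
  cat("outputs under:", x$out_dir, "\n")
  invisible(x)
}

# union-of-exons length per gene
gene_exonic_lengths <- function(annotation) {
  ex <- as.data.table(annotation$exons)
  out <- ex[, list(len = sum(end - start + 1L)), by = gene_id]
  stats::setNames(out$len, out$gene_id)
}

write_calls_vcf <- function(calls, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pooled qualifying depth\">",
               "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Pooled alternate depth\">",
               "##INFO=<ID=AAF,Number=1,Type=Float,Description=\"Pooled alternative allele frequency\">",
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Oriented substitution class\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) > 0L) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tDP=%d;AD=%d;AAF=%.6g;CLASS=%s",
                       calls$chrom, calls$pos, calls$ref, calls$alt,
                       calls$depth, calls$alt_depth, calls$aaf,
                       calls$edit_class), con)
  }
  invisible(path)
}

#' Self-checking end-to-end demonstration
#'
#' Simulates a compact study, runs the full pipeline, and asserts the
#' headline recovery properties (precision/recall against the planted truth,
#' no surviving germline variants or contaminants, TPM normalisation).
#' Stops with the name of the first failing check.
#'
#' @param seed integer seed.
#' @param dir output directory (default: a temporary directory).
#' @param n_true_sites,coverage_mean compact study dimensions.
#' @return invisibly, a list with the `report` and the recovery metrics.
#' @export
demo_end_to_end <- function(seed = 1L, dir = tempfile("editome_demo_"),
                            n_true_sites = 120L, coverage_mean = 40) {
  sim_cfg <- simulation_config(seed = seed, n_true_sites = n_true_sites,
                               coverage_mean = coverage_mean,
                               n_het_snps = 60L, n_hom_snps = 30L,
                               n_contaminant_sites = 18L)
  cfg <- pipeline_config(out_dir = dir, simulate = sim_cfg, seed = seed)
  report <- run_pipeline(cfg, verbose = FALSE)
  truth <- report$discovery
  man_truth <- file.path(dir, "sim", "truth_sites.bed")
  tr_bed <- data.table::fread(man_truth, header = FALSE)
  truth_key <- paste(tr_bed$V1, tr_bed$V3)
  found_key <- paste(report$sites$chrom, report$sites$pos)
  tp <- sum(found_key %in% truth_key)
  precision <- if (length(found_key)) tp / length(found_key) else NA_real_
  recall <- tp / length(truth_key)
  germ <- read_vcf_positions(file.path(dir, "sim", "germline.vcf"))
  cont <- read_pipeline_tsv(file.path(dir, "sim", "contaminants.tsv"))
  checks <- list(
    precision_ge_0.95 = precision >= 0.95,
    recall_ge_0.85 = recall >= 0.85,
    zero_germline_survivors =
      sum(found_key %in% paste(germ$chrom, germ$pos)) == 0L,
    zero_contaminant_survivors =
      sum(found_key %in% paste(cont$chrom, cont$pos)) == 0L,
    tpm_columns_sum_1e6 =
      all(abs(colSums(report$tpm) - 1e6) <= 1e-6 * 1e6)
  )
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad) > 0L)
    stop(sprintf("end-to-end check failed: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  invisible(list(report = report, precision = precision, recall = recall,
                 dir = dir))
}
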