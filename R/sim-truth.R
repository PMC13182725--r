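#' Plant ground-truth editing sites, germline variants and contaminants
#'
#' Chooses reference-adenosine positions (in transcript orientation: genomic A
#' on plus-strand genes, genomic T on minus-strand genes) for the true A-to-I
#' editing sites, keeping them discoverable: never inside or adjacent to a
#' homopolymer run of five or more identical bases, never in a simple-repeat
#' interval, never on the mitochondrial chromosome, never within six
#' nucleotides of an annotated splice junction, and never so close to a
#' transcript end that read coverage collapses. The true editing level of
#' site *i* in sample *s* is `adar_activity[s] * base_level[i]` (capped at 1)
#' with `base_level ~ beta(alpha, beta)`, mirroring global editing activity
#' that scales with ADAR expression. Germline SNPs (heterozygous and
#' homozygous) and artifact contaminants (homopolymer-embedded,
#' splice-junction proximal, read-end biased) are planted at disjoint
#' positions.
#'
#' @param genome a [build_genome()] result.
#' @param config the same [simulation_config()] used to build the genome.
#' @return an object of class `truth_set`: list with `true_sites`, `levels`
#'   (site x sample matrix), `germline`, `contaminants`, `design`.
#' @export
plant_truth <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 2L))
  design <- sim_design(config)
  n_samples <- nrow(design)

  pools <- placement_pools(genome, config)
  need <- config$n_true_sites + ceiling(config$n_contaminant_sites / 3)
  if (nrow(pools$clean) < need)
    stop(sprintf(paste0("placement error: %d eligible clean positions but %d",
                        " required; enlarge the genome or reduce site counts"),
                 nrow(pools$clean), need), call. = FALSE)

  clean <- pools$clean[sample.int(nrow(pools$clean))]
  true_sites <- clean[seq_len(config$n_true_sites)]
  true_sites[, site_id := sprintf("%s:%d", chrom, pos)]
  base_level <- stats::rbeta(nrow(true_sites), config$editing_level_shape[1],
                             config$editing_level_shape[2])
  differential <- rep(FALSE, nrow(true_sites))
  if (config$n_differential_sites > 0L)
    differential[seq_len(config$n_differential_sites)] <- TRUE

  levels <- outer(base_level, design$adar_activity)
  if (any(differential)) {
    last_group <- design$group == config$group_labels[length(config$group_labels)]
    levels[differential, last_group] <-
      levels[differential, last_group] * config$differential_effect
  }
  levels <- pmin(levels, 1)
  dimnames(levels) <- list(true_sites$site_id, design$sample_id)

  true_sites <- data.table(true_sites[, c("chrom", "pos", "strand", "gene_id")],
                           ref = true_sites$ref, alt = true_sites$alt,
                           base_level = base_level, differential = differential,
                           site_id = true_sites$site_id)

  # contaminants: one third per artifact class (remainder to read_end)
  n_cont <- config$n_contaminant_sites
  n_hp <- n_cont %/% 3L
  n_sj <- n_cont %/% 3L
  n_re <- n_cont - n_hp - n_sj
  used <- true_sites[, c("chrom", "pos")]
  cont <- rbindlist(list(
    draw_from_pool(pools$homopolymer, n_hp, "homopolymer", used),
    draw_from_pool(pools$junction, n_sj, "splice_junction", used),
    draw_from_pool(clean[-seq_len(config$n_true_sites)], n_re, "read_end", used)
  ))
  cont[, prob := stats::runif(.N, 0.15, 0.35)]
  cont[class_ == "read_end", prob := 0.9]
  setnames(cont, "class_", "class")

  # germline SNPs in expressed exons, one genotype shared by all samples
  snp_pool <- pools$exonic[!paste(chrom, pos) %in%
                             c(paste(true_sites$chrom, true_sites$pos),
                               paste(cont$chrom, cont$pos))]
  n_snp <- config$n_het_snps + config$n_hom_snps
  if (nrow(snp_pool) < n_snp)
    stop("placement error: not enough exonic positions for germline variants",
         call. = FALSE)
  snp <- snp_pool[sample.int(nrow(snp_pool), n_snp)]
  snp[, alt := vapply(ref, random_alt, character(1))]
  snp[, genotype := rep(c("het", "hom"),
                        c(config$n_het_snps, config$n_hom_snps))]

  structure(list(
    true_sites = true_sites,
    levels = levels,
    germline = snp[, c("chrom", "pos", "ref", "alt", "genotype")],
    contaminants = cont,
    design = design
  ), class = "truth_set")
}

random_alt <- function(ref) sample(setdiff(c("A", "C", "G", "T"), ref), 1L)

draw_from_pool <- function(pool, n, class, used) {
  pool <- pool[!paste(chrom, pos) %in% paste(used$chrom, used$pos)]
  if (nrow(pool) < n)
    stop(sprintf("placement error: only %d positions available for %s contaminants (%d requested)",
                 nrow(pool), class, n), call. = FALSE)
  out <- pool[sample.int(nrow(pool), n)]
  out[, class_ := class]
  out
}

# candidate-position pools, all in transcript-adenosine orientation
placement_pools <- function(genome, config) {
  th <- discovery_thresholds()
  hp <- homopolymer_intervals(genome$seqs, th$homopolymer_len)
  sj <- splice_junctions(genome)
  rl <- config$read_length

  ex <- as.data.table(genome$exons)[chrom != genome$mito_chrom]
  per_exon <- vector("list", nrow(ex))
  for (i in seq_len(nrow(ex))) {
    p <- ex$start[i]:ex$end[i]
    per_exon[[i]] <- data.table(chrom = ex$chrom[i], pos = p,
                                gene_id = ex$gene_id[i], strand = ex$strand[i])
  }
  exonic <- rbindlist(per_exon)
  chars <- lapply(genome$seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  exonic[, ref := chars[[chrom[1]]][pos], by = chrom]

  # transcript-coordinate distance to transcript ends (genomic order is fine:
  # read starts are uniform along the spliced transcript)
  exonic <- merge(exonic, tx_coordinates(genome), by = c("chrom", "pos", "gene_id"))

  # drop duplicated genomic positions (none by construction: genes don't overlap)
  a_oriented <- exonic[(strand == "+" & ref == "A") | (strand == "-" & ref == "T")]
  a_oriented[, alt := ifelse(strand == "+", "G", "C")]

  in_interval <- function(dt, iv, pad = 0L) {
    if (nrow(iv) == 0L) return(rep(FALSE, nrow(dt)))
    key <- unlist(lapply(seq_len(nrow(iv)), function(i)
      paste(iv$chrom[i], (iv$start[i] - pad):(iv$end[i] + pad))))
    paste(dt$chrom, dt$pos) %in% key
  }
  near_junction <- function(dt, dist) {
    if (nrow(sj) == 0L) return(rep(FALSE, nrow(dt)))
    key <- unlist(lapply(seq_len(nrow(sj)), function(i)
      paste(sj$chrom[i], (sj$pos[i] - dist):(sj$pos[i] + dist))))
    paste(dt$chrom, dt$pos) %in% key
  }

  hp_hit <- in_interval(a_oriented, hp, pad = 1L)
  rep_hit <- in_interval(a_oriented, genome$repeats)
  sj_hit <- near_junction(a_oriented, th$splice_junction_dist)
  end_ok <- a_oriented$tx_off >= rl %/% 2L & a_oriented$tx_off_rev >= rl %/% 2L

  clean <- a_oriented[!hp_hit & !rep_hit & !sj_hit & end_ok]
  # homopolymer-contaminant pool: transcript-A bases inside planted exonic runs
  hp_pool <- a_oriented[hp_hit & !rep_hit & end_ok & !sj_hit]
  # junction-proximal pool (clean of the other artifacts)
  sj_pool <- a_oriented[sj_hit & !hp_hit & !rep_hit & end_ok]

  cols <- c("chrom", "pos", "gene_id", "strand", "ref", "alt")
  list(clean = clean[, ..cols], homopolymer = hp_pool[, ..cols],
       junction = sj_pool[, ..cols],
       exonic = exonic[tx_off >= rl %/% 2L & tx_off_rev >= rl %/% 2L,
                       c("chrom", "pos", "gene_id", "strand", "ref")])
}

# per exonic base: offset along the spliced transcript from both ends
tx_coordinates <- function(genome) {
  ex <- as.data.table(genome$exons)
  out <- ex[, {
    e <- .SD[order(start)]
    w <- e$end - e$start + 1L
    cum <- cumsum(c(0L, w))
    total <- sum(w)
    pos <- unlist(lapply(seq_len(nrow(e)), function(i) e$start[i]:e$end[i]))
    off <- unlist(lapply(seq_len(nrow(e)), function(i)
      cum[i] + seq_len(w[i])))
    list(pos = pos, tx_off = off, tx_off_rev = total - off + 1L)
  }, by = c("gene_id", "chrom")]
  out
}
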