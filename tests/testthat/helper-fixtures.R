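# session-cached fixtures: built once, shared across test files

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the standard study: 2 x 100 kb chromosomes, 6 samples in 2 groups,
# 200 true sites with beta(2, 5) levels, 100 het + 50 hom SNPs,
# 30 contaminants, 50x coverage, 0.1% error
standard_fixture <- function() {
  cached("standard", function() {
    cfg <- simulation_config(seed = 20240117L)
    genome <- build_genome(cfg)
    truth <- plant_truth(genome, cfg)
    sim <- simulate_alignments(genome, truth, cfg)
    pileups <- lapply(sim$alignments, pileup, seqs = genome$seqs)
    list(cfg = cfg, genome = genome, truth = truth, sim = sim,
         pileups = pileups)
  })
}

standard_discovery <- function() {
  cached("standard_discovery", function() {
    fx <- standard_fixture()
    suppressMessages(discover_editing_sites(
      fx$pileups, fx$genome$seqs, fx$genome,
      mito_chrom = fx$genome$mito_chrom,
      dbsnp = fx$truth$germline[, c("chrom", "pos")],
      repeat_mask = fx$genome$repeats, verbose = FALSE))
  })
}

# a compact genome for coverage-sweep experiments
compact_config <- function(coverage, seed = 555L, n_samples_per_group = 3L) {
  simulation_config(seed = seed, coverage_mean = coverage,
                    chrom_sizes = c(chrA = 60000L),
                    genes_per_chrom = 5L, n_true_sites = 100L,
                    n_het_snps = 30L, n_hom_snps = 15L,
                    n_contaminant_sites = 0L,
                    n_samples_per_group = n_samples_per_group)
}

# mean absolute error of pooled level estimates vs truth at a given coverage
compact_mae <- function(coverage) {
  cached(paste0("mae_", coverage), function() {
    cfg <- compact_config(coverage)
    g <- build_genome(cfg)
    tr <- plant_truth(g, cfg)
    sim <- simulate_alignments(g, tr, cfg)
    pus <- lapply(sim$alignments, pileup, seqs = g$seqs)
    q <- quantify_truth_sites(pus, tr)
    mean(abs(q$estimate - q$truth), na.rm = TRUE)
  })
}

# pooled editing-level estimate at the planted truth positions, straight from
# the pileups (quantification isolated from the calling cascade)
quantify_truth_sites <- function(pileups, truth) {
  ts <- truth$true_sites
  est <- tru <- rep(NA_real_, nrow(ts))
  for (i in seq_len(nrow(ts))) {
    tot_edit <- tot_depth <- 0
    tru_num <- tru_den <- 0
    for (s in seq_along(pileups)) {
      pu <- pileups[[s]]
      d <- pu$depth[chrom == ts$chrom[i] & pos == ts$pos[i]]
      if (nrow(d) == 0L) next
      a <- pu$alt_counts[chrom == ts$chrom[i] & pos == ts$pos[i] &
                           base == ts$alt[i]]
      e <- if (nrow(a) > 0L) a$count else 0L
      tot_edit <- tot_edit + e
      tot_depth <- tot_depth + d$depth
      tru_num <- tru_num + d$depth * truth$levels[i, s]
      tru_den <- tru_den + d$depth
    }
    if (tot_depth > 0) {
      est[i] <- tot_edit / tot_depth
      tru[i] <- tru_num / tru_den
    }
  }
  data.frame(estimate = est, truth = tru)
}
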