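test_that("genome builder is deterministic and honours the requested shape", {
  cfg <- simulation_config(seed = 11L)
  g1 <- build_genome(cfg)
  g2 <- build_genome(cfg)
  expect_identical(g1$seqs, g2$seqs)
  expect_identical(g1$genes, g2$genes)

  # two 100 kb chromosomes plus the mitochondrial chromosome
  expect_setequal(names(g1$seqs), c("chr1", "chr2", "chrM"))
  expect_equal(unname(nchar(g1$seqs[c("chr1", "chr2")])), c(100000L, 100000L))

  # multi-exon genes on both strands of every autosome
  ex <- g1$exons[g1$exons$chrom != "chrM"]
  n_ex <- table(ex$gene_id)
  expect_true(all(n_ex[unique(ex$gene_id)] >= 2L))
  for (ch in c("chr1", "chr2"))
    expect_setequal(unique(g1$genes$strand[g1$genes$chrom == ch]), c("+", "-"))

  # a brute-force scan finds a homopolymer run of >= 5 identical bases,
  # and a repeat interval exists
  runs <- gregexpr("A{5,}|C{5,}|G{5,}|T{5,}", g1$seqs[["chr1"]])[[1]]
  expect_true(runs[1] > 0)
  expect_gt(nrow(g1$repeats), 0L)
})

test_that("FASTA and GTF emission is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 7L, chrom_sizes = c(chr1 = 20000L),
                           genes_per_chrom = 2L, n_true_sites = 10L,
                           n_het_snps = 4L, n_hom_snps = 2L,
                           n_contaminant_sites = 3L, coverage_mean = 10)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  m1 <- write_simulation(cfg, d1)
  m2 <- write_simulation(cfg, d2)
  for (f in c("fasta", "gtf", "truth_bed", "germline_vcf", "design")) {
    expect_identical(readLines(m1[[f]]), readLines(m2[[f]]),
                     info = paste("file:", f))
  }
  expect_identical(readLines(m1$sam[[1]]), readLines(m2$sam[[1]]))
  # FASTA round-trips with the requested record count and length
  fa <- read_genome_fasta(m1$fasta)
  expect_equal(unname(nchar(fa["chr1"])), 20000L)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(simulation_config(error_rate = 1.5), "error_rate")
  expect_error(simulation_config(n_true_sites = -1), "n_true_sites")
  expect_error(simulation_config(adar_activity = c(0.5, 0.5)), "adar_activity")
  expect_error(simulation_config(group_labels = c("a", "a")), "group_labels")
  expect_error(build_genome(list()), "config")
})

test_that("planted truth respects every placement rule", {
  fx <- standard_fixture()
  tr <- fx$truth; g <- fx$genome; cfg <- fx$cfg
  expect_equal(nrow(tr$true_sites), cfg$n_true_sites)

  key <- function(d) paste(d$chrom, d$pos)
  # positions unique across the three planted lists
  all_pos <- c(key(tr$true_sites), key(tr$germline), key(tr$contaminants))
  expect_false(anyDuplicated(all_pos) > 0)

  # never in/adjacent to a homopolymer, in a repeat, on chrM, or <= 6 nt
  # from a splice junction
  hp <- editome:::homopolymer_intervals(g$seqs, 5L)
  for (i in seq_len(nrow(tr$true_sites))) {
    ch <- tr$true_sites$chrom[i]; p <- tr$true_sites$pos[i]
    h <- hp[hp$chrom == ch]
    expect_false(any(p >= h$start - 1L & p <= h$end + 1L))
    r <- g$repeats[g$repeats$chrom == ch]
    expect_false(any(p >= r$start & p <= r$end))
  }
  expect_false(any(tr$true_sites$chrom == g$mito_chrom))
  sj <- splice_junctions(g)
  dmin <- vapply(seq_len(nrow(tr$true_sites)), function(i) {
    j <- sj$pos[sj$chrom == tr$true_sites$chrom[i]]
    min(abs(j - tr$true_sites$pos[i]))
  }, numeric(1))
  expect_true(all(dmin > 6))

  # reference base is adenosine in transcript orientation
  refs <- vapply(seq_len(nrow(tr$true_sites)), function(i)
    substr(g$seqs[[tr$true_sites$chrom[i]]], tr$true_sites$pos[i],
           tr$true_sites$pos[i]), character(1))
  expect_true(all(ifelse(tr$true_sites$strand == "+", refs == "A",
                         refs == "T")))
})

test_that("true levels scale with ADAR activity, site ranks preserved", {
  fx <- standard_fixture()
  lv <- fx$truth$levels
  act <- fx$truth$design$adar_activity
  # per-site ranking across samples matches the activity ranking (no caps hit)
  uncapped <- lv[apply(lv, 1, max) < 1, , drop = FALSE]
  for (i in seq_len(min(25L, nrow(uncapped))))
    expect_equal(order(uncapped[i, ]), order(act))
  # per-sample mean true level strictly increases with activity
  expect_true(all(diff(colMeans(lv)[order(act)]) > 0))
  # doubling one sample's activity doubles its levels (capped at 1)
  cfg2 <- fx$cfg
  cfg2$adar_activity[1] <- fx$cfg$adar_activity[1] * 2
  tr2 <- plant_truth(fx$genome, cfg2)
  expect_equal(unname(tr2$levels[, 1]),
               unname(pmin(lv[, 1] * 2, 1)), tolerance = 1e-12)
  expect_equal(tr2$levels[, -1], lv[, -1], tolerance = 1e-12)
})

test_that("placement fails loudly when the genome cannot host the request", {
  cfg <- simulation_config(seed = 5L, chrom_sizes = c(chr1 = 20000L),
                           genes_per_chrom = 2L, n_true_sites = 5000L)
  g <- build_genome(cfg)
  expect_error(plant_truth(g, cfg), "placement error")
})

test_that("read simulation reproduces the generative frequencies", {
  fx <- standard_fixture()
  tr <- fx$truth
  # at every true site, pooled edited count lies in the central 99.9%
  # binomial envelope of the pooled true level
  q <- quantify_truth_sites(fx$pileups, tr)
  ok <- !is.na(q$estimate)
  expect_gt(mean(ok), 0.9)
  n <- vapply(seq_len(nrow(tr$true_sites)), function(i) {
    tot <- 0
    for (pu in fx$pileups) {
      d <- pu$depth[chrom == tr$true_sites$chrom[i] &
                      pos == tr$true_sites$pos[i]]
      if (nrow(d)) tot <- tot + d$depth
    }
    tot
  }, numeric(1))
  viol <- 0L
  for (i in which(ok)) {
    lo <- qbinom(5e-4, n[i], q$truth[i]); hi <- qbinom(1 - 5e-4, n[i], q$truth[i])
    x <- round(q$estimate[i] * n[i])
    if (x < lo || x > hi) viol <- viol + 1L
  }
  # 200 sites x 0.1% two-sided tail: a couple of excursions allowed
  expect_lte(viol, 3L)

  # homozygous SNPs show AAF ~ 1 in every sample
  hom <- tr$germline[tr$germline$genotype == "hom"][1:5]
  for (i in seq_len(nrow(hom))) {
    for (pu in fx$pileups[1:2]) {
      d <- pu$depth[chrom == hom$chrom[i] & pos == hom$pos[i]]
      a <- pu$alt_counts[chrom == hom$chrom[i] & pos == hom$pos[i] &
                           base == hom$alt[i]]
      if (nrow(d) && d$depth >= 10) {
        expect_gte(a$count / d$depth, 0.95)
      }
    }
  }
})

test_that("with no error and no variants the pileup is pure reference", {
  cfg <- simulation_config(seed = 9L, chrom_sizes = c(chr1 = 20000L),
                           genes_per_chrom = 2L, coverage_mean = 15,
                           error_rate = 0, n_true_sites = 0L,
                           n_het_snps = 0L, n_hom_snps = 0L,
                           n_contaminant_sites = 0L,
                           n_samples_per_group = 1L)
  g <- build_genome(cfg)
  tr <- plant_truth(g, cfg)
  sim <- simulate_alignments(g, tr, cfg)
  pu <- pileup(sim$alignments[[1]], g$seqs)
  expect_equal(nrow(pu$alt_reads), 0L)
})

test_that("empirical editing fractions converge to truth as coverage grows", {
  expect_lt(compact_mae(200), compact_mae(20))
})
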