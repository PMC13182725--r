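# build a one-sample pileup object directly from count specifications
mk_pileup <- function(chrom, pos, depth, alt_count, base = "G",
                      dist5 = NULL, alen = 100L) {
  n <- alt_count
  d5 <- if (is.null(dist5)) rep(50L, n) else dist5
  structure(list(
    depth = data.table::data.table(chrom = chrom, pos = pos, depth = depth),
    alt_reads = if (n > 0)
      data.table::data.table(chrom = chrom, pos = pos, base = base,
                             qual = 37L, dist5 = d5, dist3 = alen - d5 + 1L,
                             alen = alen)
    else data.table::data.table(chrom = character(), pos = integer(),
                                base = character(), qual = integer(),
                                dist5 = integer(), dist3 = integer(),
                                alen = integer()),
    alt_counts = if (n > 0)
      data.table::data.table(chrom = chrom, pos = pos, base = base, count = n)
    else data.table::data.table(chrom = character(), pos = integer(),
                                base = character(), count = integer()),
    indels = data.table::data.table(chrom = character(), pos = integer(),
                                    op = character(), count = integer()),
    min_base_quality = 25L), class = "pileup")
}

seqs_A <- c(chr_t = paste(rep(c("A", "C", "G", "T"), 50), collapse = ""))

test_that("candidate calling applies the depth / alt depth / AAF thresholds", {
  th <- discovery_thresholds()
  called <- function(depth, alt) {
    pu <- mk_pileup("chr_t", 21L, depth, alt)
    nrow(call_candidate_snvs(list(s1 = pu), seqs_A, th)$calls) == 1L
  }
  expect_true(called(10L, 2L))        # boundary of all three thresholds
  expect_false(called(9L, 3L))        # depth below 10
  expect_false(called(300L, 2L))      # AAF ~0.0067 below 1%
  expect_true(called(300L, 3L))       # AAF exactly 1%
  expect_false(called(50L, 1L))       # alt depth below 2
})

test_that("multi-allelic columns keep only the majority alternate", {
  pu <- mk_pileup("chr_t", 21L, 50L, 6L, base = "G")
  pu$alt_counts <- rbind(pu$alt_counts,
                         data.table::data.table(chrom = "chr_t", pos = 21L,
                                                base = "C", count = 3L))
  cs <- call_candidate_snvs(list(s1 = pu), seqs_A)
  expect_equal(nrow(cs$calls), 1L)
  expect_equal(cs$calls$alt, "G")
})

test_that("substitution orientation follows the host gene strand", {
  ann <- list(genes = data.frame(
    gene_id = c("gp", "gm", "gb1", "gb2"),
    chrom = c("c", "c", "c", "c"), strand = c("+", "-", "+", "-"),
    tx_start = c(1L, 101L, 201L, 201L), tx_end = c(100L, 200L, 300L, 300L),
    cds_start = NA_integer_, cds_end = NA_integer_))
  calls <- data.table::data.table(
    chrom = "c", pos = c(10L, 110L, 20L, 120L, 250L, 400L),
    ref = c("A", "T", "C", "A", "A", "A"),
    alt = c("G", "C", "T", "G", "G", "G"))
  out <- orient_substitution(calls, ann)
  expect_equal(out$edit_class,
               c("A_to_I",     # A>G in + gene
                 "A_to_I",     # T>C in - gene
                 "other",      # C>T in + gene
                 "other",      # A>G in - gene
                 "ambiguous",  # A>G under genes on both strands
                 "other"))     # intergenic
})

test_that("filter rules fire in order with the documented geometry", {
  th <- discovery_thresholds()
  ann1 <- list(genes = data.frame(gene_id = "g", chrom = "c", strand = "+",
                                  tx_start = 1L, tx_end = 400L,
                                  cds_start = NA_integer_, cds_end = NA_integer_),
               exons = data.frame(gene_id = "g", chrom = "c", strand = "+",
                                  exon_rank = 1:2, start = c(1L, 201L),
                                  end = c(100L, 400L)))
  base_seq <- paste(rep(c("A", "C", "G", "T"), 100), collapse = "")
  run_seq <- paste0(substr(base_seq, 1, 49), "AAAAA",
                    substr(base_seq, 55, 400))
  verdict <- function(pos, seqs = c(c = base_seq), chrom = "c",
                      pileups = list(s1 = mk_pileup(chrom, pos, 50L, 10L)),
                      ...) {
    calls <- data.table::data.table(chrom = chrom, pos = pos,
                                    ref = "A", alt = "G")
    suppressMessages(apply_site_filters(calls, seqs, ann1, pileups,
                                        mito_chrom = "chrM", thresholds = th,
                                        verbose = FALSE, ...))
  }
  # inside the reference AAAAA run
  v <- verdict(52L, seqs = c(c = run_seq))
  expect_equal(v$failed_rule, "homopolymer")
  # immediately adjacent to the run
  expect_equal(verdict(55L, seqs = c(c = run_seq))$failed_rule, "homopolymer")

  # exactly 6 nt from the junction fails; 7 nt passes
  # junction boundary bases are 100 and 201
  expect_equal(verdict(94L)$failed_rule, "splice_junction")
  expect_equal(verdict(93L)$status, "pass")
  expect_equal(verdict(207L)$failed_rule, "splice_junction")
  expect_equal(verdict(208L)$status, "pass")

  # mitochondrial chromosome
  vm <- verdict(30L, seqs = c(c = base_seq, chrM = base_seq), chrom = "chrM",
                pileups = list(s1 = mk_pileup("chrM", 30L, 50L, 10L)))
  expect_equal(vm$failed_rule, "mitochondrial")

  # simple repeat interval
  vr <- verdict(30L, repeat_mask = data.frame(chrom = "c", start = 25L,
                                              end = 35L))
  expect_equal(vr$failed_rule, "simple_repeat")

  # dbSNP-listed fails; dbSNP-listed but whitelisted passes with the flag
  vd <- verdict(30L, dbsnp = data.frame(chrom = "c", pos = 30L))
  expect_equal(vd$failed_rule, "dbsnp")
  vw <- verdict(30L, dbsnp = data.frame(chrom = "c", pos = 30L),
                whitelist = data.frame(chrom = "c", pos = 30L))
  expect_equal(vw$status, "pass")
  expect_true(vw$whitelisted)

  # indel within 1 nt at >= 2 reads
  pu_ind <- mk_pileup("c", 30L, 50L, 10L)
  pu_ind$indels <- data.table::data.table(chrom = "c", pos = 31L, op = "D",
                                          count = 2L)
  vi <- verdict(30L, pileups = list(s1 = pu_ind))
  expect_equal(vi$failed_rule, "indel_proximity")
})

test_that("read-end rule discards end-biased support and re-evaluates", {
  # all 6 alternate reads within the terminal 4% (<= 4 of 100 aligned bases)
  pu_end <- mk_pileup("c", 30L, 50L, 6L, dist5 = c(1L, 2L, 3L, 4L, 98L, 100L))
  ann <- list(genes = data.frame(gene_id = "g", chrom = "c", strand = "+",
                                 tx_start = 1L, tx_end = 400L,
                                 cds_start = NA_integer_, cds_end = NA_integer_),
              exons = data.frame(gene_id = "g", chrom = "c", strand = "+",
                                 exon_rank = 1L, start = 1L, end = 400L))
  calls <- data.table::data.table(chrom = "c", pos = 30L, ref = "A", alt = "G")
  seqs <- c(c = paste(rep(c("A", "C", "G", "T"), 100), collapse = ""))
  v <- apply_site_filters(calls, seqs, ann, list(s1 = pu_end),
                          verbose = FALSE)
  expect_equal(v$failed_rule, "read_end")
  # one interior read is not enough (min_alt_depth = 2); two rescue the site
  pu_mix <- mk_pileup("c", 30L, 50L, 6L,
                      dist5 = c(1L, 2L, 3L, 4L, 50L, 60L))
  v2 <- apply_site_filters(calls, seqs, ann, list(s1 = pu_mix),
                           verbose = FALSE)
  expect_equal(v2$status, "pass")
  pu_one <- mk_pileup("c", 30L, 50L, 5L, dist5 = c(1L, 2L, 3L, 4L, 50L))
  v3 <- apply_site_filters(calls, seqs, ann, list(s1 = pu_one),
                           verbose = FALSE)
  expect_equal(v3$failed_rule, "read_end")
})

test_that("germline AAF patterns are recognised across samples", {
  mk_ps <- function(aaf, depth = 50L) {
    data.table::data.table(chrom = "c", pos = 1L,
                           sample_id = paste0("s", seq_along(aaf)),
                           depth = depth, alt_depth = round(aaf * depth),
                           aaf = aaf)
  }
  expect_equal(germline_pattern_filter(mk_ps(c(0.50, 0.48, 0.56)))$status, "fail")
  ps_hom <- mk_ps(c(1, 1, 1)); ps_hom$alt_depth <- ps_hom$depth
  expect_equal(germline_pattern_filter(ps_hom)$status, "fail")
  expect_equal(germline_pattern_filter(mk_ps(c(0.15, 0.22, 0.18)))$status, "pass")
  # "over 90%" is strict: 5 of 6 in the het band is not enough
  expect_equal(germline_pattern_filter(
    mk_ps(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.2)))$status, "pass")
  # uncovered samples carry no evidence
  ps <- mk_ps(c(0.5, 0.5, 0.1)); ps$depth[3] <- 5L
  expect_equal(germline_pattern_filter(ps)$status, "fail")
  ps0 <- mk_ps(0.5); ps0$depth <- 3L
  expect_equal(germline_pattern_filter(ps0)$status, "indeterminate")
})

test_that("high-confidence retention needs >= 1% in at least two samples", {
  mk_ps <- function(aaf, depth = 100L) {
    data.table::data.table(chrom = "c", pos = 1L,
                           sample_id = paste0("s", seq_along(aaf)),
                           depth = depth, alt_depth = round(aaf * depth),
                           aaf = aaf)
  }
  expect_equal(nrow(select_high_confidence(mk_ps(c(0.012, 0.015, 0)))), 1L)
  expect_equal(nrow(select_high_confidence(mk_ps(c(0.02, 0, 0)))), 0L)
  expect_equal(nrow(select_high_confidence(mk_ps(c(0, 0, 0)))), 0L)
  # low-coverage samples do not count towards retention
  ps <- mk_ps(c(0.02, 0.02, 0)); ps$depth[2] <- 5L
  expect_equal(nrow(select_high_confidence(ps)), 0L)
})

test_that("the cascade is deterministic end to end", {
  fx <- standard_fixture()
  d1 <- standard_discovery()
  d2 <- suppressMessages(discover_editing_sites(
    fx$pileups, fx$genome$seqs, fx$genome,
    mito_chrom = fx$genome$mito_chrom,
    dbsnp = fx$truth$germline[, c("chrom", "pos")],
    repeat_mask = fx$genome$repeats, verbose = FALSE))
  expect_identical(d1$sites, d2$sites)
  expect_identical(d1$attrition, d2$attrition)
})

test_that("every retained site is A-to-I oriented", {
  d <- standard_discovery()
  expect_true(all(d$sites$edit_class == "A_to_I"))
  expect_true(all((d$sites$ref == "A" & d$sites$alt == "G") |
                    (d$sites$ref == "T" & d$sites$alt == "C")))
})
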