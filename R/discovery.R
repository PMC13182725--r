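#' Call candidate single-nucleotide variants from pileups
#'
#' A candidate is emitted at a position if, in at least one sample (or in the
#' pooled counts when `mode = "pooled"`), the qualifying depth is at least
#' `min_depth`, some single alternate base is supported by at least
#' `min_alt_depth` reads, and the alternative allele frequency (AAF) is at
#' least `min_aaf`. Multi-allelic columns keep only the majority alternate
#' (summed over samples; ties broken alphabetically for determinism).
#'
#' @param pileups a named list of [pileup()] objects (one per sample), or a
#'   single `pileup`.
#' @param seqs named character vector of reference sequences.
#' @param thresholds a [discovery_thresholds()].
#' @param mode evaluate calling thresholds per sample (default) or on counts
#'   pooled across samples.
#' @return list with `calls` (chrom, pos, ref, alt, pooled depth/alt_depth/
#'   aaf) and `per_sample` (long table of depth, alt_depth, aaf per sample).
#' @export
call_candidate_snvs <- function(pileups, seqs,
                                thresholds = discovery_thresholds(),
                                mode = c("per_sample", "pooled")) {
  mode <- match.arg(mode)
  if (inherits(pileups, "pileup")) pileups <- list(sample_1 = pileups)
  th <- thresholds

  per <- rbindlist(lapply(names(pileups), function(s) {
    pu <- pileups[[s]]
    x <- merge(pu$alt_counts, pu$depth, by = c("chrom", "pos"))
    x[, sample_id := s]
    x
  }))
  if (nrow(per) == 0L) return(empty_callset(names(pileups)))

  if (mode == "per_sample") {
    qual <- per[depth >= th$min_depth & count >= th$min_alt_depth &
                  count / depth >= th$min_aaf]
  } else {
    pooled <- per[, list(count = sum(count), depth = sum(depth)),
                  by = c("chrom", "pos", "base")]
    qual <- pooled[depth >= th$min_depth & count >= th$min_alt_depth &
                     count / depth >= th$min_aaf]
  }
  if (nrow(qual) == 0L) return(empty_callset(names(pileups)))

  # majority alternate per position, pooled across samples
  tot <- per[paste(chrom, pos) %in% paste(qual$chrom, qual$pos)]
  by_base <- tot[, list(count = sum(count)), by = c("chrom", "pos", "base")]
  setorder(by_base, chrom, pos, -count, base)
  alt_pick <- by_base[!duplicated(paste(chrom, pos))]
  alt_pick[, ref := substring(seqs[chrom], pos, pos)]

  # per-sample depth / alt depth at every picked site
  site_key <- alt_pick[, c("chrom", "pos", "ref", "alt" = "base")]
  setnames(site_key, "base", "alt")
  grid <- site_key[, {
    data.table(sample_id = names(pileups))
  }, by = c("chrom", "pos", "ref", "alt")]
  depths <- rbindlist(lapply(names(pileups), function(s) {
    d <- pileups[[s]]$depth[, c("chrom", "pos", "depth")]
    d[, sample_id := s]
    d
  }))
  alts <- rbindlist(lapply(names(pileups), function(s) {
    a <- pileups[[s]]$alt_counts
    a[, sample_id := s]
    a
  }))
  per_sample <- merge(grid, depths, by = c("chrom", "pos", "sample_id"),
                      all.x = TRUE)
  per_sample <- merge(per_sample,
                      alts[, list(chrom, pos, sample_id, alt = base,
                                  alt_depth = count)],
                      by = c("chrom", "pos", "sample_id", "alt"), all.x = TRUE)
  per_sample[is.na(depth), depth := 0L]
  per_sample[is.na(alt_depth), alt_depth := 0L]
  per_sample[, aaf := ifelse(depth > 0L, alt_depth / depth, NA_real_)]

  calls <- per_sample[, list(depth = sum(depth), alt_depth = sum(alt_depth)),
                      by = c("chrom", "pos", "ref", "alt")]
  calls[, aaf := alt_depth / depth]
  setorder(calls, chrom, pos)
  setorder(per_sample, chrom, pos, sample_id)
  list(calls = calls, per_sample = per_sample)
}

empty_callset <- function(sample_ids) {
  list(calls = data.table(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          depth = integer(), alt_depth = integer(),
                          aaf = numeric()),
       per_sample = data.table(chrom = character(), pos = integer(),
                               ref = character(), alt = character(),
                               sample_id = character(), depth = integer(),
                               alt_depth = integer(), aaf = numeric()))
}

#' Orient substitutions relative to gene strand
#'
#' A-to-I editing appears as an A>G mismatch on the transcribed strand:
#' genomic A>G inside a plus-strand gene or genomic T>C inside a minus-strand
#' gene is classified `A_to_I`. Positions inside genes on both strands where
#' the two orientations disagree are `ambiguous`; everything else is `other`.
#'
#' @param calls the `calls` table from [call_candidate_snvs()].
#' @param annotation a `genome_model` or [read_annotation_gtf()] result.
#' @return `calls` with an added `edit_class` column.
#' @export
orient_substitution <- function(calls, annotation) {
  genes <- as.data.table(annotation$genes)
  out <- data.table::copy(as.data.table(calls))
  if (nrow(out) == 0L) { out[, edit_class := character()]; return(out) }
  on_strand <- function(str) {
    g <- genes[strand == str]
    if (nrow(g) == 0L) return(rep(FALSE, nrow(out)))
    hit <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(g)))
      hit <- hit | (out$chrom == g$chrom[i] & out$pos >= g$tx_start[i] &
                      out$pos <= g$tx_end[i])
    hit
  }
  plus <- on_strand("+")
  minus <- on_strand("-")
  ag <- out$ref == "A" & out$alt == "G"
  tc <- out$ref == "T" & out$alt == "C"
  cls <- rep("other", nrow(out))
  cls[ag & plus & !minus] <- "A_to_I"
  cls[tc & minus & !plus] <- "A_to_I"
  cls[(ag | tc) & plus & minus] <- "ambiguous"
  out[, edit_class := cls]
  out
}

#' Apply the positional and read-level exclusion rules
#'
#' Tests each candidate against the exclusion rules in a fixed order --
#' homopolymer (inside or immediately adjacent to a reference run of
#' `homopolymer_len`+ identical bases), simple repeat, mitochondrial
#' chromosome, splice-junction proximity, indel proximity, read-end bias,
#' and dbSNP membership -- recording the first failing rule. Sites on a
#' whitelist of known editing positions pass regardless, with the
#' `whitelisted` flag set. The read-end rule discards alternate-supporting
#' reads whose mismatch lies within `floor(read_end_frac * aligned length)`
#' bases of either read end and re-evaluates the call: it fails if no sample
#' retains `min_alt_depth` surviving alternate reads.
#'
#' @param calls oriented calls from [orient_substitution()].
#' @param seqs reference sequences.
#' @param annotation gene annotation (for splice junctions).
#' @param pileups the per-sample pileups (for read-end offsets and indels).
#' @param mito_chrom name of the mitochondrial chromosome (or `NULL`).
#' @param thresholds a [discovery_thresholds()].
#' @param dbsnp optional data.table of known SNP positions (`chrom`, `pos`).
#' @param whitelist optional data.table of known editing positions.
#' @param repeat_mask optional data.table of repeat intervals
#'   (`chrom`, `start`, `end`, 1-based inclusive).
#' @param verbose log skipped optional resources.
#' @return data.table verdicts: `chrom`, `pos`, `status` (pass/fail),
#'   `failed_rule`, `whitelisted`.
#' @export
apply_site_filters <- function(calls, seqs, annotation, pileups,
                               mito_chrom = NULL,
                               thresholds = discovery_thresholds(),
                               dbsnp = NULL, whitelist = NULL,
                               repeat_mask = NULL, verbose = TRUE) {
  th <- thresholds
  v <- data.table(chrom = calls$chrom, pos = calls$pos, alt = calls$alt,
                  failed_rule = NA_character_, whitelisted = FALSE)
  if (nrow(v) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      status = character(), failed_rule = character(),
                      whitelisted = logical()))

  if (!is.null(whitelist) && nrow(whitelist) > 0L) {
    wl_key <- if ("pos" %in% names(whitelist)) {
      paste(whitelist$chrom, whitelist$pos)
    } else {
      unlist(lapply(seq_len(nrow(whitelist)), function(i)
        paste(whitelist$chrom[i], whitelist$start[i]:whitelist$end[i])))
    }
    v[, whitelisted := paste(chrom, pos) %in% wl_key]
  } else if (is.null(whitelist) && verbose) {
    message("editing-site whitelist not provided; whitelist exemption skipped")
  }

  fail <- function(rule, hit) {
    v[is.na(failed_rule) & !whitelisted & hit, failed_rule := rule]
  }

  hp <- homopolymer_intervals(seqs, th$homopolymer_len)
  fail("homopolymer", in_intervals(v, hp, pad = 1L))

  if (!is.null(repeat_mask) && nrow(repeat_mask) > 0L) {
    fail("simple_repeat", in_intervals(v, repeat_mask))
  } else if (is.null(repeat_mask) && verbose) {
    message("repeat mask not provided; simple-repeat rule skipped")
  }

  if (!is.null(mito_chrom)) fail("mitochondrial", v$chrom == mito_chrom)

  sj <- splice_junctions(annotation)
  if (nrow(sj) > 0L) {
    near_sj <- mapply(function(ch, p) {
      j <- sj$pos[sj$chrom == ch]
      length(j) > 0L && min(abs(j - p)) <= th$splice_junction_dist
    }, v$chrom, v$pos)
    fail("splice_junction", near_sj)
  }

  indels <- rbindlist(lapply(pileups, function(pu) pu$indels))
  if (nrow(indels) > 0L) {
    indels <- indels[, list(count = sum(count)), by = c("chrom", "pos")]
    indels <- indels[count >= 2L]
    if (nrow(indels) > 0L) {
      near_indel <- mapply(function(ch, p) {
        ip <- indels$pos[indels$chrom == ch]
        length(ip) > 0L && min(abs(ip - p)) <= th$indel_dist
      }, v$chrom, v$pos)
      fail("indel_proximity", near_indel)
    }
  }

  fail("read_end", !read_end_survives(v, pileups, th))

  if (!is.null(dbsnp) && nrow(dbsnp) > 0L) {
    fail("dbsnp", paste(v$chrom, v$pos) %in% paste(dbsnp$chrom, dbsnp$pos))
  } else if (is.null(dbsnp) && verbose) {
    message("dbSNP list not provided; dbSNP rule skipped")
  }

  v[, status := ifelse(is.na(failed_rule), "pass", "fail")]
  v[whitelisted == TRUE, status := "pass"]
  v[, c("chrom", "pos", "status", "failed_rule", "whitelisted")]
}

in_intervals <- function(dt, iv, pad = 0L) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, nrow(dt)))
  key <- unlist(lapply(seq_len(nrow(iv)), function(i)
    paste(iv$chrom[i], (iv$start[i] - pad):(iv$end[i] + pad))))
  paste(dt$chrom, dt$pos) %in% key
}

# TRUE where at least one sample keeps >= min_alt_depth alternate reads whose
# mismatch lies outside the terminal read_end_frac zone of its read
read_end_survives <- function(v, pileups, th) {
  surv <- matrix(0L, nrow(v), length(pileups))
  key <- paste(v$chrom, v$pos, v$alt)
  for (si in seq_along(pileups)) {
    ar <- pileups[[si]]$alt_reads
    ar <- ar[paste(chrom, pos, base) %in% key]
    if (nrow(ar) == 0L) next
    ar[, k := floor(th$read_end_frac * alen)]
    ok <- ar[dist5 > k & dist3 > k, list(n = .N), by = c("chrom", "pos", "base")]
    idx <- match(paste(ok$chrom, ok$pos, ok$base), key)
    surv[idx, si] <- ok$n
  }
  apply(surv, 1L, max) >= th$min_alt_depth
}

#' Cross-sample germline-pattern filter
#'
#' Among samples covered at `min_depth`, a site whose AAF equals 100% (every
#' qualifying read alternate) or falls in the heterozygous band in more than
#' `germline_sample_frac` of the covered samples is flagged as a germline
#' genotype rather than editing. Sites covered in no sample are
#' indeterminate and dropped.
#'
#' @param per_sample the per-sample table from [call_candidate_snvs()].
#' @param thresholds a [discovery_thresholds()].
#' @return data.table: `chrom`, `pos`, `status` (pass/fail/indeterminate),
#'   `failed_rule`.
#' @export
germline_pattern_filter <- function(per_sample,
                                    thresholds = discovery_thresholds()) {
  th <- thresholds
  out <- per_sample[, {
    cov <- depth >= th$min_depth
    n_cov <- sum(cov)
    if (n_cov == 0L) {
      list(status = "indeterminate", failed_rule = NA_character_)
    } else {
      f_hom <- sum(cov & alt_depth == depth) / n_cov
      f_het <- sum(cov & aaf >= th$het_band[1] & aaf <= th$het_band[2]) / n_cov
      bad <- f_hom > th$germline_sample_frac || f_het > th$germline_sample_frac
      list(status = if (bad) "fail" else "pass",
           failed_rule = if (bad) "germline_pattern" else NA_character_)
    }
  }, by = c("chrom", "pos")]
  out
}

#' Retain high-confidence editing sites
#'
#' A filtered A-to-I call is retained if its editing level (alternate-read
#' fraction) is at least `min_level` in at least `min_samples` covered
#' samples. Output is sorted by (chrom, pos).
#'
#' @param per_sample per-sample call table (filtered candidates).
#' @param thresholds a [discovery_thresholds()].
#' @return data.table of retained site keys (`chrom`, `pos`).
#' @export
select_high_confidence <- function(per_sample,
                                   thresholds = discovery_thresholds()) {
  th <- thresholds
  keep <- per_sample[, list(
    n_qual = sum(depth >= th$min_depth & aaf >= th$min_level, na.rm = TRUE)),
    by = c("chrom", "pos")]
  out <- keep[n_qual >= th$min_samples, c("chrom", "pos")]
  setorder(out, chrom, pos)
  out
}

#' Discover high-confidence A-to-I editing sites from alignments
#'
#' End-to-end site discovery: pileup per sample, candidate SNV calling,
#' strand orientation, the positional/read-level filter cascade, the
#' cross-sample germline-pattern filter, and final retention. Only
#' `A_to_I`-class substitutions survive; ambiguous-strand sites are dropped
#' and counted.
#'
#' @param alignments named list of per-sample alignment tables (or
#'   pre-computed [pileup()] objects).
#' @param seqs named character vector of reference sequences.
#' @param annotation gene annotation (a `genome_model` or
#'   [read_annotation_gtf()] result).
#' @param mito_chrom mitochondrial chromosome name, or `NULL`.
#' @param thresholds a [discovery_thresholds()].
#' @param dbsnp,whitelist,repeat_mask optional resources, see
#'   [apply_site_filters()].
#' @param verbose log progress and skipped resources.
#' @return list with `sites` (retained editing sites with per-sample
#'   counts), `matrix` (an [editing_matrix()]), `calls`, `verdicts`, and an
#'   `attrition` table of counts removed per stage/rule.
#' @export
discover_editing_sites <- function(alignments, seqs, annotation,
                                   mito_chrom = NULL,
                                   thresholds = discovery_thresholds(),
                                   dbsnp = NULL, whitelist = NULL,
                                   repeat_mask = NULL, verbose = TRUE) {
  th <- thresholds
  pileups <- lapply(alignments, function(a) {
    if (inherits(a, "pileup")) a else pileup(a, seqs, th$min_base_quality)
  })

  cs <- call_candidate_snvs(pileups, seqs, th)
  oriented <- orient_substitution(cs$calls, annotation)
  n_cand <- nrow(oriented)

  a2i <- oriented[edit_class == "A_to_I"]
  n_ambiguous <- sum(oriented$edit_class == "ambiguous")
  if (verbose && n_ambiguous > 0L)
    message(sprintf("dropped %d ambiguous-strand candidate(s)", n_ambiguous))

  verdicts <- apply_site_filters(a2i, seqs, annotation, pileups, mito_chrom,
                                 th, dbsnp, whitelist, repeat_mask, verbose)
  ps_a2i <- cs$per_sample[paste(chrom, pos) %in% paste(a2i$chrom, a2i$pos)]

  passed <- verdicts[status == "pass"]
  ps_pass <- ps_a2i[paste(chrom, pos) %in% paste(passed$chrom, passed$pos)]
  germ <- germline_pattern_filter(ps_pass, th)
  # whitelisted sites are exempt from the germline rule as well
  wl_pass <- passed[whitelisted == TRUE]
  germ[paste(chrom, pos) %in% paste(wl_pass$chrom, wl_pass$pos),
       `:=`(status = "pass", failed_rule = NA_character_)]

  germ_pass <- germ[status == "pass"]
  ps_clean <- ps_pass[paste(chrom, pos) %in% paste(germ_pass$chrom, germ_pass$pos)]
  hc <- select_high_confidence(ps_clean, th)
  sites_ps <- ps_clean[paste(chrom, pos) %in% paste(hc$chrom, hc$pos)]

  site_meta <- a2i[paste(chrom, pos) %in% paste(hc$chrom, hc$pos),
                   c("chrom", "pos", "ref", "alt", "edit_class")]
  site_meta[, strand := ifelse(ref == "A", "+", "-")]
  setorder(site_meta, chrom, pos)

  mat <- editing_matrix_from_calls(sites_ps, names(pileups), th)

  rule_counts <- table(factor(verdicts$failed_rule[verdicts$status == "fail"],
                              levels = FILTER_RULE_ORDER))
  attrition <- data.table(
    stage = c("candidates", "non_A_to_I", "ambiguous_strand",
              names(rule_counts), "germline_pattern_crosssample",
              "no_covered_samples", "below_min_level", "retained"),
    n = c(n_cand,
          sum(oriented$edit_class == "other"), n_ambiguous,
          as.integer(rule_counts),
          sum(germ$status == "fail"),
          sum(germ$status == "indeterminate"),
          nrow(germ_pass) - nrow(hc),
          nrow(hc))
  )
  # the germline rule appears both in the per-rule table (read-level rules)
  # and as its own cross-sample stage; keep the cross-sample count only
  attrition <- attrition[stage != "germline_pattern"]

  list(sites = site_meta, matrix = mat, calls = oriented,
       per_sample = sites_ps, verdicts = verdicts, germline = germ,
       attrition = attrition)
}

# assemble an editing_matrix from the long per-sample call table
editing_matrix_from_calls <- function(per_sample, sample_ids, thresholds) {
  sites <- unique(per_sample[, c("chrom", "pos", "ref", "alt")])
  setorder(sites, chrom, pos)
  site_id <- if (nrow(sites) > 0L) paste0(sites$chrom, ":", sites$pos)
             else character(0)
  edited <- total <- matrix(0L, nrow(sites), length(sample_ids),
                            dimnames = list(site_id, sample_ids))
  if (nrow(per_sample) > 0L) {
    i <- match(paste0(per_sample$chrom, ":", per_sample$pos), site_id)
    j <- match(per_sample$sample_id, sample_ids)
    edited[cbind(i, j)] <- per_sample$alt_depth
    total[cbind(i, j)] <- per_sample$depth
  }
  editing_matrix(edited, total, sites, sample_ids,
                 min_depth = thresholds$min_depth)
}
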