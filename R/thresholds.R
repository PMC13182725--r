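#' Discovery thresholds for editing-site calling and filtering
#'
#' Bundles every tunable cutoff used during candidate SNV calling and the
#' high-confidence filter cascade. The defaults are the standard editome
#' calling parameters: minimum base quality 25, total depth >= 10, alternative
#' allele depth >= 2, AAF >= 1%; artifact context rules (homopolymer runs
#' >= 5 nt, <= 6 nt from splice junctions, <= 1 nt from indels, mismatches
#' within 4% of read ends); a germline-pattern rule (AAF = 100% or
#' 40%-60% in more than 90% of covered samples); and final retention of sites
#' edited at >= 1% in at least two samples.
#'
#' @param min_base_quality minimum Phred base quality for a read base to count.
#' @param min_depth minimum qualifying depth for a sample to be considered
#'   covered at a site.
#' @param min_alt_depth minimum alternative-allele read count to call a
#'   candidate variant.
#' @param min_aaf minimum alternative allele frequency (fraction) to call.
#' @param homopolymer_len run length (identical reference bases) at or above
#'   which a site inside or immediately adjacent to the run is excluded.
#' @param splice_junction_dist maximum distance (nt) from an annotated splice
#'   junction at which a site is excluded.
#' @param indel_dist maximum distance (nt) from an observed indel at which a
#'   site is excluded.
#' @param read_end_frac fraction of the aligned read length defining the
#'   read-end zone; alternate-supporting reads with the mismatch inside the
#'   zone are discarded before re-evaluation.
#' @param germline_sample_frac fraction of covered samples above which a
#'   homozygous/heterozygous AAF pattern marks a site as germline.
#' @param het_band numeric length-2: inclusive AAF band treated as a
#'   heterozygous genotype signature.
#' @param min_level minimum per-sample editing level for final retention.
#' @param min_samples minimum number of samples at `min_level` for retention.
#'
#' @return an object of class `discovery_thresholds` (a validated list).
#' @export
#' @examples
#' th <- discovery_thresholds()
#' th$min_depth
discovery_thresholds <- function(min_base_quality = 25L,
                                 min_depth = 10L,
                                 min_alt_depth = 2L,
                                 min_aaf = 0.01,
                                 homopolymer_len = 5L,
                                 splice_junction_dist = 6L,
                                 indel_dist = 1L,
                                 read_end_frac = 0.04,
                                 germline_sample_frac = 0.90,
                                 het_band = c(0.40, 0.60),
                                 min_level = 0.01,
                                 min_samples = 2L) {
  th <- list(
    min_base_quality = as.integer(min_base_quality),
    min_depth = as.integer(min_depth),
    min_alt_depth = as.integer(min_alt_depth),
    min_aaf = as.numeric(min_aaf),
    homopolymer_len = as.integer(homopolymer_len),
    splice_junction_dist = as.integer(splice_junction_dist),
    indel_dist = as.integer(indel_dist),
    read_end_frac = as.numeric(read_end_frac),
    germline_sample_frac = as.numeric(germline_sample_frac),
    het_band = as.numeric(het_band),
    min_level = as.numeric(min_level),
    min_samples = as.integer(min_samples)
  )
  for (f in c("min_base_quality", "min_depth", "min_alt_depth", "min_aaf",
              "homopolymer_len", "splice_junction_dist", "read_end_frac",
              "germline_sample_frac", "min_level", "min_samples")) {
    if (length(th[[f]]) != 1L || is.na(th[[f]]) || th[[f]] <= 0)
      stop_config(f, "must be a single positive value")
  }
  if (th$indel_dist < 0) stop_config("indel_dist", "must be non-negative")
  if (length(th$het_band) != 2L || any(th$het_band < 0) ||
      any(th$het_band > 1) || th$het_band[1] > th$het_band[2])
    stop_config("het_band", "must be an increasing pair within [0, 1]")
  structure(th, class = "discovery_thresholds")
}

#' @export
print.discovery_thresholds <- function(x, ...) {
  cat("discovery_thresholds:\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, paste(x[[f]], collapse = ", ")))
  invisible(x)
}

# the fixed order in which exclusion rules are tested; the first failing rule
# is the one recorded in the verdict
FILTER_RULE_ORDER <- c("homopolymer", "simple_repeat", "mitochondrial",
                       "splice_junction", "indel_proximity", "read_end",
                       "dbsnp", "germline_pattern")
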