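REGION_LEVELS <- c("CDS", "three_prime_UTR", "five_prime_UTR",
                   "noncoding_exon", "intron", "intergenic")

#' Annotate editing sites by genomic region and coding consequence
#'
#' Assigns each site one region with precedence CDS > 3'UTR > 5'UTR >
#' non-coding exon > intron > intergenic across all overlapping transcripts
#' (the ranking used by standard consequence annotators). For CDS sites the
#' coding consequence is computed by codon substitution in transcript
#' orientation -- the edited adenosine reads as guanosine -- under the
#' standard genetic code.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based) and optionally
#'   `ref`/`alt` (defaults: transcript-strand A>G).
#' @param annotation a `genome_model` or [read_annotation_gtf()] result.
#' @param seqs named character vector of reference sequences.
#' @return data.table: site key plus `gene_id`, `region`, and for CDS sites
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `consequence`
#'   (missense / synonymous / stop_altering).
#' @export
annotate_sites <- function(sites, annotation, seqs) {
  sites <- as.data.table(sites)
  genes <- as.data.table(annotation$genes)
  exons <- as.data.table(annotation$exons)
  out <- sites[, c("chrom", "pos")]
  out[, `:=`(gene_id = NA_character_, region = "intergenic",
             ref_codon = NA_character_, alt_codon = NA_character_,
             ref_aa = NA_character_, alt_aa = NA_character_,
             consequence = NA_character_)]

  for (i in seq_len(nrow(out))) {
    ch <- out$chrom[i]; p <- out$pos[i]
    g <- genes[chrom == ch & tx_start <= p & tx_end >= p]
    if (nrow(g) == 0L) next
    regs <- vapply(seq_len(nrow(g)), function(k)
      region_in_gene(p, g[k], exons[gene_id == g$gene_id[k]]), character(1))
    best <- which.min(match(regs, REGION_LEVELS))
    out$region[i] <- regs[best]
    out$gene_id[i] <- g$gene_id[best]
    if (regs[best] == "CDS") {
      cons <- cds_consequence(p, g[best], exons[gene_id == g$gene_id[best]], seqs)
      out$ref_codon[i] <- cons$ref_codon
      out$alt_codon[i] <- cons$alt_codon
      out$ref_aa[i] <- cons$ref_aa
      out$alt_aa[i] <- cons$alt_aa
      out$consequence[i] <- cons$consequence
    }
  }
  out
}

# region of a position within one gene (position is inside the gene span)
region_in_gene <- function(p, g, ex) {
  in_exon <- any(p >= ex$start & p <= ex$end)
  if (!in_exon) return("intron")
  if (is.na(g$cds_start)) return("noncoding_exon")
  if (p >= g$cds_start & p <= g$cds_end) return("CDS")
  upstream <- p < g$cds_start
  if (g$strand == "+") {
    if (upstream) "five_prime_UTR" else "three_prime_UTR"
  } else {
    if (upstream) "three_prime_UTR" else "five_prime_UTR"
  }
}

# codon substitution for a CDS position; editing reads A as G in transcript
# orientation
cds_consequence <- function(p, g, ex, seqs, alt_tx = "G") {
  pieces <- ex[order(start)]
  pieces[, `:=`(cstart = pmax(start, g$cds_start), cend = pmin(end, g$cds_end))]
  pieces <- pieces[cstart <= cend]
  cds_positions <- unlist(Map(seq.int, pieces$cstart, pieces$cend))
  if (length(cds_positions) %% 3L != 0L)
    stop(sprintf("annotation error: CDS of %s has length not divisible by 3",
                 g$gene_id), call. = FALSE)
  cds_seq <- paste(substring(seqs[[g$chrom]], pieces$cstart, pieces$cend),
                   collapse = "")
  if (g$strand == "-") {
    cds_seq <- revcomp(cds_seq)
    cds_positions <- rev(cds_positions)
  }
  cpos <- match(p, cds_positions)
  if (is.na(cpos))
    stop("internal error: position not in CDS", call. = FALSE)
  codon_idx <- (cpos - 1L) %/% 3L
  within <- (cpos - 1L) %% 3L + 1L
  ref_codon <- substr(cds_seq, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_tx
  ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
  consequence <- if (ref_aa == alt_aa) {
    "synonymous"
  } else if (ref_aa == "*" || alt_aa == "*") {
    "stop_altering"
  } else {
    "missense"
  }
  list(ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, consequence = consequence)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Fraction of sites per region category
#'
#' @param records an [annotate_sites()] result (or any table with a
#'   `region` column).
#' @return named numeric vector of fractions over the observed categories,
#'   summing to 1.
#' @export
annotation_distribution <- function(records) {
  if (nrow(records) == 0L)
    stop("annotation_distribution requires at least one record", call. = FALSE)
  tab <- table(factor(records$region, levels = REGION_LEVELS))
  tab <- tab[tab > 0]
  as.numeric(tab) / sum(tab) -> fr
  stats::setNames(fr, names(tab))
}
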