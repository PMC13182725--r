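#' Write a complete synthetic study to disk
#'
#' Runs [build_genome()], [plant_truth()] and [simulate_alignments()] under
#' the configured seed and writes every artifact the pipeline consumes:
#' genome FASTA, annotation GTF, one coordinate-sorted SAM per sample, the
#' truth BED (0-based half-open) with a companion per-sample level TSV,
#' germline VCF, repeat-mask BED, per-gene read counts and the design table.
#' A fixed seed yields byte-identical files across runs.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if missing).
#' @return invisible list with all file paths plus the in-memory `genome`,
#'   `truth` and `sim` objects.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- build_genome(config)
  truth <- plant_truth(genome, config)
  sim <- simulate_alignments(genome, truth, config)

  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    sam = stats::setNames(file.path(dir, paste0(sim$design$sample_id, ".sam")),
                          sim$design$sample_id),
    truth_bed = file.path(dir, "truth_sites.bed"),
    truth_levels = file.path(dir, "truth_levels.tsv"),
    germline_vcf = file.path(dir, "germline.vcf"),
    contaminants = file.path(dir, "contaminants.tsv"),
    repeats_bed = file.path(dir, "repeats.bed"),
    counts = file.path(dir, "gene_counts.tsv"),
    design = file.path(dir, "design.tsv")
  )

  write_genome_fasta(genome, paths$fasta)
  write_annotation_gtf(genome, paths$gtf)
  for (s in sim$design$sample_id)
    write_sam(sim$alignments[[s]], genome, paths$sam[[s]])

  write_bed(truth$true_sites, paths$truth_bed, name = truth$true_sites$site_id,
            strand = truth$true_sites$strand)
  lv <- data.table(site_id = rownames(truth$levels),
                   as.data.table(truth$levels))
  write_pipeline_tsv(lv, paths$truth_levels, "true per-sample editing levels")
  write_vcf(truth$germline, paths$germline_vcf, names(genome$seqs))
  write_pipeline_tsv(truth$contaminants, paths$contaminants,
                     "planted artifact sites")
  write_bed(genome$repeats, paths$repeats_bed)
  cnt <- data.table(gene_id = rownames(sim$counts), as.data.table(sim$counts))
  write_pipeline_tsv(cnt, paths$counts, "simulated per-gene read counts")
  write_pipeline_tsv(sim$design, paths$design, "sample design")

  invisible(c(paths, list(genome = genome, truth = truth, sim = sim)))
}

#' @rdname write_simulation
#' @param genome a `genome_model`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(genome$seqs)),
                              path, width = 70L)
  invisible(path)
}

#' Read a reference genome FASTA into the sequence representation used here
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}

#' @rdname write_simulation
#' @export
write_annotation_gtf <- function(genome, path) {
  g <- as.data.table(genome$genes)
  e <- as.data.table(genome$exons)
  rows <- list()
  rows$gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$tx_start, g$tx_end), g$strand,
    type = "gene", gene_id = g$gene_id, transcript_id = NA_character_)
  rows$transcript <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$tx_start, g$tx_end), g$strand,
    type = "transcript", gene_id = g$gene_id,
    transcript_id = paste0(g$gene_id, ".t1"))
  rows$exon <- GenomicRanges::GRanges(
    e$chrom, IRanges::IRanges(e$start, e$end), e$strand,
    type = "exon", gene_id = e$gene_id,
    transcript_id = paste0(e$gene_id, ".t1"))
  cds <- cds_intervals(genome)
  if (nrow(cds) > 0L) {
    # phase: bases to skip before the first complete codon of each CDS piece
    setorder(cds, gene_id, start)
    cds[, w := end - start + 1L]
    cds[, prior := {
      o <- if (strand[1] == "+") seq_len(.N) else rev(seq_len(.N))
      cumsum(c(0L, w[order(o)][-length(w)]))[order(order(o))]
    }, by = gene_id]
    cds[, phase := (3L - prior %% 3L) %% 3L]
    rows$cds <- GenomicRanges::GRanges(
      cds$chrom, IRanges::IRanges(cds$start, cds$end), cds$strand,
      type = "CDS", gene_id = cds$gene_id,
      transcript_id = paste0(cds$gene_id, ".t1"), phase = cds$phase)
  }
  gr <- suppressWarnings(do.call(c, unname(rows)))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# genomic CDS intervals (exon pieces clipped to [cds_start, cds_end])
cds_intervals <- function(genome) {
  g <- as.data.table(genome$genes)[!is.na(cds_start)]
  if (nrow(g) == 0L)
    return(data.table(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer()))
  e <- as.data.table(genome$exons)[g[, c("gene_id", "cds_start", "cds_end")],
                                   on = "gene_id", nomatch = NULL]
  e[, `:=`(start = pmax(start, cds_start), end = pmin(end, cds_end))]
  e[start <= end, c("gene_id", "chrom", "strand", "start", "end")]
}

#' Read a GTF annotation into the gene/exon tables used by the pipeline
#'
#' @param path GTF file with gene/transcript/exon/CDS features (one
#'   transcript per gene).
#' @return list with `genes` and `exons` data.tables matching the layout of a
#'   `genome_model`.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  dt <- as.data.table(gr)
  setnames(dt, "seqnames", "chrom")
  ex <- dt[type == "exon",
           list(chrom = as.character(chrom), strand = as.character(strand),
                start = as.integer(start), end = as.integer(end),
                gene_id = gene_id)]
  setorder(ex, gene_id, start)
  ex[, exon_rank := seq_len(.N), by = gene_id]
  cds <- dt[type == "CDS",
            list(cds_start = min(as.integer(start)),
                 cds_end = max(as.integer(end))), by = gene_id]
  genes <- ex[, list(chrom = chrom[1], strand = strand[1],
                     tx_start = min(start), tx_end = max(end)), by = gene_id]
  genes <- merge(genes, cds, by = "gene_id", all.x = TRUE)
  list(genes = genes, exons = ex[, c("gene_id", "chrom", "strand",
                                     "exon_rank", "start", "end")])
}

#' @rdname write_simulation
#' @param alignments a per-sample alignment data.table from
#'   [simulate_alignments()].
#' @export
write_sam <- function(alignments, genome, path) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$seqs),
                      nchar(genome$seqs)))
  writeLines(header, path)
  body <- alignments[, list(qname, flag, chrom, pos, mapq, cigar,
                            rnext = "*", pnext = 0L, tlen = 0L, seq, qual)]
  data.table::fwrite(body, path, append = TRUE, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

write_bed <- function(dt, path, name = ".", score = 0L, strand = NULL) {
  bed <- data.table(chrom = dt$chrom,
                    start = (if ("pos" %in% names(dt)) dt$pos else dt$start) - 1L,
                    end = if ("pos" %in% names(dt)) dt$pos else dt$end,
                    name = name, score = score,
                    strand = if (is.null(strand)) "." else strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED interval file (repeat mask or editing-site whitelist)
#' @param path BED file (0-based half-open).
#' @return data.table with 1-based inclusive `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr))
}

write_vcf <- function(germline, path, chrom_names) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", chrom_names),
               "##INFO=<ID=GT,Number=1,Type=String,Description=\"Simulated germline genotype\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(germline) > 0L) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tGT=%s",
                       germline$chrom, germline$pos, germline$ref,
                       germline$alt, germline$genotype), con)
  }
  invisible(path)
}

#' Read the positions listed in a VCF (e.g. a dbSNP exclusion list)
#' @param path VCF file (plain text).
#' @return data.table with `chrom`, `pos`.
#' @export
read_vcf_positions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) return(data.table(chrom = character(), pos = integer()))
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  data.table(chrom = parts[[1]], pos = as.integer(parts[[2]]))
}
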