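#' Build a toy genome with annotated multi-exon genes
#'
#' Generates random chromosome sequences plus a small mitochondrial
#' chromosome, lays out multi-exon genes on alternating strands (most coding,
#' one non-coding per chromosome), and guarantees by construction the genomic
#' contexts the filter cascade needs to be exercisable: homopolymer runs of at
#' least five identical bases inside expressed exons, simple-repeat intervals
#' (both exonic and intergenic), and spliced genes so splice-junction
#' proximity is meaningful.
#'
#' @param config a [simulation_config()].
#' @return an object of class `genome_model`: a list with `seqs` (a named
#'   character vector of chromosome sequences), `genes`, `exons`, `repeats`,
#'   `planted_runs` data.tables, and `mito_chrom`.
#' @export
#' @examples
#' g <- build_genome(simulation_config(seed = 1))
#' names(g$seqs)
build_genome <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop_config("config", "must be a simulation_config object")
  set.seed(derive_seed(config$seed, 1L))

  chrom_names <- names(config$chrom_sizes)
  seqs <- vapply(config$chrom_sizes, random_dna, character(1))
  seqs[[config$mito_chrom]] <- random_dna(config$mito_size)

  genes_list <- list()
  exons_list <- list()
  runs_list <- list()
  repeats_list <- list()

  for (ci in seq_along(chrom_names)) {
    chrom <- chrom_names[ci]
    L <- as.integer(config$chrom_sizes[[ci]])
    layout <- layout_genes(chrom, L, config$genes_per_chrom,
                           gene_prefix = sprintf("g%d", ci))
    genes_list[[chrom]] <- layout$genes
    exons_list[[chrom]] <- layout$exons

    planted <- plant_homopolymers(seqs[[chrom]], layout$genes, layout$exons)
    seqs[[chrom]] <- planted$seq
    runs_list[[chrom]] <- planted$runs

    repeats_list[[chrom]] <- place_repeats(chrom, L, layout$genes,
                                           layout$exons, planted$runs)
  }

  # mitochondrial chromosome: one expressed single-exon non-coding gene so
  # reads map there and the mitochondrial exclusion rule sees real calls
  mito_gene <- data.table(
    gene_id = "mt_g1", chrom = config$mito_chrom, strand = "+",
    tx_start = 201L, tx_end = config$mito_size - 200L,
    cds_start = NA_integer_, cds_end = NA_integer_
  )
  mito_exon <- data.table(
    gene_id = "mt_g1", chrom = config$mito_chrom, strand = "+",
    exon_rank = 1L, start = 201L, end = config$mito_size - 200L
  )

  genome <- structure(list(
    seqs = seqs,
    genes = rbindlist(c(genes_list, list(mito_gene))),
    exons = rbindlist(c(exons_list, list(mito_exon))),
    repeats = rbindlist(repeats_list),
    planted_runs = rbindlist(runs_list),
    mito_chrom = config$mito_chrom
  ), class = "genome_model")
  validate_genome(genome)
  genome
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# lay out multi-exon genes left-to-right in equal slots, alternating strands;
# the last gene of each chromosome is non-coding
layout_genes <- function(chrom, L, n_genes, gene_prefix) {
  margin <- 2000L
  slot <- (L - 2L * margin) %/% n_genes
  genes <- vector("list", n_genes)
  exons <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    slot_start <- margin + (i - 1L) * slot + 1L
    n_ex <- sample(4:7, 1L)
    ex_w <- sample(150:450, n_ex, replace = TRUE)
    in_w <- sample(300:1000, n_ex - 1L, replace = TRUE)
    total <- sum(ex_w) + sum(in_w)
    budget <- slot - 400L
    if (total > budget) {
      in_w <- pmax(100L, as.integer(floor(in_w * (budget - sum(ex_w)) / sum(in_w))))
      total <- sum(ex_w) + sum(in_w)
    }
    gstart <- slot_start + sample.int(max(1L, slot - total - 200L), 1L)
    starts <- gstart + c(0L, cumsum(ex_w[-n_ex] + in_w))
    ends <- starts + ex_w - 1L
    strand <- if (i %% 2L == 1L) "+" else "-"
    gene_id <- sprintf("%s_%d", gene_prefix, i)

    coding <- i < n_genes   # last gene per chromosome is non-coding
    cds <- c(NA_integer_, NA_integer_)
    if (coding) {
      Lx <- sum(ex_w)
      utr5 <- sample(40:120, 1L)
      utr3 <- sample(60:200, 1L)
      cds_len <- Lx - utr5 - utr3
      cds_len <- cds_len - (cds_len %% 3L)
      if (cds_len >= 60L) {
        tx_cds <- c(utr5 + 1L, utr5 + cds_len)
        gpos <- tx_to_genome(tx_cds, starts, ends, strand)
        cds <- c(min(gpos), max(gpos))
      }
    }
    genes[[i]] <- data.table(
      gene_id = gene_id, chrom = chrom, strand = strand,
      tx_start = gstart, tx_end = max(ends),
      cds_start = cds[1], cds_end = cds[2]
    )
    exons[[i]] <- data.table(
      gene_id = gene_id, chrom = chrom, strand = strand,
      exon_rank = seq_len(n_ex), start = starts, end = ends
    )
  }
  list(genes = rbindlist(genes), exons = rbindlist(exons))
}

# map transcript coordinates (1 = 5' end of the mature transcript) to genomic
# positions given genomic exon starts/ends sorted by genomic position
tx_to_genome <- function(tx_pos, starts, ends, strand) {
  w <- ends - starts + 1L
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends); w <- rev(w) }
  cum <- cumsum(c(0L, w))
  idx <- findInterval(tx_pos, cum + 1L)
  off <- tx_pos - cum[idx] - 1L
  if (strand == "+") starts[idx] + off else ends[idx] - off
}

# overwrite short exonic windows with 6-base homopolymer runs (A on + genes,
# T on - genes, so the run base is adenosine in transcript orientation)
plant_homopolymers <- function(seq, genes, exons, per_chrom = 3L) {
  wide <- exons[exons$end - exons$start + 1L >= 60L]
  wide <- wide[order(wide$gene_id, wide$exon_rank)]
  pick <- wide[!duplicated(wide$gene_id)][seq_len(min(per_chrom, sum(!duplicated(wide$gene_id))))]
  runs <- vector("list", nrow(pick) + 1L)
  for (i in seq_len(nrow(pick))) {
    mid <- (pick$start[i] + pick$end[i]) %/% 2L
    base <- if (pick$strand[i] == "+") "A" else "T"
    substr(seq, mid, mid + 5L) <- strrep(base, 6L)
    runs[[i]] <- data.table(chrom = pick$chrom[i], start = mid, end = mid + 5L,
                            base = base, context = "exonic")
  }
  # one guaranteed intergenic run upstream of the first gene
  pos0 <- max(200L, min(genes$tx_start) - 1000L)
  substr(seq, pos0, pos0 + 6L) <- strrep("C", 7L)
  runs[[length(runs)]] <- data.table(chrom = exons$chrom[1], start = pos0,
                                     end = pos0 + 6L, base = "C",
                                     context = "intergenic")
  list(seq = seq, runs = rbindlist(runs))
}

place_repeats <- function(chrom, L, genes, exons, runs) {
  # one exonic repeat window (inside the 2nd gene's largest exon) and one
  # intergenic window; sequence content is left as-is -- the mask is the input
  g2 <- genes$gene_id[2]
  ex <- exons[exons$gene_id == g2]
  ex <- ex[which.max(ex$end - ex$start)]
  w <- min(100L, ex$end - ex$start - 19L)
  mid <- (ex$start + ex$end) %/% 2L
  exonic <- data.table(chrom = chrom, start = mid, end = mid + w - 1L,
                       context = "exonic")
  inter <- data.table(chrom = chrom, start = L - 1500L, end = L - 1001L,
                      context = "intergenic")
  rbindlist(list(exonic, inter))
}

validate_genome <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  if (anyDuplicated(names(genome$seqs)))
    stop("genome invariant violated: duplicate chromosome names")
  lens <- nchar(genome$seqs)
  ex <- genome$exons
  if (any(ex$start > ex$end) || any(ex$end > lens[ex$chrom]) || any(ex$start < 1L))
    stop("genome invariant violated: exon outside chromosome bounds")
  for (gid in unique(ex$gene_id)) {
    e <- ex[ex$gene_id == gid][order(start)]
    if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)]))
      stop(sprintf("genome invariant violated: overlapping exons in %s", gid))
  }
  g <- genome$genes[!is.na(genome$genes$cds_start)]
  for (i in seq_len(nrow(g))) {
    len <- cds_tx_length(genome, g$gene_id[i])
    if (len %% 3L != 0L)
      stop(sprintf("genome invariant violated: CDS length of %s not divisible by 3",
                   g$gene_id[i]))
  }
  invisible(genome)
}

# exonic length of the CDS of a gene, in transcript bases
cds_tx_length <- function(genome, gid) {
  g <- genome$genes[which(genome$genes$gene_id == gid)]
  e <- genome$exons[which(genome$exons$gene_id == gid)]
  sum(pmax(0L, pmin(e$end, g$cds_end) - pmax(e$start, g$cds_start) + 1L))
}

#' Genomic positions of annotated splice junctions
#'
#' Internal exon boundaries (donor and acceptor bases) of every multi-exon
#' gene; transcript termini are not junctions.
#'
#' @param genome a `genome_model` or compatible annotation list.
#' @return data.table with columns `chrom`, `pos`.
#' @export
splice_junctions <- function(genome) {
  ex <- as.data.table(genome$exons)
  out <- ex[, {
    e <- .SD[order(start)]
    n <- nrow(e)
    if (n > 1L) list(pos = c(e$end[-n], e$start[-1])) else list(pos = integer(0))
  }, by = c("gene_id", "chrom")]
  unique(out[, c("chrom", "pos")])
}

# reference homopolymer runs of >= min_len identical bases, per chromosome
homopolymer_intervals <- function(seqs, min_len = 5L) {
  out <- lapply(names(seqs), function(chrom) {
    r <- rle(strsplit(seqs[[chrom]], "", fixed = TRUE)[[1]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= min_len
    if (!any(keep)) return(NULL)
    data.table(chrom = chrom, start = ends[keep] - r$lengths[keep] + 1L,
               end = ends[keep], base = r$values[keep])
  })
  rbindlist(out[!vapply(out, is.null, logical(1))])
}
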