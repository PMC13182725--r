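#' Simulate spliced RNA-seq alignments carrying the planted variants
#'
#' Draws single-end reads from the spliced transcripts (placed back in
#' genomic coordinates with gapped, `M`/`N` CIGAR alignments so
#' splice-junction proximity is meaningful), at a per-gene depth set by
#' log-normal expression weights around `coverage_mean`. At a true editing
#' site with level `p` each overlapping read carries the edited base with
#' probability `p`; heterozygous SNPs alternate alleles with probability 0.5
#' and homozygous SNPs always; independent per-base errors occur at
#' `error_rate`. Read-end-biased contaminants place their mismatch only on
#' reads where the site falls within the terminal 4% of the aligned read.
#'
#' @param genome a [build_genome()] result.
#' @param truth the matching [plant_truth()] result.
#' @param config the same [simulation_config()].
#' @return list with `alignments` (named list of per-sample data.tables with
#'   columns `qname`, `flag`, `chrom`, `pos`, `mapq`, `cigar`, `seq`, `qual`),
#'   `counts` (gene x sample read-count matrix), `gene_lengths` (exonic union
#'   lengths), and `design`.
#' @export
simulate_alignments <- function(genome, truth, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(truth, "truth_set"),
            inherits(config, "simulation_config"))
  design <- truth$design
  rl <- config$read_length

  # per-gene expression weights, shared by all samples
  set.seed(derive_seed(config$seed, 3L))
  genes <- as.data.table(genome$genes)
  gene_len <- tx_lengths(genome)
  genes <- genes[gene_len[gene_id] >= rl + 10L]
  weights <- stats::rlnorm(nrow(genes), meanlog = 0, sdlog = config$expression_sdlog)
  names(weights) <- genes$gene_id

  total_len <- sum(gene_len[genes$gene_id])
  n_reads <- as.integer(round(config$coverage_mean * total_len / rl))

  variants <- variant_table(truth)
  exon_maps <- lapply(genes$gene_id, function(g) {
    e <- genome$exons[genome$exons$gene_id == g, ][order(start)]
    w <- e$end - e$start + 1L
    list(chrom = e$chrom[1], start = e$start, end = e$end,
         w = w, cum = cumsum(c(0L, w)), txlen = sum(w))
  })
  names(exon_maps) <- genes$gene_id

  counts <- matrix(0L, nrow = nrow(genes), ncol = nrow(design),
                   dimnames = list(genes$gene_id, design$sample_id))
  alignments <- vector("list", nrow(design))
  names(alignments) <- design$sample_id

  for (s in seq_len(nrow(design))) {
    set.seed(derive_seed(config$seed, 10L + s))
    prob <- weights * gene_len[genes$gene_id]
    n_g <- as.vector(stats::rmultinom(1, n_reads, prob))
    counts[, s] <- n_g
    alignments[[s]] <- simulate_sample_reads(
      genome, exon_maps, genes$gene_id, n_g, variants, s, config,
      qname_prefix = design$sample_id[s])
  }

  list(alignments = alignments, counts = counts,
       gene_lengths = gene_len[rownames(counts)], design = design)
}

# exonic (spliced transcript) length per gene
tx_lengths <- function(genome) {
  ex <- as.data.table(genome$exons)
  out <- ex[, list(len = sum(end - start + 1L)), by = gene_id]
  stats::setNames(out$len, out$gene_id)
}

# one row per planted variant with per-sample alternate-allele probabilities
variant_table <- function(truth) {
  n_samples <- nrow(truth$design)
  ts <- truth$true_sites
  pt <- data.table(chrom = ts$chrom, pos = ts$pos, alt = ts$alt,
                   class = "edit")
  p_true <- truth$levels

  g <- truth$germline
  pg <- data.table(chrom = g$chrom, pos = g$pos, alt = g$alt, class = "snp")
  p_g <- matrix(ifelse(g$genotype == "hom", 1, 0.5), nrow(g), n_samples)

  ct <- truth$contaminants
  pc <- data.table(chrom = ct$chrom, pos = ct$pos, alt = ct$alt,
                   class = ct$class)
  p_c <- matrix(ct$prob, nrow(ct), n_samples)

  out <- rbindlist(list(pt, pg, pc))
  out_p <- rbind(p_true, p_g, p_c)
  out[, var_idx := .I]
  list(tab = out, p = out_p)
}

simulate_sample_reads <- function(genome, exon_maps, gene_ids, n_g, variants,
                                  sample_idx, config, qname_prefix) {
  rl <- config$read_length
  reads_list <- vector("list", length(gene_ids))
  for (gi in seq_along(gene_ids)) {
    n <- n_g[gi]
    if (n == 0L) next
    m <- exon_maps[[gene_ids[gi]]]
    tstart <- sample.int(m$txlen - rl + 1L, n, replace = TRUE)
    tend <- tstart + rl - 1L
    e1 <- findInterval(tstart, m$cum + 1L)
    e2 <- findInterval(tend, m$cum + 1L)
    nblk <- e2 - e1 + 1L
    read_id <- rep(seq_len(n), nblk)
    exidx <- sequence(nblk) + rep(e1 - 1L, nblk)
    bstart <- pmax(m$start[exidx], m$start[exidx] + tstart[read_id] - m$cum[exidx] - 1L)
    bend <- pmin(m$end[exidx], m$start[exidx] + tend[read_id] - m$cum[exidx] - 1L)
    blocks <- data.table(read_id = read_id, exidx = exidx,
                         bstart = bstart, bend = bend)
    blocks[, blen := bend - bstart + 1L]
    blocks[, boff := cumsum(c(0L, blen[-.N])), by = read_id]
    reads_list[[gi]] <- list(gene = gene_ids[gi], chrom = m$chrom,
                             tstart = tstart, blocks = blocks)
  }
  reads_list <- reads_list[!vapply(reads_list, is.null, logical(1))]

  # assemble per-gene reads into one table
  per_gene <- lapply(reads_list, function(r) {
    b <- r$blocks
    chrom_seq <- genome$seqs[[r$chrom]]
    b[, piece := substr(rep(chrom_seq, .N), bstart, bend)]
    # CIGAR: M blocks joined by N gaps
    reads <- b[, list(
      pos = bstart[1],
      cigar = paste0(paste0(blen, "M", c(ifelse(diff(bstart) - blen[-.N] > 0,
                                                paste0(diff(bstart) - blen[-.N], "N"), ""),
                                         "")), collapse = ""),
      seq = paste(piece, collapse = "")
    ), by = read_id]
    setorder(reads, read_id)
    reads[, chrom := r$chrom]

    # overlay planted variants
    vt <- variants$tab[chrom == r$chrom]
    if (nrow(vt) > 0L) {
      hits <- b[vt, on = list(bstart <= pos, bend >= pos), nomatch = NULL,
                list(read_id = x.read_id, off = i.pos - x.bstart + 1L + x.boff,
                     var_idx = i.var_idx)]
      if (nrow(hits) > 0L) {
        hits[, p := variants$p[var_idx, sample_idx]]
        hits[, class := variants$tab$class[var_idx]]
        hits[, alt := variants$tab$alt[var_idx]]
        # read-end-biased contaminants only mismatch inside the terminal zone
        kz <- floor(0.04 * rl)
        hits[class == "read_end" & off > kz & off < rl - kz + 1L, p := 0]
        hits <- hits[stats::runif(.N) < p]
        if (nrow(hits) > 0L) {
          hits[, round := seq_len(.N), by = read_id]
          for (k in seq_len(max(hits$round))) {
            h <- hits[round == k]
            str <- reads$seq[h$read_id]
            substr(str, h$off, h$off) <- h$alt
            reads$seq[h$read_id] <- str
          }
        }
      }
    }
    reads
  })
  reads <- rbindlist(per_gene)

  # independent per-base sequencing errors
  n_err <- stats::rbinom(nrow(reads), rl, config$error_rate)
  err_reads <- which(n_err > 0L)
  if (length(err_reads) > 0L) {
    err <- data.table(read = rep(err_reads, n_err[err_reads]))
    err[, off := sample.int(rl, .N, replace = TRUE)]
    err <- err[!duplicated(paste(read, off))]
    cur <- substring(reads$seq[err$read], err$off, err$off)
    err[, newb := vapply(cur, random_alt, character(1))]
    err[, round := seq_len(.N), by = read]
    for (k in seq_len(max(err$round))) {
      h <- err[round == k]
      str <- reads$seq[h$read]
      substr(str, h$off, h$off) <- h$newb
      reads$seq[h$read] <- str
    }
  }

  setorder(reads, chrom, pos)
  data.table(
    qname = sprintf("%s_r%06d", qname_prefix, seq_len(nrow(reads))),
    flag = 0L, chrom = reads$chrom, pos = reads$pos, mapq = 255L,
    cigar = reads$cigar, seq = reads$seq,
    qual = strrep("F", rl)
  )
}

#' Simulate per-site editing read counts without read-level simulation
#'
#' A count-level companion to [simulate_alignments()] for statistical
#' experiments: per-site, per-sample totals are Poisson around the target
#' coverage and edited counts are binomial at the true level. Useful for
#' large calibration and power studies where read-level simulation is
#' unnecessary.
#'
#' @param levels site x sample matrix of true editing levels.
#' @param coverage mean per-sample coverage (Poisson), or a matrix of totals.
#' @param seed integer seed.
#' @return list of matrices `edited`, `total`.
#' @export
simulate_editing_counts <- function(levels, coverage, seed = 1L) {
  set.seed(derive_seed(seed, 4L))
  n <- length(levels)
  if (is.matrix(coverage)) {
    stopifnot(all(dim(coverage) == dim(levels)))
    total <- coverage
  } else {
    total <- matrix(stats::rpois(n, coverage), nrow(levels), ncol(levels))
  }
  edited <- matrix(stats::rbinom(n, as.vector(total), as.vector(levels)),
                   nrow(levels), ncol(levels))
  dimnames(edited) <- dimnames(total) <- dimnames(levels)
  list(edited = edited, total = total)
}
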