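#' Read a SAM alignment file
#'
#' Minimal reader for coordinate-sorted, single-end SAM used by the pileup
#' engine. Unmapped records (`FLAG & 0x4`) and records with `*` CIGARs are
#' dropped.
#'
#' @param path SAM file.
#' @return data.table with columns `qname`, `flag`, `chrom`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    stop(sprintf("parse error: alignment file '%s' is empty", path), call. = FALSE)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L)
    return(data.table(qname = character(), flag = integer(), chrom = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      seq = character(), qual = character()))
  parts <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(parts) < 11L || anyNA(parts[[10]]))
    stop(sprintf("parse error: truncated or malformed SAM records in '%s'", path),
         call. = FALSE)
  aln <- data.table(qname = parts[[1]], flag = as.integer(parts[[2]]),
                    chrom = parts[[3]], pos = as.integer(parts[[4]]),
                    mapq = as.integer(parts[[5]]), cigar = parts[[6]],
                    seq = parts[[10]], qual = parts[[11]])
  aln[bitwAnd(flag, 4L) == 0L & cigar != "*"]
}

#' Per-position pileup with base-quality filtering and read-end offsets
#'
#' Walks every CIGAR (via the standard exploded-CIGAR utilities), counts
#' qualifying bases per position (base quality at or above
#' `min_base_quality`; deletions and reference skips are never counted),
#' and records, for every non-reference base, its distance from the 5' and
#' 3' ends of the aligned portion of its read. Also tallies observed
#' insertion/deletion events for the indel-proximity rule.
#'
#' @param alignments a data.table from [read_sam()] (or
#'   [simulate_alignments()]).
#' @param seqs named character vector of reference chromosome sequences.
#' @param min_base_quality minimum Phred quality (offset 33) for a base to
#'   be counted.
#' @return an object of class `pileup`: list with data.tables `depth`
#'   (`chrom`, `pos`, `depth`), `alt_reads` (one row per qualifying
#'   non-reference base: `chrom`, `pos`, `base`, `qual`, `dist5`, `dist3`,
#'   `alen`), `alt_counts` (`chrom`, `pos`, `base`, `count`), and `indels`
#'   (`chrom`, `pos`, `op`, `count`).
#' @export
pileup <- function(alignments, seqs, min_base_quality = 25L) {
  stopifnot(is.data.frame(alignments))
  missing_chrom <- setdiff(unique(alignments$chrom), names(seqs))
  if (length(missing_chrom) > 0L)
    stop(sprintf("reference mismatch: chromosome(s) %s absent from genome",
                 paste(missing_chrom, collapse = ", ")), call. = FALSE)
  n <- nrow(alignments)
  if (n == 0L) return(empty_pileup())

  ops <- GenomicAlignments::explodeCigarOps(alignments$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(alignments$cigar)
  nop <- lengths(ops)
  ct <- data.table(read = rep(seq_len(n), nop),
                   op = unlist(ops), len = unlist(lens))
  ct[, ref_consumes := op %in% c("M", "D", "N", "=", "X")]
  ct[, query_consumes := op %in% c("M", "I", "S", "=", "X")]
  ct[, aligned := op %in% c("M", "=", "X")]
  ct[, ref_off := cumsum(c(0L, (len * ref_consumes)[-.N])), by = read]
  ct[, q_off := cumsum(c(0L, (len * query_consumes)[-.N])), by = read]
  ct[, a_off := cumsum(c(0L, (len * aligned)[-.N])), by = read]
  read_alen <- ct[, list(alen = sum(len[aligned])), by = read]$alen
  read_pos <- alignments$pos
  read_chrom <- alignments$chrom

  mb <- ct[aligned == TRUE]
  mb[, rstart := read_pos[read] + ref_off]
  mb[, rend := rstart + len - 1L]
  mb[, qstart := q_off + 1L]
  mb[, astart := a_off + 1L]

  # raw depth from aligned-block coverage, per chromosome
  depth_list <- lapply(split(mb, mb[, read_chrom[read]]), function(b) {
    cov <- IRanges::coverage(IRanges::IRanges(b$rstart, b$rend))
    rd <- data.table(pos_end = cumsum(S4Vectors::runLength(cov)),
                     depth = S4Vectors::runValue(cov))
    rd[, pos_start := pos_end - S4Vectors::runLength(cov) + 1L]
    rd <- rd[depth > 0L]
    if (nrow(rd) == 0L)
      return(data.table(pos = integer(), depth = integer()))
    data.table(pos = unlist(Map(seq.int, rd$pos_start, rd$pos_end)),
               depth = rep(rd$depth, rd$pos_end - rd$pos_start + 1L))
  })
  depth <- rbindlist(lapply(names(depth_list), function(ch)
    data.table(chrom = ch, depth_list[[ch]])))

  # byte-level scan of the aligned blocks for mismatches and low-quality bases
  big_read <- paste(substring(alignments$seq[mb$read], mb$qstart,
                              mb$qstart + mb$len - 1L), collapse = "")
  big_qual <- paste(substring(alignments$qual[mb$read], mb$qstart,
                              mb$qstart + mb$len - 1L), collapse = "")
  big_ref <- paste(substring(unname(seqs[read_chrom[mb$read]]), mb$rstart, mb$rend),
                   collapse = "")
  rb <- charToRaw(big_read)
  fb <- charToRaw(big_ref)
  qb <- as.integer(charToRaw(big_qual)) - 33L
  bad_q <- qb < min_base_quality
  is_n <- rb == charToRaw("N")
  mism <- which((rb != fb & !bad_q & !is_n))
  lowq <- which(bad_q | is_n)

  cum <- cumsum(c(0L, mb$len))
  locate <- function(idx) {
    blk <- findInterval(idx, cum + 1L)
    off <- idx - cum[blk] - 1L
    data.table(read = mb$read[blk],
               chrom = read_chrom[mb$read[blk]],
               pos = mb$rstart[blk] + off,
               aidx = mb$astart[blk] + off)
  }

  if (length(mism) > 0L) {
    alt_reads <- locate(mism)
    alt_reads[, base := strsplit(rawToChar(rb[mism]), "")[[1]]]
    alt_reads[, qual := qb[mism]]
    alt_reads[, alen := read_alen[read]]
    alt_reads[, dist5 := aidx]
    alt_reads[, dist3 := alen - aidx + 1L]
    alt_reads <- alt_reads[, c("chrom", "pos", "base", "qual",
                               "dist5", "dist3", "alen")]
  } else {
    alt_reads <- data.table(chrom = character(), pos = integer(),
                            base = character(), qual = integer(),
                            dist5 = integer(), dist3 = integer(),
                            alen = integer())
  }

  # subtract excluded (low-quality or N) bases from depth
  if (length(lowq) > 0L) {
    ex <- locate(lowq)[, list(n_ex = .N), by = c("chrom", "pos")]
    depth <- merge(depth, ex, by = c("chrom", "pos"), all.x = TRUE)
    depth[is.na(n_ex), n_ex := 0L]
    depth[, depth := depth - n_ex]
    depth[, n_ex := NULL]
    depth <- depth[depth > 0L]
  }

  alt_counts <- alt_reads[, list(count = .N), by = c("chrom", "pos", "base")]

  # indel events: I anchored to the preceding reference base, D to its span
  id <- ct[op %in% c("I", "D")]
  if (nrow(id) > 0L) {
    id[, pos := read_pos[read] + ref_off - (op == "I")]
    reps <- ifelse(id$op == "D", id$len, 1L)
    expand <- id[rep(seq_len(nrow(id)), reps)]
    expand[, pos := pos + sequence(reps) - 1L]
    indels <- expand[, list(count = .N),
                     by = list(chrom = read_chrom[read], pos, op)]
  } else {
    indels <- data.table(chrom = character(), pos = integer(),
                         op = character(), count = integer())
  }

  structure(list(depth = depth, alt_reads = alt_reads,
                 alt_counts = alt_counts, indels = indels,
                 min_base_quality = as.integer(min_base_quality)),
            class = "pileup")
}

empty_pileup <- function() {
  structure(list(
    depth = data.table(chrom = character(), pos = integer(), depth = integer()),
    alt_reads = data.table(chrom = character(), pos = integer(),
                           base = character(), qual = integer(),
                           dist5 = integer(), dist3 = integer(), alen = integer()),
    alt_counts = data.table(chrom = character(), pos = integer(),
                            base = character(), count = integer()),
    indels = data.table(chrom = character(), pos = integer(),
                        op = character(), count = integer()),
    min_base_quality = 25L), class = "pileup")
}

#' Single-position observation from a pileup
#'
#' @param pu a [pileup()] result.
#' @param chrom,pos position (1-based).
#' @param seqs reference sequences (for the reference base).
#' @return list with `ref_base`, `allele_counts` (named A/C/G/T vector) and
#'   `end_offsets` (data.table of `dist5`, `dist3`, `alen` per non-reference
#'   supporting read).
#' @export
site_observation <- function(pu, chrom, pos, seqs) {
  ch <- chrom; p <- pos
  ref <- substr(seqs[[ch]], p, p)
  d <- pu$depth[chrom == ch & pos == p]
  total <- if (nrow(d) > 0L) d$depth else 0L
  ac <- stats::setNames(rep(0L, 4L), c("A", "C", "G", "T"))
  alt <- pu$alt_counts[chrom == ch & pos == p]
  ac[alt$base] <- alt$count
  ac[ref] <- total - sum(ac)
  list(ref_base = ref, allele_counts = ac,
       end_offsets = pu$alt_reads[chrom == ch & pos == p,
                                  c("base", "dist5", "dist3", "alen")])
}
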