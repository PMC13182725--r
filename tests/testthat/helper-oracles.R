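# independent brute-force oracles; deliberately written with plain loops and
# none of the package's internals

# ---- filter-cascade oracle -------------------------------------------------

# one randomized candidate site with its full context
random_site_context <- function() {
  L <- 200L
  seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  pos <- sample(50:150, 1)
  seq_chars[pos] <- "A"
  # sometimes embed the site in / next to a run
  r <- runif(1)
  if (r < 0.15) {
    w <- sample(5:8, 1)
    seq_chars[pos:(pos + w - 1L)] <- "A"
  } else if (r < 0.25) {
    w <- sample(5:7, 1)
    seq_chars[(pos + 1L):(pos + w)] <- "T"
  }
  chrom <- if (runif(1) < 0.07) "chrM" else "chr_t"
  n_j <- sample(0:2, 1)
  junctions <- integer(0)
  if (n_j > 0) {
    junctions <- pos + sample(-10:10, 1)
    if (n_j > 1) junctions <- c(junctions, sample(10:190, n_j - 1))
    junctions <- sort(unique(pmax(2L, pmin(198L, as.integer(junctions)))))
  }
  reps <- if (runif(1) < 0.2)
    data.frame(chrom = chrom, start = pos - sample(0:3, 1), end = pos + sample(0:3, 1))
  else data.frame(chrom = character(), start = integer(), end = integer())
  n_ind <- sample(0:2, 1)
  indels <- if (n_ind > 0)
    data.frame(chrom = chrom, pos = pos + sample(-3:3, n_ind),
               op = sample(c("I", "D"), n_ind, replace = TRUE),
               count = sample(1:4, n_ind, replace = TRUE))
  else data.frame(chrom = character(), pos = integer(), op = character(),
                  count = integer())
  # alternate-supporting reads (one simulated sample)
  n_alt <- sample(2:20, 1)
  d5 <- sample(1:100, n_alt, replace = TRUE)
  alt_reads <- data.frame(chrom = chrom, pos = pos, base = "G",
                          qual = 37L, dist5 = d5, dist3 = 100L - d5 + 1L,
                          alen = 100L)
  if (runif(1) < 0.25) {  # sometimes make all support end-biased
    d5 <- sample(c(1:4, 97:100), n_alt, replace = TRUE)
    alt_reads$dist5 <- d5
    alt_reads$dist3 <- 100L - d5 + 1L
  }
  # cross-sample AAF profile (6 samples)
  profile_kind <- sample(c("edit", "het", "hom", "mixed"), 1,
                         prob = c(0.5, 0.2, 0.15, 0.15))
  depth <- sample(c(0:5, 12:60), 6, replace = TRUE)
  aaf <- switch(profile_kind,
                edit = runif(6, 0, 0.35),
                het = runif(6, 0.40, 0.60),
                hom = rep(1, 6),
                mixed = runif(6, 0, 1))
  alt_depth <- round(aaf * depth)
  if (profile_kind == "hom") alt_depth <- depth
  list(chrom = chrom, pos = pos, seq = paste(seq_chars, collapse = ""),
       junctions = junctions, repeats = reps, indels = indels,
       alt_reads = alt_reads,
       per_sample = data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                               sample_id = paste0("s", 1:6), depth = depth,
                               alt_depth = alt_depth,
                               aaf = ifelse(depth > 0, alt_depth / depth, NA)),
       in_dbsnp = runif(1) < 0.12, in_whitelist = runif(1) < 0.12)
}

# first failing rule, re-derived from scratch
oracle_verdict <- function(ctx) {
  if (ctx$in_whitelist) return(list(status = "pass", rule = NA_character_))
  chars <- strsplit(ctx$seq, "")[[1]]
  # homopolymer: any run of >= 5 identical bases containing pos or adjacent
  run_hit <- FALSE
  i <- 1L
  while (i <= length(chars)) {
    j <- i
    while (j < length(chars) && chars[j + 1L] == chars[i]) j <- j + 1L
    if (j - i + 1L >= 5L && ctx$pos >= i - 1L && ctx$pos <= j + 1L)
      run_hit <- TRUE
    i <- j + 1L
  }
  if (run_hit) return(list(status = "fail", rule = "homopolymer"))
  if (nrow(ctx$repeats) > 0) {
    for (k in seq_len(nrow(ctx$repeats)))
      if (ctx$pos >= ctx$repeats$start[k] && ctx$pos <= ctx$repeats$end[k])
        return(list(status = "fail", rule = "simple_repeat"))
  }
  if (ctx$chrom == "chrM") return(list(status = "fail", rule = "mitochondrial"))
  # a junction spans the boundary between base b (donor side) and b+1
  # (acceptor side); distance is to the nearest of the two boundary bases
  jb <- c(ctx$junctions, ctx$junctions + 1L)
  if (length(jb) > 0 && min(abs(jb - ctx$pos)) <= 6)
    return(list(status = "fail", rule = "splice_junction"))
  near_ind <- ctx$indels[ctx$indels$count >= 2, , drop = FALSE]
  if (nrow(near_ind) > 0 && min(abs(near_ind$pos - ctx$pos)) <= 1)
    return(list(status = "fail", rule = "indel_proximity"))
  surviving <- sum(ctx$alt_reads$dist5 > floor(0.04 * ctx$alt_reads$alen) &
                     ctx$alt_reads$dist3 > floor(0.04 * ctx$alt_reads$alen))
  if (surviving < 2) return(list(status = "fail", rule = "read_end"))
  if (ctx$in_dbsnp) return(list(status = "fail", rule = "dbsnp"))
  ps <- ctx$per_sample
  cov <- ps$depth >= 10
  if (sum(cov) > 0) {
    f_hom <- sum(cov & ps$alt_depth == ps$depth) / sum(cov)
    f_het <- sum(cov & ps$aaf >= 0.40 & ps$aaf <= 0.60) / sum(cov)
    if (f_hom > 0.90 || f_het > 0.90)
      return(list(status = "fail", rule = "germline_pattern"))
  } else {
    return(list(status = "indeterminate", rule = NA_character_))
  }
  list(status = "pass", rule = NA_character_)
}

# run the package's cascade on the same context
package_verdict <- function(ctx) {
  seqs <- stats::setNames(ctx$seq, ctx$chrom)
  annotation <- list(
    genes = data.frame(gene_id = "gx", chrom = ctx$chrom, strand = "+",
                       tx_start = 1L, tx_end = 200L,
                       cds_start = NA_integer_, cds_end = NA_integer_),
    exons = junctions_to_exons(ctx$junctions, ctx$chrom))
  pu <- structure(list(
    depth = data.table::data.table(chrom = ctx$chrom, pos = ctx$pos,
                                   depth = 50L),
    alt_reads = data.table::as.data.table(ctx$alt_reads),
    alt_counts = data.table::data.table(chrom = ctx$chrom, pos = ctx$pos,
                                        base = "G",
                                        count = nrow(ctx$alt_reads)),
    indels = data.table::as.data.table(ctx$indels),
    min_base_quality = 25L), class = "pileup")
  calls <- data.table::data.table(chrom = ctx$chrom, pos = ctx$pos,
                                  ref = "A", alt = "G")
  v <- suppressMessages(apply_site_filters(
    calls, seqs, annotation, list(s1 = pu), mito_chrom = "chrM",
    dbsnp = if (ctx$in_dbsnp) data.frame(chrom = ctx$chrom, pos = ctx$pos)
            else data.frame(chrom = character(), pos = integer()),
    whitelist = if (ctx$in_whitelist)
      data.frame(chrom = ctx$chrom, pos = ctx$pos)
    else data.frame(chrom = character(), pos = integer()),
    repeat_mask = ctx$repeats, verbose = FALSE))
  if (v$status == "fail")
    return(list(status = "fail", rule = v$failed_rule))
  if (v$whitelisted)   # whitelisted sites are exempt from every rule
    return(list(status = "pass", rule = NA_character_))
  g <- germline_pattern_filter(data.table::as.data.table(ctx$per_sample))
  list(status = g$status, rule = g$failed_rule)
}

# encode a junction list as a gene's exon table: each junction position is an
# internal exon boundary (donor base)
junctions_to_exons <- function(junctions, chrom) {
  if (length(junctions) == 0)
    return(data.frame(gene_id = "gx", chrom = chrom, strand = "+",
                      exon_rank = 1L, start = 1L, end = 200L))
  b <- sort(unique(pmax(2L, pmin(198L, as.integer(junctions)))))
  # exons: [1, b1], [b1+1, b2], ..., [bk+1, 200]; boundaries at b_i and b_i+1
  starts <- c(1L, b + 1L)
  ends <- c(b, 200L)
  data.frame(gene_id = "gx", chrom = chrom, strand = "+",
             exon_rank = seq_along(starts), start = starts, end = ends)
}

# ---- small statistical oracles ---------------------------------------------

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

pca_oracle <- function(L) {
  # mean-impute per row, centre rows, eigendecompose the site covariance
  # (samples are the observations), project samples onto the eigenvectors
  for (i in seq_len(nrow(L))) {
    na <- is.na(L[i, ]); if (any(na)) L[i, na] <- mean(L[i, !na])
  }
  Lc <- L - rowMeans(L)
  S <- Lc %*% t(Lc) / (ncol(L) - 1)
  ev <- eigen(S, symmetric = TRUE)
  list(values = ev$values, scores = t(Lc) %*% ev$vectors)
}

# closed-form binomial LRT: pooled vs per-group MLE log-likelihoods
lrt_oracle <- function(edited, total, groups) {
  ll <- function(e, t, p) {
    p <- min(max(p, 1e-12), 1 - 1e-12)
    sum(e * log(p) + (t - e) * log(1 - p))
  }
  p0 <- sum(edited) / sum(total)
  l0 <- ll(edited, total, p0)
  l1 <- 0
  for (g in unique(groups)) {
    sel <- groups == g
    pg <- sum(edited[sel]) / sum(total[sel])
    l1 <- l1 + ll(edited[sel], total[sel], pg)
  }
  stat <- 2 * (l1 - l0)
  df <- length(unique(groups)) - 1
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

# independent consequence classification: plain string handling + seqinr
codon_oracle <- function(p, gene, exons, seqs) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ex <- exons[order(exons$start), , drop = FALSE]
  pieces <- list(); cpos_map <- integer(0)
  for (k in seq_len(nrow(ex))) {
    s <- max(ex$start[k], gene$cds_start); e <- min(ex$end[k], gene$cds_end)
    if (s > e) next
    pieces[[length(pieces) + 1L]] <- substring(seqs[[gene$chrom]], s, e)
    cpos_map <- c(cpos_map, s:e)
  }
  cds <- paste(unlist(pieces), collapse = "")
  if (gene$strand == "-") {
    cds <- paste(rev(comp[strsplit(cds, "")[[1]]]), collapse = "")
    cpos_map <- rev(cpos_map)
  }
  cpos <- which(cpos_map == p)
  ci <- (cpos - 1) %/% 3
  off <- (cpos - 1) %% 3 + 1
  codon <- substring(cds, ci * 3 + 1, ci * 3 + 3)
  alt_codon <- codon
  substr(alt_codon, off, off) <- "G"
  aa1 <- seqinr::translate(strsplit(codon, "")[[1]])
  aa2 <- seqinr::translate(strsplit(alt_codon, "")[[1]])
  cls <- if (aa1 == aa2) "synonymous"
  else if (aa1 == "*" || aa2 == "*") "stop_altering"
  else "missense"
  list(ref_codon = codon, alt_codon = alt_codon, ref_aa = aa1, alt_aa = aa2,
       consequence = cls)
}
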