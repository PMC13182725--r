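#' Differential editing via binomial GLM likelihood-ratio test
#'
#' Per site, fits a binomial GLM with logit link on the per-sample
#' (edited, total) counts: full model = group factor, null = intercept only.
#' The LRT statistic is twice the log-likelihood difference (equivalently the
#' deviance difference), compared to a chi-square with
#' `df = n_groups - 1`. Masked (under-covered) samples are excluded; groups
#' left with no covered sample are dropped and the degrees of freedom
#' adjusted. Sites with fewer than two covered groups are skipped with a
#' reason. FDR q-values are Benjamini-Hochberg.
#'
#' @param mat an [editing_matrix()].
#' @param groups group label per sample (defaults to `mat$groups`).
#' @return data.table: `site_id`, `lrt_statistic`, `df`, `p_value`,
#'   `q_value`, one `mean_<group>` column per group, `n_groups_used`,
#'   `skip_reason`.
#' @export
lrt_differential <- function(mat, groups = NULL) {
  stopifnot(inherits(mat, "editing_matrix"))
  groups <- groups %||% mat$groups
  if (is.null(groups)) stop("group labels required", call. = FALSE)
  stopifnot(length(groups) == ncol(mat$levels))
  if (length(unique(groups)) < 2L)
    stop("at least two groups are required", call. = FALSE)
  glabs <- unique(groups)

  n_sites <- nrow(mat$levels)
  stat <- df <- p <- rep(NA_real_, n_sites)
  reason <- rep(NA_character_, n_sites)
  gmeans <- matrix(NA_real_, n_sites, length(glabs),
                   dimnames = list(NULL, glabs))
  for (i in seq_len(n_sites)) {
    cov <- mat$mask[i, ]
    for (gl in glabs) {
      sel <- cov & groups == gl
      if (any(sel)) gmeans[i, gl] <- mean(mat$levels[i, sel])
    }
    g <- factor(groups[cov])
    g <- droplevels(g)
    if (nlevels(g) < 2L) {
      reason[i] <- "fewer than two covered groups"
      next
    }
    e <- mat$edited[i, cov]
    tt <- mat$total[i, cov]
    fit <- suppressWarnings(
      stats::glm(cbind(e, tt - e) ~ g, family = stats::binomial()))
    stat[i] <- max(0, fit$null.deviance - fit$deviance)
    df[i] <- nlevels(g) - 1L
    p[i] <- stats::pchisq(stat[i], df[i], lower.tail = FALSE)
  }
  out <- data.table(site_id = rownames(mat$levels) %||%
                      as.character(seq_len(n_sites)),
                    lrt_statistic = stat, df = df, p_value = p,
                    q_value = adjust_fdr(p))
  for (gl in glabs) out[, paste0("mean_", gl) := gmeans[, gl]]
  out[, n_groups_used := df + 1L]
  out[, skip_reason := reason]
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_i = min over j with rank >= rank(i) of p_(j) * m / j`, capped at 1,
#' with `m` the number of non-missing p-values; missing values propagate.
#'
#' @param p_values numeric vector of p-values (NA/NaN allowed).
#' @return q-values of the same length.
#' @export
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03))
adjust_fdr <- function(p_values) {
  q <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Spearman rank correlation with mid-ranks and exact small-n p-values
#'
#' `rho` is the Pearson correlation of mid-ranks (average ranks for ties).
#' For more than 9 complete pairs the p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`; for 9 or fewer pairs it is the
#' exact two-sided permutation probability of `|rho|` at least as large.
#'
#' @param x,y numeric vectors; incomplete pairs are dropped.
#' @return list with `rho`, `p_value`, `n` (complete pairs used). `rho` is
#'   `NA` when either vector has zero variance.
#' @export
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))
spearman_cor <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  if (n > 9L) {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    perms <- all_permutations(n)
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    # Pearson of rx with each permuted ry via the linear identity
    mx <- mean(rx); my <- mean(ry)
    sx <- sqrt(sum((rx - mx)^2)); sy <- sqrt(sum((ry - my)^2))
    # sum((rx - mx) * ry_perm) equals the centred cross-product because
    # sum(rx - mx) = 0, so my drops out
    rho_all <- as.vector(ry_perm %*% (rx - mx)) / (sx * sy)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p_value = min(1, p), n = n)
}

# all permutations of 1..n as a (n!)-row matrix
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, p + (p >= i))))
}

#' Welch / pooled two-sample t-test on expression values
#'
#' @param a,b numeric vectors (one per group, each with at least 2 values).
#' @param pooled use the pooled-variance (classic Student) form instead of
#'   the Welch default.
#' @return list with `t`, `p_value`, `df`.
#' @export
students_t <- function(a, b, pooled = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, p_value = 1, df = NA_real_))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p_value = 0, df = NA_real_))
  }
  ht <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Per-sample overall editing level
#'
#' Both common summaries of global editing activity: the unweighted mean of
#' defined site levels per sample, and the read-weighted variant
#' (total edited reads / total qualifying reads over covered cells).
#'
#' @param mat an [editing_matrix()].
#' @return data.table: `sample_id`, `mean_level`, `pooled_level`.
#' @export
overall_editing_level <- function(mat) {
  stopifnot(inherits(mat, "editing_matrix"))
  e <- mat$edited; tt <- mat$total
  e[!mat$mask] <- 0L; tt[!mat$mask] <- 0L
  data.table(sample_id = mat$sample_ids,
             mean_level = colMeans(mat$levels, na.rm = TRUE),
             pooled_level = colSums(e) / pmax(colSums(tt), 1L))
}

#' Editing-expression correlation per site/host-gene pair
#'
#' Spearman correlation between a site's editing levels and its host gene's
#' TPM across samples, over samples where the site is covered.
#'
#' @param mat an [editing_matrix()].
#' @param tpm gene x sample TPM matrix (samples in the same order).
#' @param site2gene data.frame mapping `site_id` to `gene_id`.
#' @param min_pairs minimum covered samples per pair (default 5).
#' @param alpha significance level for the `significant` flag.
#' @param verbose log skipped pairs.
#' @return data.table: `site_id`, `gene_id`, `rho`, `p_value`, `n_pairs`,
#'   `significant`.
#' @export
editing_expression_correlation <- function(mat, tpm, site2gene,
                                           min_pairs = 5L, alpha = 0.05,
                                           verbose = TRUE) {
  stopifnot(inherits(mat, "editing_matrix"))
  site2gene <- as.data.table(site2gene)
  rows <- vector("list", nrow(site2gene))
  for (i in seq_len(nrow(site2gene))) {
    sid <- site2gene$site_id[i]; gid <- site2gene$gene_id[i]
    if (is.na(gid) || !gid %in% rownames(tpm)) {
      if (verbose) message(sprintf("site %s: host gene %s absent from expression table; skipped",
                                   sid, gid %||% "NA"))
      next
    }
    si <- match(sid, rownames(mat$levels))
    if (is.na(si)) next
    x <- mat$levels[si, ]
    y <- tpm[gid, ]
    ok <- !is.na(x)
    if (sum(ok) < min_pairs) {
      if (verbose) message(sprintf("site %s: only %d covered samples (< %d); skipped",
                                   sid, sum(ok), min_pairs))
      next
    }
    sc <- spearman_cor(x[ok], y[ok])
    rows[[i]] <- data.table(site_id = sid, gene_id = gid, rho = sc$rho,
                            p_value = sc$p_value, n_pairs = sc$n,
                            significant = !is.na(sc$p_value) && sc$p_value < alpha)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.table(site_id = character(), gene_id = character(),
                      rho = numeric(), p_value = numeric(),
                      n_pairs = integer(), significant = logical()))
  rbindlist(rows)
}

#' Principal component analysis of editing profiles
#'
#' Masked cells are mean-imputed per site, sites centred, and the
#' decomposition computed by SVD. Sites undefined in every sample are
#' dropped (and logged).
#'
#' @param mat an [editing_matrix()] (at least 2 sites and 2 samples).
#' @param verbose log dropped sites.
#' @return object of class `pca_result`: `scores` (samples x PC),
#'   `loadings` (sites x PC), `variance_fraction`.
#' @export
pca_editing <- function(mat, verbose = TRUE) {
  stopifnot(inherits(mat, "editing_matrix"))
  L <- mat$levels
  all_na <- rowSums(!is.na(L)) == 0L
  if (any(all_na)) {
    if (verbose)
      message(sprintf("dropping %d site(s) undefined in all samples", sum(all_na)))
    L <- L[!all_na, , drop = FALSE]
  }
  if (nrow(L) < 2L || ncol(L) < 2L)
    stop("PCA requires at least 2 sites and 2 samples", call. = FALSE)
  for (i in seq_len(nrow(L))) {
    na <- is.na(L[i, ])
    if (any(na)) L[i, na] <- mean(L[i, !na])
  }
  pc <- stats::prcomp(t(L), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_fraction = vf), class = "pca_result")
}

#' Overlap summary of site or gene sets
#'
#' Counts every exclusive intersection region of up to four sets (Venn
#' regions), per-set unique elements, and "shared by at least k sets"
#' counts.
#'
#' @param sets named list of 2-4 character vectors.
#' @return list with `membership` (element x set logical data.table),
#'   `regions` (exclusive region counts keyed like `"A&B"`), `unique`
#'   (per-set unique element lists), `at_least` (counts of elements in >= k
#'   sets).
#' @export
#' @examples
#' overlap_sets(list(A = c("x", "y"), B = c("y", "z")))
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, length(sets) <= 4L,
            !is.null(names(sets)))
  sets <- lapply(sets, unique)
  elements <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) elements %in% s,
                 logical(length(elements)))
  if (length(elements) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1L, function(r) paste(names(sets)[r], collapse = "&"))
  k <- length(sets)
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(names(sets), m, paste, collapse = "&")))
  regions <- stats::setNames(integer(length(combos)), combos)
  tab <- table(pattern)
  regions[names(tab)] <- as.integer(tab)
  uniq <- lapply(seq_along(sets), function(i)
    elements[memb[, i] & rowSums(memb) == 1L])
  names(uniq) <- names(sets)
  at_least <- vapply(seq_len(k), function(m) sum(rowSums(memb) >= m),
                     integer(1))
  names(at_least) <- paste0(">=", seq_len(k))
  list(membership = data.table(element = elements, as.data.table(memb)),
       regions = regions, unique = uniq, at_least = at_least)
}
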