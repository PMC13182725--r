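mk_mat <- function(edited, total, groups = NULL, min_depth = 10L) {
  e <- as.matrix(edited); t <- as.matrix(total)
  rownames(e) <- rownames(t) <- paste0("site", seq_len(nrow(e)))
  colnames(e) <- colnames(t) <- paste0("s", seq_len(ncol(e)))
  editing_matrix(e, t, groups = groups, min_depth = min_depth)
}

test_that("LRT is null for identical groups and sharp for separated ones", {
  m0 <- mk_mat(matrix(5L, 1, 4), matrix(50L, 1, 4))
  r0 <- lrt_differential(m0, groups = c("a", "a", "b", "b"))
  expect_lt(r0$lrt_statistic, 1e-8)
  expect_gt(r0$p_value, 0.999)

  e <- matrix(c(2L, 3L, 20L, 22L), 1, 4)
  t <- matrix(40L, 1, 4)
  m1 <- mk_mat(e, t)
  r1 <- lrt_differential(m1, groups = c("a", "a", "b", "b"))
  expect_lt(r1$p_value, 1e-4)
  # agrees with the closed-form pooled-vs-per-group MLE oracle
  want <- lrt_oracle(as.vector(e), as.vector(t), c("a", "a", "b", "b"))
  expect_equal(r1$lrt_statistic, want$stat, tolerance = 1e-6)
  expect_equal(r1$df, want$df)
  expect_equal(r1$p_value, want$p, tolerance = 1e-6)
})

test_that("LRT drops uncovered groups and skips single-group sites", {
  e <- matrix(c(2L, 3L, 20L, 22L, 2L, 1L), 1, 6)
  t <- matrix(c(40L, 40L, 40L, 40L, 5L, 5L), 1, 6)   # group c uncovered
  m <- mk_mat(e, t)
  r <- lrt_differential(m, groups = c("a", "a", "b", "b", "c", "c"))
  expect_equal(r$df, 1)
  expect_equal(r$n_groups_used, 2)
  expect_true(is.na(r$mean_c))

  e2 <- matrix(c(2L, 3L, 4L, 5L, 2L, 1L), 1, 6)
  t2 <- matrix(c(40L, 40L, 5L, 5L, 5L, 5L), 1, 6)
  m2 <- mk_mat(e2, t2)
  r2 <- lrt_differential(m2, groups = c("a", "a", "b", "b", "c", "c"))
  expect_true(is.na(r2$p_value))
  expect_match(r2$skip_reason, "fewer than two")
})

test_that("BH adjustment matches the step-up oracle and handles NAs", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(sample(3:50, 1))^sample(1:3, 1)
    expect_equal(adjust_fdr(p), bh_oracle(p), tolerance = 1e-15)
  }
  p <- c(0.01, NA, 0.04, NaN, 0.2)
  q <- adjust_fdr(p)
  expect_true(all(is.na(q[c(2, 4)])))
  expect_equal(q[!is.na(p)], bh_oracle(p[!is.na(p)]))
  # invariant under permutation of input order
  set.seed(4)
  p2 <- runif(30)
  o <- sample(30)
  expect_equal(adjust_fdr(p2)[o], adjust_fdr(p2[o]))
  # ranks never decrease
  expect_true(all(diff(adjust_fdr(sort(p2))) >= -1e-15))
})

test_that("Spearman rho equals the mid-rank Pearson oracle", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(30, 20, 10))$rho, -1)
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- sample(1:8, n, replace = TRUE)
    r <- spearman_cor(x, y)
    if (is.na(r$rho)) { expect_true(sd(x) == 0 || sd(y) == 0); next }
    expect_equal(r$rho, spearman_oracle(x, y), tolerance = 1e-12)
  }
  expect_true(is.na(spearman_cor(rep(1, 6), 1:6)$rho))
})

test_that("Spearman p-values: exact enumeration small n, t approximation after", {
  # tie-free small samples: cross-check against the exact reference
  set.seed(21)
  for (rep in 1:5) {
    x <- sample(1:7); y <- sample(1:7)
    r <- spearman_cor(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(r$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(r$p_value, ref$p.value, tolerance = 0.02)
  }
  # t approximation for larger n
  set.seed(22)
  x <- rnorm(30); y <- x + rnorm(30)
  r <- spearman_cor(x, y)
  tstat <- r$rho * sqrt((30 - 2) / (1 - r$rho^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), 28), tolerance = 1e-12)
})

test_that("t-test wrapper: identity, shift, antisymmetry, degenerate input", {
  same <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  shift <- students_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$p_value, 0.01)
  ref <- t.test(c(1, 2, 3), c(11, 12, 13))
  expect_equal(shift$t, unname(ref$statistic))
  expect_equal(shift$p_value, ref$p.value)
  swapped <- students_t(c(11, 12, 13), c(1, 2, 3))
  expect_equal(swapped$t, -shift$t)
  expect_equal(swapped$p_value, shift$p_value)
  flat <- students_t(c(2, 2), c(2, 2))
  expect_equal(flat$t, 0); expect_equal(flat$p_value, 1)
  pooled <- students_t(c(1, 2, 3), c(2, 3, 5), pooled = TRUE)
  refp <- t.test(c(1, 2, 3), c(2, 3, 5), var.equal = TRUE)
  expect_equal(pooled$p_value, refp$p.value)
})

test_that("overall editing level: mean of defined sites plus pooled variant", {
  m <- mk_mat(matrix(c(0L, 0L, 2L, 6L), 2, 2), matrix(20L, 2, 2))
  ov <- overall_editing_level(m)
  expect_equal(ov$mean_level, c(0, 0.2))
  expect_equal(ov$pooled_level, c(0, 8 / 40))
  m2 <- mk_mat(matrix(c(2L, 6L), 2, 1), matrix(c(20L, 20L), 2, 1))
  expect_equal(overall_editing_level(m2)$mean_level, 0.2)
})

test_that("PCA matches the covariance eigendecomposition oracle", {
  # only one site varies -> PC1 carries everything
  e <- matrix(c(1L, 5L, 10L, 5L, 20L, 5L), 2, 3)
  t <- matrix(100L, 2, 3)
  p1 <- pca_editing(mk_mat(e, t))
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-9)

  set.seed(31)
  for (rep in 1:5) {
    L <- matrix(runif(200), 20, 10)
    tot <- matrix(1000L, 20, 10)
    ed <- round(L * tot)
    m <- mk_mat(ed, tot)
    pc <- pca_editing(m)
    orc <- pca_oracle(m$levels)
    k <- min(9, ncol(pc$scores))
    for (j in seq_len(k)) {
      a <- pc$scores[, j]; b <- orc$scores[, j]
      expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
    }
    vf <- pc$variance_fraction
    expect_lte(sum(vf), 1 + 1e-9)
    expect_equal(vf[seq_len(k)],
                 (orc$values / sum(orc$values))[seq_len(k)],
                 tolerance = 1e-8)
    # components with non-trivial variance are mutually orthogonal
    S <- pc$scores[, seq_len(k)]
    G <- crossprod(scale(S, center = FALSE, scale = sqrt(colSums(S^2))))
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  }

  # masked cells are mean-imputed; all-NA sites dropped with a message
  e2 <- matrix(c(1L, 0L, 10L, 0L, 20L, 0L, 3L, 0L), 2, 4)
  t2 <- matrix(c(100L, 5L, 100L, 5L, 100L, 5L, 100L, 5L), 2, 4)
  expect_message(p2 <- pca_editing(mk_mat(rbind(e2, e2[1, ]),
                                          rbind(t2, t2[1, ]))),
                 "dropping 1 site")
})

test_that("set overlaps equal brute-force powerset enumeration", {
  ov <- overlap_sets(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(unname(ov$regions["A&B"]), 1L)
  expect_equal(unname(ov$regions["A"]), 1L)
  expect_equal(unname(ov$regions["B"]), 1L)
  expect_equal(ov$unique$A, "a")

  idsets <- list(X = c("u", "v"), Y = c("u", "v"))
  ov2 <- overlap_sets(idsets)
  expect_equal(unname(ov2$regions["X&Y"]), 2L)
  expect_equal(unname(ov2$regions["X"]), 0L)

  set.seed(41)
  sets <- lapply(1:4, function(i) sample(letters, sample(5:20, 1)))
  names(sets) <- LETTERS[1:4]
  ov4 <- overlap_sets(sets)
  # brute force: classify every element by its exact membership pattern
  for (el in unique(unlist(sets))) {
    pat <- paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
                 collapse = "&")
    expect_true(ov4$regions[pat] >= 1L)
  }
  expect_equal(sum(ov4$regions), length(unique(unlist(sets))))
  brute_at_least <- vapply(1:4, function(k)
    sum(vapply(unique(unlist(sets)), function(el)
      sum(vapply(sets, function(s) el %in% s, logical(1))) >= k,
      logical(1))), integer(1))
  expect_equal(unname(ov4$at_least), brute_at_least)
})

test_that("editing-expression correlation recovers construction and nulls", {
  set.seed(51)
  n <- 12
  tpm <- matrix(seq(10, 120, length.out = n), 1, n,
                dimnames = list("gene1", paste0("s", 1:n)))
  lev <- matrix(plogis(seq(-2, 1, length.out = n)), 1, n)
  tot <- matrix(100L, 1, n)
  m <- mk_mat(round(lev * 100), tot)
  s2g <- data.frame(site_id = "site1", gene_id = "gene1")
  r <- editing_expression_correlation(m, tpm, s2g, verbose = FALSE)
  expect_equal(r$rho, 1)

  # constant editing level -> undefined, excluded
  mconst <- mk_mat(matrix(10L, 1, n), tot)
  rc <- editing_expression_correlation(mconst, tpm, s2g, verbose = FALSE)
  expect_true(is.na(rc$rho))

  # unknown host gene skipped with a log line
  expect_message(
    r2 <- editing_expression_correlation(m, tpm,
                                         data.frame(site_id = "site1",
                                                    gene_id = "nope"),
                                         verbose = TRUE),
    "absent")
  expect_equal(nrow(r2), 0L)

  # permuted sample labels: |rho| rarely significant
  set.seed(52)
  x <- rnorm(n); y <- rnorm(n)
  hits <- 0L
  for (i in 1:100) {
    sc <- spearman_cor(x, sample(y))
    if (sc$p_value < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 10L)
})

test_that("graded ADAR activity is recovered by the overall editing level", {
  # count-level fixture: 60 sites, 12 samples with a graded activity ramp
  set.seed(61)
  act <- seq(0.3, 1, length.out = 12)
  base <- rbeta(60, 2, 5)
  lv <- pmin(outer(base, act), 1)
  cnt <- simulate_editing_counts(lv, coverage = 40, seed = 61L)
  m <- editing_matrix(cnt$edited, cnt$total)
  ov <- overall_editing_level(m)
  expect_gt(spearman_cor(ov$mean_level, act)$rho, 0.7)
})

test_that("planted group shifts are recovered with controlled error", {
  set.seed(71)
  n_sites <- 600; n_shift <- 60
  lv <- matrix(0.1, n_sites, 6)
  lv[seq_len(n_shift), 4:6] <- 0.3
  cnt <- simulate_editing_counts(lv, coverage = 50, seed = 71L)
  m <- editing_matrix(cnt$edited, cnt$total)
  res <- lrt_differential(m, groups = rep(c("a", "b"), each = 3))
  des <- which(res$q_value < 0.05)
  recovered <- mean(seq_len(n_shift) %in% des)
  fp <- sum(des > n_shift) / (n_sites - n_shift)
  expect_gte(recovered, 0.8)
  expect_lte(fp, 0.05)
})
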