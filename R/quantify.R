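#' Editing level: edited-read fraction
#'
#' @param edited_count,total_count non-negative integer vectors.
#' @return `edited / total`, with `NA` where `total_count` is zero.
#' @export
#' @examples
#' editing_level(3, 10)
editing_level <- function(edited_count, total_count) {
  if (any(total_count < 0) || any(edited_count < 0))
    stop("data-integrity error: negative read counts", call. = FALSE)
  if (any(edited_count > total_count))
    stop("data-integrity error: edited_count exceeds total_count", call. = FALSE)
  ifelse(total_count == 0, NA_real_, edited_count / total_count)
}

#' Sites-by-samples editing matrix with coverage mask
#'
#' The central container for editing-level statistics: per-site, per-sample
#' edited and total read counts, the derived level matrix, and a coverage
#' mask marking cells with at least `min_depth` qualifying reads. Masked
#' cells are excluded from every downstream statistic.
#'
#' @param edited,total integer matrices (sites x samples, same dimnames).
#' @param sites data.frame of site metadata (chrom, pos, ...), one row per
#'   matrix row.
#' @param sample_ids character vector of sample names (matrix columns).
#' @param groups optional group label per sample.
#' @param min_depth coverage below which a cell is masked.
#' @return an object of class `editing_matrix`.
#' @export
editing_matrix <- function(edited, total, sites = NULL,
                           sample_ids = colnames(edited), groups = NULL,
                           min_depth = 10L) {
  stopifnot(all(dim(edited) == dim(total)))
  if (any(edited > total))
    stop("data-integrity error: edited count exceeds total", call. = FALSE)
  mask <- total >= min_depth
  levels <- matrix(NA_real_, nrow(edited), ncol(edited),
                   dimnames = dimnames(edited))
  levels[mask] <- edited[mask] / total[mask]
  structure(list(edited = edited, total = total, levels = levels,
                 mask = mask,
                 sites = if (is.null(sites))
                   data.table(site_id = rownames(edited) %||%
                                as.character(seq_len(nrow(edited))))
                 else as.data.table(sites),
                 sample_ids = sample_ids %||% as.character(seq_len(ncol(edited))),
                 groups = groups, min_depth = as.integer(min_depth)),
            class = "editing_matrix")
}

#' @export
print.editing_matrix <- function(x, ...) {
  cat(sprintf("editing_matrix: %d sites x %d samples (%.1f%% cells covered)\n",
              nrow(x$levels), ncol(x$levels), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.editing_matrix <- function(x) dim(x$levels)

#' Transcripts-per-million from per-gene counts
#'
#' `rate_g = count_g / (length_g / 1000)`; `TPM_g = rate_g / sum(rate) * 1e6`.
#' Gene length is the union of exonic bases, matching how reads are counted.
#'
#' @param counts gene x sample matrix (or vector) of read counts.
#' @param lengths per-gene exonic lengths in bases (named or positional).
#' @return matrix of TPM values; every column sums to 1e6 (zero-count
#'   columns, warned about, stay zero).
#' @export
#' @examples
#' compute_tpm(c(g1 = 10, g2 = 20), c(g1 = 1000, g2 = 2000))
compute_tpm <- function(counts, lengths) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1,
                                          dimnames = list(names(counts), "s1"))
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0) || anyNA(lengths))
    stop("gene lengths must be positive for every counted gene", call. = FALSE)
  rate <- counts / (lengths / 1000)
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("sample(s) %s have zero total counts; TPM column left zero",
                    paste(colnames(counts)[zero], collapse = ", ")))
    totals[zero] <- 1
  }
  sweep(rate, 2, totals, "/") * 1e6
}
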