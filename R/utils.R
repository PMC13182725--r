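# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom data.table data.table as.data.table setkey setkeyv rbindlist
#' @importFrom data.table fwrite fread setorder setnames := .N .SD
NULL

# quiet R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", "..keep", "aaf", "alen", "alt", "alt_depth", "base", "chrom", "class_",
  "count", "depth", "dist3", "dist5", "edited", "end", "gene_id", "level",
  "n_alt", "pos", "qual", "read_id", "ref", "sample_id", "start", "strand",
  "total", "op", "len", "width", "exon_rank", "tx_start", "tx_end", "qwidth",
  "site_id", "region", "failed_rule", "status", "i.strand", "keep"
))

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

# write a tab-separated table with a '#'-prefixed provenance comment and header
write_pipeline_tsv <- function(x, path, provenance = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_pipeline_tsv <- function(path) {
  data.table::as.data.table(
    utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE)
  )
}

# deterministic sub-seed derivation: keeps every stream below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
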