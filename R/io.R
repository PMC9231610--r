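# Plain-text I/O for the pipeline's tabular artifacts.

#' Write a genes x samples count matrix as TSV
#'
#' First column `gene`, then one column per sample.
#' @param counts Matrix with gene rownames and sample colnames.
#' @param path Output file.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples count matrix from TSV
#' @param path File written by [write_counts_tsv()].
#' @return Numeric matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a count matrix in MatrixMarket format (with sidecar row/col names)
#'
#' @param counts Matrix.
#' @param path Output `.mtx` file; `<path>.rownames` and `<path>.colnames`
#'   are written alongside.
#' @export
write_counts_mtx <- function(counts, path) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  writeLines(rownames(counts), paste0(path, ".rownames"))
  writeLines(colnames(counts), paste0(path, ".colnames"))
  invisible(path)
}

#' Read a count matrix written by [write_counts_mtx()]
#' @param path The `.mtx` file.
#' @return Dense numeric matrix with dimnames restored.
#' @export
read_counts_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  rn <- paste0(path, ".rownames"); cn <- paste0(path, ".colnames")
  if (file.exists(rn)) rownames(m) <- readLines(rn)
  if (file.exists(cn)) colnames(m) <- readLines(cn)
  m
}

#' Write a marker set as two-column TSV plus a stats TSV
#' @param m A `marker_set`.
#' @param path Output TSV (subclass, gene); stats are written to
#'   `<path-sans-ext>_stats.tsv`.
#' @export
write_markers_tsv <- function(m, path) {
  stopifnot(inherits(m, "marker_set"))
  df <- data.frame(subclass = rep(names(m$markers), lengths(m$markers)),
                   gene = unlist(m$markers, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  stats_path <- sub("\\.tsv$", "_stats.tsv", path)
  utils::write.table(m$stats, stats_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write rCTP scores as TSV with a JSON sidecar
#'
#' The sidecar records the markers used and PC1 variance explained per
#' subclass.
#' @param rctp An `rctp` object.
#' @param path Output TSV; the sidecar goes to `<path>.json`.
#' @export
write_rctp_tsv <- function(rctp, path) {
  stopifnot(inherits(rctp, "rctp"))
  df <- data.frame(sample_id = rownames(rctp$scores), rctp$scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(variance_explained = as.list(rctp$variance_explained),
         markers_used = rctp$markers_used,
         failed = as.list(rctp$failed)),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
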