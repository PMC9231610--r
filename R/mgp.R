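# Marker-gene-profile deconvolution: relative cell-type proportions (rCTPs)
# as the first principal component of a subclass's marker-gene expression.

#' Estimate a relative proportion score from marker genes
#'
#' Subsets the expression matrix to the marker genes (markers absent from
#' the matrix are dropped silently, mirroring cross-dataset harmonization;
#' fewer than 3 surviving markers is an error), z-scores each marker across
#' samples, and extracts the first principal component via singular value
#' decomposition. Sign convention: if the sum of PC1 loadings is negative,
#' scores and loadings are negated, so a higher score always means higher
#' average marker expression ("more of that cell type"). Zero-variance
#' markers are dropped with a warning before the PCA.
#'
#' @param log_expr Genes x samples expression matrix (normalized scale).
#' @param markers Character vector of marker gene ids.
#' @param subclass Optional label used in error messages.
#' @return A list with `scores` (named per-sample vector, PC1 scores),
#'   `variance_explained` (fraction of marker variance on PC1), `loadings`
#'   (named per-marker vector), and `markers_used`.
#' @export
estimate_rctp <- function(log_expr, markers, subclass = "subclass") {
  stopifnot(is.matrix(log_expr))
  if (ncol(log_expr) < 4) stop("need at least 4 samples")
  present <- markers[markers %in% rownames(log_expr)]
  X <- t(log_expr[present, , drop = FALSE])   # samples x markers
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance marker(s): ",
            paste(present[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    present <- present[sds > 0]
  }
  if (length(present) < 3)
    stop("fewer than 3 usable markers for ", subclass)
  Xs <- scale(X)
  sv <- svd(Xs)
  scores <- sv$u[, 1] * sv$d[1]
  loadings <- sv$v[, 1]
  if (sum(loadings) < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  names(scores) <- colnames(log_expr)
  names(loadings) <- present
  list(scores = scores,
       variance_explained = sv$d[1]^2 / sum(sv$d^2),
       loadings = loadings,
       markers_used = present)
}

#' Estimate rCTPs for every subclass in a dataset
#'
#' Applies [estimate_rctp()] per subclass using a harmonized marker set,
#' then z-scores each subclass column within the dataset. Per-subclass
#' failures (e.g., too few markers post-QC) do not abort the others; failed
#' subclasses are reported in the result's `failed` manifest.
#'
#' @param log_expr Genes x samples expression matrix.
#' @param marker_set A `marker_set` (ideally harmonized against this
#'   dataset's QC-passing genes).
#' @return An `rctp` object: list with `scores` (samples x subclasses,
#'   z-scored columns), `variance_explained`, `markers_used`, `loadings`,
#'   and `failed` (named character vector of error messages, possibly
#'   empty).
#' @export
estimate_all <- function(log_expr, marker_set) {
  stopifnot(inherits(marker_set, "marker_set"))
  subclasses <- names(marker_set$markers)
  fits <- lapply(subclasses, function(k)
    tryCatch(estimate_rctp(log_expr, marker_set$markers[[k]], subclass = k),
             error = function(e) e))
  names(fits) <- subclasses
  ok <- !vapply(fits, inherits, logical(1), what = "error")
  if (!any(ok)) stop("rCTP estimation failed for every subclass")
  scores <- vapply(fits[ok], function(f) f$scores, numeric(ncol(log_expr)))
  scores <- scale(scores)
  attr(scores, "scaled:center") <- NULL
  attr(scores, "scaled:scale") <- NULL
  rownames(scores) <- colnames(log_expr)
  structure(list(
    scores = scores,
    variance_explained = vapply(fits[ok], `[[`, numeric(1), "variance_explained"),
    markers_used = lapply(fits[ok], `[[`, "markers_used"),
    loadings = lapply(fits[ok], `[[`, "loadings"),
    failed = vapply(fits[!ok], conditionMessage, character(1))),
    class = "rctp")
}

#' @export
print.rctp <- function(x, ...) {
  cat(sprintf("rCTP matrix: %d samples x %d subclasses (PC1 variance explained %.2f-%.2f)\n",
              nrow(x$scores), ncol(x$scores),
              min(x$variance_explained), max(x$variance_explained)))
  if (length(x$failed))
    cat("  failed subclasses:", paste(names(x$failed), collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-marker-out rCTP score
#'
#' Re-estimates a subclass score with one marker gene excluded, for
#' assessing robustness of the score to any single marker (e.g., the
#' subclass's namesake transcript).
#'
#' @inheritParams estimate_rctp
#' @param excluded_gene Gene id to drop; must be in `markers`.
#' @return As [estimate_rctp()].
#' @export
leave_one_marker_out <- function(log_expr, markers, excluded_gene,
                                 subclass = "subclass") {
  if (!excluded_gene %in% markers)
    stop("excluded_gene is not in the marker list")
  estimate_rctp(log_expr, setdiff(markers, excluded_gene), subclass = subclass)
}
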