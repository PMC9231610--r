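# Subclass marker derivation from a labeled single-nucleus reference.

cpm <- function(counts) {
  sweep(counts, 2, colSums(counts), "/") * 1e6
}

#' Select subclass-specific marker genes
#'
#' For each subclass, retains genes whose mean CPM in the subclass exceeds
#' `fold_threshold` times the *maximum* mean CPM over every other subclass
#' (plus a 1-CPM pseudocount), and which are detected (count > 0) in at
#' least `min_detect` of in-type nuclei. Genes are ranked by fold enrichment
#' and the top `top_n` kept. A gene qualifying for more than one subclass is
#' assigned to none, so the final assignment is a partial function
#' gene -> subclass. Using the maximum (not mean) out-type expression makes
#' the statistic robust to a single confusable sibling subclass, the failure
#' mode that matters at subclass resolution.
#'
#' @param counts Genes x nuclei count matrix with gene rownames.
#' @param labels Subclass label per nucleus (length = ncol(counts)).
#' @param fold_threshold Minimum fold enrichment (default 4).
#' @param min_detect Minimum in-type detection fraction (default 0.3).
#' @param top_n Maximum markers per subclass (default 50).
#' @param pseudocount CPM pseudocount in the enrichment denominator
#'   (default 1; penalizes low-expression "markers").
#' @return A `marker_set`: list with `markers` (subclass -> ordered gene
#'   vector) and `stats` (per subclass x candidate gene: in-type mean CPM,
#'   max out-type mean CPM, fold enrichment, detection fraction).
#' @export
select_markers <- function(counts, labels, fold_threshold = 4,
                           min_detect = 0.3, top_n = 50, pseudocount = 1) {
  stopifnot(is.matrix(counts), length(labels) == ncol(counts))
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (fold_threshold < 1) stop("fold_threshold must be >= 1")
  tab <- table(labels)
  empty <- setdiff(unique(labels), names(tab[tab > 0]))
  if (length(empty))
    warning("subclasses with zero nuclei excluded: ",
            paste(empty, collapse = ", "))
  subclasses <- names(tab[tab > 0])
  if (length(subclasses) < 2) stop("need at least 2 subclasses with nuclei")
  x <- cpm(counts)
  means <- vapply(subclasses,
                  function(k) rowMeans(x[, labels == k, drop = FALSE]),
                  numeric(nrow(x)))
  detect <- vapply(subclasses,
                   function(k) rowMeans(counts[, labels == k, drop = FALSE] > 0),
                   numeric(nrow(x)))
  genes <- rownames(counts)
  per_class <- lapply(seq_along(subclasses), function(j) {
    in_mean <- means[, j]
    out_max <- apply(means[, -j, drop = FALSE], 1, max)
    fold <- in_mean / (out_max + pseudocount)
    pass <- fold >= fold_threshold & detect[, j] >= min_detect
    d <- data.frame(subclass = subclasses[j], gene = genes,
                    in_mean = in_mean, out_max = out_max, fold = fold,
                    detect = detect[, j], stringsAsFactors = FALSE)[pass, ]
    d[order(-d$fold), , drop = FALSE]
  })
  stats <- do.call(rbind, c(per_class, make.row.names = FALSE))
  # exclusivity: drop genes qualifying for more than one subclass
  dup <- unique(stats$gene[duplicated(stats$gene)])
  stats <- stats[!stats$gene %in% dup, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(stats)), stats$subclass), utils::head,
                        n = top_n), use.names = FALSE)
  stats <- stats[sort(keep), , drop = FALSE]
  markers <- lapply(stats_split <- split(stats, stats$subclass),
                    function(d) d$gene[order(-d$fold)])
  failed <- setdiff(subclasses, names(markers)[lengths(markers) > 0])
  if (length(failed))
    stop("no markers selected for subclass(es): ",
         paste(sort(failed), collapse = ", "))
  markers <- markers[subclasses]
  structure(list(markers = markers, stats = stats,
                 params = list(fold_threshold = fold_threshold,
                               min_detect = min_detect, top_n = top_n,
                               pseudocount = pseudocount)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  n <- lengths(x$markers)
  cat(sprintf("Marker set: %d subclasses, %d-%d markers each (median %d)\n",
              length(n), min(n), max(n), as.integer(stats::median(n))))
  invisible(x)
}

#' Harmonize a marker set against QC-passing gene sets
#'
#' Restricts every subclass marker list to genes present in *all* supplied
#' QC gene sets (typically the post-filter gene universes of each bulk
#' dataset), so relative-proportion scores share one marker definition
#' across datasets. Order and per-gene statistics are preserved.
#'
#' @param m A `marker_set`.
#' @param qc_gene_sets Non-empty list of character vectors of gene ids.
#' @param min_markers Minimum surviving markers per subclass (default 3).
#' @return A `marker_set` restricted to the common genes.
#' @export
harmonize_markers <- function(m, qc_gene_sets, min_markers = 3) {
  stopifnot(inherits(m, "marker_set"))
  if (!is.list(qc_gene_sets) || length(qc_gene_sets) == 0)
    stop("qc_gene_sets must be a non-empty list")
  common <- Reduce(intersect, qc_gene_sets)
  out <- lapply(m$markers, function(g) g[g %in% common])
  short <- names(out)[lengths(out) < min_markers]
  if (length(short))
    stop("marker list(s) fall below ", min_markers,
         " after harmonization: ", paste(sort(short), collapse = ", "))
  m$markers <- out
  m$stats <- m$stats[m$stats$gene %in% common, , drop = FALSE]
  m
}
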