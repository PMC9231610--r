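# Bulk RNA-seq QC and normalization protocol.
#
# Fixed stage order: median-count gene filter -> MDS outlier removal ->
# per-gene winsorization on the log2 scale -> TMM normalization ->
# mean-variance observation weights -> technical-covariate removal.

#' Filter genes by median expected count
#'
#' Retains exactly the genes whose median expected count across samples is
#' strictly greater than `threshold`; a gene whose median equals the
#' threshold is removed.
#'
#' @param counts Genes x samples nonnegative matrix.
#' @param threshold Median-count cutoff (default 15).
#' @return The filtered matrix (same samples).
#' @export
filter_genes <- function(counts, threshold = 15) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  med <- apply(counts, 1, stats::median)
  keep <- med > threshold
  if (!any(keep)) stop("all genes removed by median filter")
  counts[keep, , drop = FALSE]
}

#' Detect outlier samples on an MDS embedding
#'
#' Embeds samples by classical multidimensional scaling (principal
#' coordinates of Euclidean distances on log2 CPM, equivalent to PCA on this
#' distance) and flags a sample as an outlier iff its score differs from the
#' sample median by more than `k_iqr` interquartile ranges on *any* of the
#' first `n_components` axes. Detection is a single pass; flagged samples
#' are not removed and re-tested.
#'
#' @param counts Genes x samples matrix.
#' @param n_components Number of leading components tested (default 5).
#' @param k_iqr IQR multiplier (default 3).
#' @param cpm_offset Offset added to CPM before log2 (default 1).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(counts, n_components = 5, k_iqr = 3,
                                   cpm_offset = 1) {
  stopifnot(is.matrix(counts))
  if (ncol(counts) < n_components + 1)
    stop("need at least n_components + 1 samples")
  x <- log2(cpm(counts) + cpm_offset)
  d <- stats::dist(t(x))
  if (max(d) == 0) return(character(0))
  k <- min(n_components, ncol(counts) - 1)
  mds <- suppressWarnings(stats::cmdscale(d, k = k))
  if (is.null(dim(mds)) || ncol(mds) == 0) return(character(0))
  flagged <- rep(FALSE, ncol(counts))
  for (j in seq_len(ncol(mds))) {
    sc <- mds[, j]
    band <- k_iqr * stats::IQR(sc)
    flagged <- flagged | abs(sc - stats::median(sc)) > band
  }
  colnames(counts)[flagged]
}

#' Winsorize counts on the log2 scale, per gene
#'
#' Transforms each count to `log2(count + offset)`, clamps values differing
#' from the gene's median (across samples) by more than `k_iqr` interquartile
#' ranges to the nearest band edge, and transforms back with `2^x - offset`
#' (clamped at 0). Values already inside the band are returned bit-for-bit
#' unchanged; a gene with zero IQR collapses to its median value.
#'
#' @param counts Genes x samples nonnegative matrix.
#' @param offset Log2 offset (default 0.5).
#' @param k_iqr IQR multiplier (default 3).
#' @return Winsorized matrix on the expected-count scale.
#' @export
winsorize_log2 <- function(counts, offset = 0.5, k_iqr = 3) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  x <- log2(counts + offset)
  med <- apply(x, 1, stats::median)
  iqr <- apply(x, 1, stats::IQR)
  lo <- med - k_iqr * iqr
  hi <- med + k_iqr * iqr
  out_lo <- x < lo
  out_hi <- x > hi
  res <- counts
  if (any(out_lo)) {
    v <- pmax(2^(lo[row(x)[out_lo]]) - offset, 0)
    res[out_lo] <- v
  }
  if (any(out_hi)) {
    res[out_hi] <- pmax(2^(hi[row(x)[out_hi]]) - offset, 0)
  }
  res
}

# Single-pair TMM factor: trimmed, precision-weighted mean of gene-wise
# log2 expression ratios (M) against the reference, double-trimmed on M and
# on average log2 abundance (A), weights = inverse asymptotic binomial
# variance.
tmm_pair <- function(obs, ref, trim_M, trim_A, do_weighting = TRUE,
                     a_cutoff = -1e10) {
  nO <- sum(obs); nR <- sum(ref)
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > a_cutoff)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0) stop("sample shares no positive genes with reference")
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_M) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trim_A) + 1; hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
    (rank(absE) >= loS & rank(absE) <= hiS)
  f <- if (do_weighting)
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  else mean(logR[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes per-sample TMM scale factors: the reference sample is the one
#' whose upper-quartile/library-size ratio is closest to the mean of those
#' ratios; each sample's factor is the inverse-variance-weighted mean of
#' gene-wise log2 expression ratios against the reference after double
#' trimming (`trim_M` on the log-ratios, `trim_A` on average log2
#' abundance), and factors are rescaled to geometric mean 1.
#'
#' @param counts Genes x samples matrix with positive library sizes.
#' @param trim_M Fraction trimmed from each tail of the M values (default 0.3).
#' @param trim_A Fraction trimmed from each tail of the A values (default 0.05).
#' @return Named numeric vector of factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  stopifnot(is.matrix(counts))
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample must have a positive library size")
  f75 <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(tmm_pair(counts[, j], counts[, ref], trim_M, trim_A))
    tryCatch(tmm_pair(counts[, j], counts[, ref], trim_M, trim_A),
             error = function(e)
               stop("TMM failed for sample ", colnames(counts)[j], ": ",
                    conditionMessage(e)))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Mean-variance observation-level precision weights
#'
#' Fits (per gene) the supplied linear design, regresses sqrt(residual SD)
#' on mean log2 expression with lowess, and inverts the trend predicted at
#' each observation's fitted value to a precision weight (trend^-4). With
#' fewer than 10 genes the smoother is unreliable and unit weights are
#' returned with a warning.
#'
#' @param log_expr Genes x samples log2-expression matrix.
#' @param design Optional samples x covariates model matrix (default:
#'   intercept only).
#' @param span Lowess span (default 0.5).
#' @return Matrix of positive weights, same dimensions as `log_expr`.
#' @export
observation_weights <- function(log_expr, design = NULL, span = 0.5) {
  stopifnot(is.matrix(log_expr))
  n <- ncol(log_expr)
  if (is.null(design)) design <- matrix(1, n, 1)
  if (nrow(log_expr) < 10) {
    warning("fewer than 10 genes; returning unit weights")
    return(matrix(1, nrow(log_expr), n, dimnames = dimnames(log_expr)))
  }
  fit <- stats::lm.fit(design, t(log_expr))
  fitted <- t(fit$fitted.values)
  df_resid <- n - fit$rank
  sd_g <- sqrt(rowSums(t(fit$residuals)^2) / max(df_resid, 1))
  mean_g <- rowMeans(log_expr)
  lo <- stats::lowess(mean_g, sqrt(sd_g), f = span)
  trend <- stats::approx(lo$x, lo$y, xout = as.vector(fitted), rule = 2)$y
  trend <- pmax(trend, 1e-4)
  w <- matrix(trend^-4, nrow(log_expr), n, dimnames = dimnames(log_expr))
  w
}

# Expand technical covariates into a full-rank numeric matrix: numeric
# columns are kept as-is (centered), factors/characters get sum-to-zero
# contrasts.
expand_covariates <- function(covariates) {
  stopifnot(is.data.frame(covariates))
  blocks <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v - mean(v), ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2) return(NULL)
      m <- stats::model.matrix(~f, contrasts.arg = list(f = "contr.sum"))[, -1, drop = FALSE]
      colnames(m) <- paste0(nm, seq_len(ncol(m)))
    }
    m
  })
  do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
}

#' Remove technical covariate effects from a log-expression matrix
#'
#' Fits, per gene, a weighted least-squares model of expression on an
#' intercept plus the technical covariates and subtracts the fitted
#' technical component (the intercept is retained). Categorical covariates
#' are expanded to sum-to-zero contrasts so the grand mean is preserved.
#' Implemented via `limma::removeBatchEffect`.
#'
#' @param log_expr Genes x samples matrix.
#' @param covariates Data frame of per-sample technical covariates (numeric
#'   and/or categorical), rows aligned with samples.
#' @param weights Optional observation weight matrix (as from
#'   [observation_weights()]).
#' @return Residualized matrix, same dimensions.
#' @export
remove_technical <- function(log_expr, covariates, weights = NULL) {
  stopifnot(is.matrix(log_expr), nrow(covariates) == ncol(log_expr))
  X <- expand_covariates(covariates)
  if (is.null(X) || ncol(X) == 0) return(log_expr)
  full <- cbind(1, X)
  qrx <- qr(full)
  if (qrx$rank < ncol(full)) {
    bad <- colnames(full)[qrx$pivot[(qrx$rank + 1):ncol(full)]]
    stop("technical covariate design is rank-deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  limma::removeBatchEffect(log_expr, covariates = X, weights = weights,
                           design = matrix(1, ncol(log_expr), 1))
}

#' Run the full bulk preprocessing protocol on one dataset
#'
#' Applies, in fixed order: median-count gene filtering, MDS outlier-sample
#' removal, per-gene log2 winsorization, TMM normalization, observation
#' weights, and technical-covariate removal. Returns log2 expression on the
#' TMM-normalized CPM scale with the technical component removed.
#'
#' @param counts Genes x samples expected-count matrix.
#' @param covariates Data frame of technical covariates per sample (e.g.,
#'   batch, RIN, PMI, percent mapped/usable bases), rows aligned with
#'   samples.
#' @param median_threshold Gene filter cutoff (default 15).
#' @param n_components,k_iqr Outlier-detection parameters.
#' @param winsor_offset Winsorization log2 offset (default 0.5).
#' @param cpm_offset Offset for the final log2 CPM transform (default 0.5).
#' @param span Weight-trend lowess span.
#' @return A `normalized_matrix`: list with `log_expr` (genes x retained
#'   samples), `weights`, `tmm` (factors), `dropped_samples`,
#'   `genes_removed` (count), and `qc` (a summary list suitable for JSON
#'   serialization).
#' @export
preprocess_counts <- function(counts, covariates,
                              median_threshold = 15, n_components = 5,
                              k_iqr = 3, winsor_offset = 0.5,
                              cpm_offset = 0.5, span = 0.5) {
  stopifnot(is.matrix(counts), nrow(covariates) == ncol(counts))
  n_genes_in <- nrow(counts)
  filt <- filter_genes(counts, median_threshold)
  outliers <- detect_outlier_samples(filt, n_components, k_iqr)
  keep <- !(colnames(filt) %in% outliers)
  filt <- filt[, keep, drop = FALSE]
  covariates <- covariates[keep, , drop = FALSE]
  wins <- winsorize_log2(filt, offset = winsor_offset, k_iqr = k_iqr)
  tmm <- tmm_factors(wins)
  eff_lib <- colSums(wins) * tmm
  log_expr <- log2(sweep(wins, 2, eff_lib / 1e6, "/") + cpm_offset)
  design <- cbind(1, expand_covariates(covariates))
  w <- observation_weights(log_expr, design = design, span = span)
  resid <- remove_technical(log_expr, covariates, weights = w)
  structure(list(log_expr = resid, weights = w, tmm = tmm,
                 dropped_samples = outliers,
                 genes_removed = n_genes_in - nrow(filt),
                 covariates = covariates,
                 qc = list(n_genes_in = n_genes_in,
                           n_genes_kept = nrow(filt),
                           n_samples_in = length(keep),
                           outlier_samples = outliers,
                           tmm_range = range(tmm),
                           covariates_used = names(covariates))),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("Normalized expression: %d genes x %d samples (%d genes filtered, %d outlier samples dropped)\n",
              nrow(x$log_expr), ncol(x$log_expr), x$genes_removed,
              length(x$dropped_samples)))
  invisible(x)
}
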