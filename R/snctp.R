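# Single-nucleus cell-type proportions (snCTPs) by annotated-nucleus
# counting, and bulk/single-nucleus concordance.

#' Compute single-nucleus cell-type proportions
#'
#' Counts the nuclei annotated to each subclass per subject and normalizes
#' by the subject's total QC-passing nuclei, in percent. Subjects with fewer
#' than `min_nuclei` nuclei are excluded with a warning (a floor stabilizes
#' the percentages). Subclasses absent in a subject get 0; every retained
#' row sums to 100.
#'
#' @param annotations Data frame with columns `subject_id` and `subclass`
#'   (one row per nucleus).
#' @param subclasses Optional character vector fixing the column set/order
#'   (default: subclasses observed in the data).
#' @param min_nuclei Minimum nuclei per retained subject (default 100).
#' @return An `snctp` object: list with `percents` (subjects x subclasses)
#'   and `n_nuclei` (named per-subject totals).
#' @export
compute_snctp <- function(annotations, subclasses = NULL, min_nuclei = 100) {
  stopifnot(all(c("subject_id", "subclass") %in% names(annotations)))
  if (anyNA(annotations$subject_id) || anyNA(annotations$subclass))
    stop("every nucleus must carry a subject id and a subclass label")
  totals <- table(annotations$subject_id)
  low <- names(totals)[totals < min_nuclei]
  if (length(low))
    warning("excluding ", length(low), " subject(s) below ", min_nuclei,
            " nuclei: ", paste(utils::head(low, 5), collapse = ", "),
            if (length(low) > 5) ", ..." else "")
  keep <- annotations$subject_id %in% names(totals)[totals >= min_nuclei]
  ann <- annotations[keep, , drop = FALSE]
  if (nrow(ann) == 0) stop("no subjects pass the minimum-nuclei filter")
  if (is.null(subclasses)) subclasses <- sort(unique(ann$subclass))
  tab <- table(factor(ann$subject_id),
               factor(ann$subclass, levels = subclasses))
  pct <- 100 * sweep(unclass(tab), 1, rowSums(tab), "/")
  structure(list(percents = pct,
                 n_nuclei = stats::setNames(as.integer(rowSums(tab)),
                                            rownames(tab))),
            class = "snctp")
}

#' @export
print.snctp <- function(x, ...) {
  cat(sprintf("snCTP matrix: %d subjects x %d subclasses (median %d nuclei/subject)\n",
              nrow(x$percents), ncol(x$percents),
              as.integer(stats::median(x$n_nuclei))))
  invisible(x)
}

#' Bulk / single-nucleus concordance
#'
#' Two complementary concordance summaries: (i) per-subclass Spearman rank
#' correlation between bulk rCTP scores and snCTP percentages across the
#' subjects present in both; (ii) if per-subclass standardized AD effect
#' vectors from the bulk and single-nucleus analyses are supplied, their
#' overall Spearman correlation.
#'
#' @param rctp_scores Subjects x subclasses matrix of bulk rCTP scores
#'   (rownames = subject ids).
#' @param sn An `snctp` object (or subjects x subclasses percent matrix).
#' @param effects_bulk,effects_sn Optional named per-subclass standardized
#'   beta vectors from the two AD analyses.
#' @return A list with `per_subclass` (data frame: subclass, rho,
#'   n_subjects) and `effect_rho` (scalar or NA).
#' @export
bulk_sn_concordance <- function(rctp_scores, sn,
                                effects_bulk = NULL, effects_sn = NULL) {
  pct <- if (inherits(sn, "snctp")) sn$percents else sn
  common <- intersect(rownames(rctp_scores), rownames(pct))
  per_subclass <- NULL
  if (length(common) >= 5) {
    shared <- intersect(colnames(rctp_scores), colnames(pct))
    per_subclass <- data.frame(
      subclass = shared,
      rho = vapply(shared, function(k)
        stats::cor(rctp_scores[common, k], pct[common, k],
                   method = "spearman"), numeric(1)),
      n_subjects = length(common),
      stringsAsFactors = FALSE)
    rownames(per_subclass) <- NULL
  } else if (is.null(effects_bulk)) {
    stop("fewer than 5 overlapping subjects and no effect vectors supplied")
  }
  effect_rho <- NA_real_
  if (!is.null(effects_bulk) && !is.null(effects_sn)) {
    shared <- intersect(names(effects_bulk), names(effects_sn))
    if (length(shared) < 3) stop("effect vectors share fewer than 3 subclasses")
    effect_rho <- stats::cor(effects_bulk[shared], effects_sn[shared],
                             method = "spearman")
  }
  list(per_subclass = per_subclass, effect_rho = effect_rho)
}

#' Within-cell-type expression model
#'
#' Tests whether a gene's expression *within* an annotated subclass differs
#' by AD status over and above the subclass's proportion difference:
#' nucleus-level expression is aggregated to subject-level pseudobulk means
#' (nuclei are not independent within subject), z-scored, and regressed on
#' AD status with the subclass's snCTP as covariate.
#'
#' @param nucleus_expr Named numeric vector: the gene's expression per
#'   nucleus (names = nucleus ids), or a 1-row matrix.
#' @param annotations Nucleus annotation data frame (`subject_id`,
#'   `nucleus_id`, `subclass`).
#' @param subclass Subclass whose nuclei are analyzed.
#' @param ad_status Named per-subject 0/1 AD indicator.
#' @param snctp_covariate Named per-subject snCTP percentage for `subclass`.
#' @return A list with `beta` (standardized), `se`, `p`, `n_subjects`.
#' @export
within_type_expression_model <- function(nucleus_expr, annotations, subclass,
                                         ad_status, snctp_covariate) {
  if (is.matrix(nucleus_expr)) nucleus_expr <- nucleus_expr[1, ]
  ann <- annotations[annotations$subclass == subclass, , drop = FALSE]
  if (nrow(ann) == 0) stop("no nuclei annotated to ", subclass)
  e <- nucleus_expr[ann$nucleus_id]
  if (anyNA(e)) stop("expression missing for some ", subclass, " nuclei")
  pseudo <- tapply(e, ann$subject_id, mean)
  ids <- names(pseudo)
  ad <- ad_status[ids]
  ctp <- snctp_covariate[ids]
  ok <- !is.na(ad) & !is.na(ctp)
  pseudo <- pseudo[ok]; ad <- ad[ok]; ctp <- ctp[ok]
  if (length(unique(ad)) < 2 || min(table(ad)) < 2)
    stop("need at least 2 subjects per AD group")
  fit <- stats::lm(scale(pseudo) ~ ad + scale(ctp))
  cf <- summary(fit)$coefficients["ad", ]
  list(beta = unname(cf["Estimate"]), se = unname(cf["Std. Error"]),
       p = unname(cf["Pr(>|t|)"]), n_subjects = length(pseudo))
}
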