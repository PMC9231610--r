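#' Full-scale multi-study bulk cohort design
#'
#' Bookkeeping table for the three AMP-AD bulk RNA-seq studies and six
#' neocortical regions that motivate the synthetic cohort generator: ROS/MAP
#' (dorsolateral prefrontal cortex), MSBB (four regions sampled from the same
#' individuals, so samples are not independent across regions), and the Mayo
#' Clinic temporal-cortex study. Counts are individuals passing QC, split
#' into consensus controls, AD cases, and individuals meeting neither
#' criterion.
#'
#' @return A data frame with one row per bulk dataset (study x region) and
#'   columns `dataset`, `study`, `region`, `n_total`, `n_control`, `n_case`,
#'   `n_other`, `shared_subjects` (logical; TRUE where the study re-samples
#'   the same individuals across its regions).
#' @seealso [design_totals()] for the derived sample/individual totals.
#' @export
cohort_design_full <- function() {
  d <- data.frame(
    dataset = c("DLPFC", "FP", "IFG", "PHG", "STG", "TCX"),
    study   = c("ROSMAP", "MSBB", "MSBB", "MSBB", "MSBB", "Mayo"),
    region  = c("Dorsolateral Prefrontal Cortex", "Frontal Pole",
                "Inferior Frontal Gyrus", "Parahippocampal Gyrus",
                "Superior Temporal Gyrus", "Temporal Cortex"),
    n_total   = c(1092L, 134L, 112L, 104L, 117L, 147L),
    n_control = c(138L, 44L, 34L, 38L, 35L, 67L),
    n_case    = c(285L, 90L, 78L, 66L, 82L, 80L),
    n_other   = c(669L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
  d$shared_subjects <- d$study == "MSBB"
  d
}

#' Derived totals of a multi-study design
#'
#' Computes the three bookkeeping totals used to sanity-check a design table:
#' the number of case/control samples entering the mega-analysis (summing
#' controls + AD cases over every dataset row, counting repeated-region
#' samples from the same individual separately), the number of distinct
#' individuals (each study with shared subjects across regions contributes
#' its largest regional count once), and the number of distinct individuals
#' meeting consensus case or control criteria.
#'
#' @param design A design data frame as returned by [cohort_design_full()].
#' @return A list with elements `n_samples_case_control`, `n_individuals`,
#'   and `n_individuals_case_control`.
#' @export
#' @examples
#' design_totals(cohort_design_full())
design_totals <- function(design) {
  stopifnot(all(c("study", "n_total", "n_control", "n_case", "shared_subjects")
                %in% names(design)))
  n_cc_samples <- sum(design$n_control + design$n_case)
  per_study <- split(design, design$study)
  one_study <- function(s, col) {
    # shared-subject studies re-sample the same individuals per region; the
    # largest regional count covers the distinct-individual set
    if (any(s$shared_subjects)) max(s[[col]]) else sum(s[[col]])
  }
  n_ind <- sum(vapply(per_study, one_study, numeric(1), col = "n_total"))
  n_ind_cc <- sum(vapply(per_study, function(s) {
    if (any(s$shared_subjects)) max(s$n_control + s$n_case)
    else sum(s$n_control + s$n_case)
  }, numeric(1)))
  list(n_samples_case_control = as.integer(n_cc_samples),
       n_individuals = as.integer(n_ind),
       n_individuals_case_control = as.integer(n_ind_cc))
}

#' Single-nucleus reference composition
#'
#' Nucleus counts of the high-depth reference atlas used to build the
#' subclass taxonomy and markers: all nuclei from cingulate gyrus and medial
#' temporal cortex, supplemented with non-neuronal nuclei from four other
#' cortical regions (non-neurons being undersampled in the two primary
#' regions).
#'
#' @return A list with `primary` (named counts for the two primary regions)
#'   and `nonneuronal_supplement` (named counts for the four supplementary
#'   regions, non-neuronal nuclei only).
#' @export
reference_composition <- function() {
  list(
    primary = c("cingulate gyrus" = 5939L, "medial temporal cortex" = 15519L),
    nonneuronal_supplement = c(visual = 502L, auditory = 742L,
                               somatosensory = 595L, motor = 781L)
  )
}

#' Desk-scale synthetic study design
#'
#' Default design for the synthetic cohort generator: three studies over six
#' neocortical regions with 400 distinct subjects in total, one study
#' (MSBB-like) sampling the same 100 subjects in four regions so that the
#' mega-analysis random intercept has repeated measures to absorb.
#'
#' @param n_subjects Total distinct subjects across studies (default 400).
#'   Allocated 55/25/20 percent to the three studies.
#' @return A `study_design` list with per-study elements `name`, `regions`,
#'   `n_control`, `n_case`, `n_other`, `shared_subjects`.
#' @export
default_study_design <- function(n_subjects = 400L) {
  stopifnot(n_subjects >= 40)
  n1 <- round(n_subjects * 0.55)
  n2 <- round(n_subjects * 0.25)
  n3 <- n_subjects - n1 - n2
  split3 <- function(n, f_ctrl, f_case) {
    nc <- round(n * f_ctrl); na <- round(n * f_case)
    c(control = nc, case = na, other = n - nc - na)
  }
  s1 <- split3(n1, 0.30, 0.45)  # ROSMAP-like: sizeable "other" stratum
  s2 <- split3(n2, 0.40, 0.60)
  s3 <- split3(n3, 0.45, 0.55)
  design <- list(
    studies = list(
      list(name = "studyA", regions = "DLPFC",
           n_control = s1[["control"]], n_case = s1[["case"]],
           n_other = s1[["other"]], shared_subjects = FALSE),
      list(name = "studyB", regions = c("FP", "IFG", "PHG", "STG"),
           n_control = s2[["control"]], n_case = s2[["case"]],
           n_other = s2[["other"]], shared_subjects = TRUE),
      list(name = "studyC", regions = "TCX",
           n_control = s3[["control"]], n_case = s3[["case"]],
           n_other = s3[["other"]], shared_subjects = FALSE)
    )
  )
  class(design) <- "study_design"
  design
}

#' @export
print.study_design <- function(x, ...) {
  cat("Multi-study bulk cohort design:\n")
  for (s in x$studies) {
    cat(sprintf("  %s: %d control / %d case / %d other, regions: %s%s\n",
                s$name, s$n_control, s$n_case, s$n_other,
                paste(s$regions, collapse = ", "),
                if (isTRUE(s$shared_subjects) && length(s$regions) > 1)
                  " (same subjects in every region)" else ""))
  }
  invisible(x)
}

design_n_subjects <- function(design) {
  sum(vapply(design$studies,
             function(s) s$n_control + s$n_case + s$n_other, numeric(1)))
}
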