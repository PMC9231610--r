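# Analysis-ready phenotype derivation: consensus AD labels, cognitive
# composites and slopes, residual cognition, global AD pathology.

#' Default consensus diagnosis rule
#'
#' Encodes the harmonized case/control definition combining neuropathology
#' (Braak stage, CERAD neuritic-plaque category) with antemortem cognition
#' (clinical cognitive diagnosis, or CDR where used). AD requires high
#' tangle and plaque burden plus cognitive impairment; control requires low
#' burden of both plus intact cognition; everything else is "other". A
#' neuropathology-only variant (for cohorts without antemortem cognition)
#' drops the cognitive arm.
#'
#' @param neuropathology_only Logical; drop the cognitive criteria.
#' @return A `diagnosis_rule` list of thresholds.
#' @export
default_diagnosis_rule <- function(neuropathology_only = FALSE) {
  structure(list(
    braak_case_min = 4, cerad_case = c("moderate", "frequent"),
    braak_control_max = 3, cerad_control = c("none", "sparse"),
    cogdx_case_min = 4, cdr_case_min = 1, cdr_control_max = 0.5,
    neuropathology_only = neuropathology_only),
    class = "diagnosis_rule")
}

#' Classify subjects as AD case, control, or other
#'
#' Applies a consensus diagnosis rule to per-subject Braak stage, CERAD
#' category, and cognition (clinical diagnosis code `cogdx` where present,
#' else CDR). The case and control regions of the rule space are disjoint;
#' any subject with a required field missing is labeled "other" with a
#' logged reason, never silently.
#'
#' @param subjects Data frame with columns `braak`, `cerad`, and (unless the
#'   rule is neuropathology-only) `cogdx` and/or `cdr`.
#' @param rule A `diagnosis_rule` (default [default_diagnosis_rule()]).
#' @return A list with `label` (factor control/AD/other per subject) and
#'   `reasons` (character; why each "other" was assigned).
#' @export
classify_ad <- function(subjects, rule = default_diagnosis_rule()) {
  stopifnot(inherits(rule, "diagnosis_rule"),
            all(c("braak", "cerad") %in% names(subjects)))
  n <- nrow(subjects)
  label <- rep("other", n)
  reasons <- rep("", n)
  braak <- subjects$braak
  cerad <- as.character(subjects$cerad)
  impaired <- intact <- rep(NA, n)
  if (!rule$neuropathology_only) {
    if ("cogdx" %in% names(subjects)) {
      impaired <- subjects$cogdx >= rule$cogdx_case_min
      intact <- subjects$cogdx < rule$cogdx_case_min
    }
    if ("cdr" %in% names(subjects)) {
      use <- is.na(impaired) & !is.na(subjects$cdr)
      impaired[use] <- subjects$cdr[use] >= rule$cdr_case_min
      intact[use] <- subjects$cdr[use] <= rule$cdr_control_max
    }
    if (all(is.na(impaired)))
      stop("rule requires cognition but neither cogdx nor cdr is present")
  } else {
    impaired <- intact <- rep(TRUE, n)
  }
  missing_req <- is.na(braak) | is.na(cerad) |
    (!rule$neuropathology_only & (is.na(impaired) | is.na(intact)))
  is_case <- !missing_req & braak >= rule$braak_case_min &
    cerad %in% rule$cerad_case & impaired
  is_ctrl <- !missing_req & braak <= rule$braak_control_max &
    cerad %in% rule$cerad_control & intact
  label[is_case] <- "AD"
  label[is_ctrl & !is_case] <- "control"
  reasons[missing_req] <- "required field missing"
  reasons[label == "other" & !missing_req] <- "mixed profile"
  list(label = factor(label, levels = c("control", "AD", "other")),
       reasons = reasons)
}

#' Population baseline reference for cognitive tests
#'
#' Means and SDs of each raw test computed once from the whole population at
#' the baseline visit, used to z-score every subsequent visit.
#'
#' @param visits Long visit table with `visit` and test columns.
#' @param test_cols Character vector of test column names.
#' @param baseline_visit Visit index defining baseline (default 1).
#' @return A list with `mean` and `sd` (named per test).
#' @export
baseline_reference <- function(visits, test_cols, baseline_visit = 1L) {
  base <- visits[visits$visit == baseline_visit, test_cols, drop = FALSE]
  list(mean = vapply(base, mean, numeric(1), na.rm = TRUE),
       sd = vapply(base, stats::sd, numeric(1), na.rm = TRUE))
}

#' Compute global cognition composites
#'
#' Z-scores each raw test against the population baseline reference,
#' averages tests within each cognitive domain, and averages the domain
#' composites into the global composite. A domain's composite is computed
#' when at least half of its tests are observed at the visit, else missing;
#' the global composite is missing only when every domain is missing.
#'
#' @param visits Long visit table (one row per subject-visit) with test
#'   columns.
#' @param domains Named character vector mapping test column -> domain.
#' @param baseline_ref A list as from [baseline_reference()].
#' @return `visits` with added columns `composite_global` and one
#'   `composite_<domain>` per domain.
#' @export
compute_global_cognition <- function(visits, domains, baseline_ref) {
  test_cols <- names(domains)
  stopifnot(all(test_cols %in% names(visits)))
  Z <- sweep(as.matrix(visits[, test_cols, drop = FALSE]), 2,
             baseline_ref$mean[test_cols], "-")
  Z <- sweep(Z, 2, baseline_ref$sd[test_cols], "/")
  dom_levels <- unique(domains)
  dom_comp <- sapply(dom_levels, function(d) {
    cols <- test_cols[domains == d]
    M <- Z[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(M))
    out <- rowMeans(M, na.rm = TRUE)
    out[n_obs < length(cols) / 2] <- NA_real_
    out
  })
  global <- rowMeans(dom_comp, na.rm = TRUE)
  global[rowSums(!is.na(dom_comp)) == 0] <- NA_real_
  visits[paste0("composite_", dom_levels)] <- as.data.frame(dom_comp)
  visits$composite_global <- global
  visits
}

#' Estimate per-subject cognitive slopes
#'
#' Fits a linear mixed model of the global composite on years-from-baseline
#' with correlated random intercepts and slopes per subject, and returns
#' each subject's slope as the fixed slope plus the empirical-Bayes random
#' slope (shrinkage stabilizes the few-visit, noisy trajectories). Subjects
#' with fewer than 2 non-missing visits receive a missing slope.
#'
#' @param visits Long table with `subject_id`, `year`, and a composite
#'   column.
#' @param composite_col Name of the composite column (default
#'   "composite_global").
#' @param min_subjects Minimum subjects required for the mixed fit.
#' @return Named numeric vector of slopes (SD units / year) per subject.
#' @export
estimate_cognitive_slope <- function(visits, composite_col = "composite_global",
                                     min_subjects = 20L) {
  stopifnot(all(c("subject_id", "year", composite_col) %in% names(visits)))
  d <- visits[!is.na(visits[[composite_col]]), , drop = FALSE]
  n_visits <- table(d$subject_id)
  eligible <- names(n_visits)[n_visits >= 2]
  if (length(eligible) < min_subjects)
    stop("fewer than ", min_subjects, " subjects with >= 2 visits")
  dd <- d[d$subject_id %in% eligible, , drop = FALSE]
  dd$y <- dd[[composite_col]]
  fit <- suppressWarnings(
    lme4::lmer(y ~ year + (year | subject_id), data = dd,
               control = lme4::lmerControl(check.conv.singular = "ignore")))
  fixed_slope <- lme4::fixef(fit)[["year"]]
  re <- lme4::ranef(fit)$subject_id
  slopes <- stats::setNames(fixed_slope + re[, "year"], rownames(re))
  all_ids <- unique(visits$subject_id)
  out <- stats::setNames(rep(NA_real_, length(all_ids)), all_ids)
  out[names(slopes)] <- slopes
  out
}

#' Residual cognition (cognitive resilience proxy)
#'
#' Ordinary least squares of global cognition proximal to death on the 11
#' neuropathology measures plus demographics (age at death, sex, years of
#' education); the residuals quantify better- or worse-than-expected
#' cognition given measured brain pathology.
#'
#' @param subjects Data frame with `cog_at_death`, the 11 pathology columns
#'   (see [pathology_measures()]), `age_at_death`, `sex`, `educ`.
#' @param pathologies Pathology column names (default
#'   [pathology_measures()]).
#' @return Named numeric vector of residuals per subject.
#' @export
compute_residual_cognition <- function(subjects,
                                       pathologies = pathology_measures()) {
  req <- c("cog_at_death", pathologies, "age_at_death", "sex", "educ")
  miss <- setdiff(req, names(subjects))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- subjects[stats::complete.cases(subjects[, req]), req, drop = FALSE]
  X <- cbind(1, as.matrix(d[, pathologies]),
             age_at_death = d$age_at_death,
             sex = as.numeric(factor(d$sex)) - 1,
             educ = d$educ)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- stats::lm.fit(X, d$cog_at_death)$residuals
  ids <- if ("subject_id" %in% names(subjects))
    subjects$subject_id[stats::complete.cases(subjects[, req])]
  else rownames(d)
  stats::setNames(res, ids)
}

#' Global AD pathology score
#'
#' The arithmetic mean of brain-wide diffuse plaques, neuritic plaques, and
#' neurofibrillary tangles; missing any of the three gives a missing score.
#' An optional square-root pre-transform of the inputs is off by default.
#'
#' @param subjects Data frame with columns `plaq_d`, `plaq_n`, `tangles`.
#' @param sqrt_transform Apply sqrt to each measure first (requires
#'   nonnegative inputs).
#' @return Numeric vector per subject (named by `subject_id` if present).
#' @export
compute_global_pathology <- function(subjects, sqrt_transform = FALSE) {
  need <- c("plaq_d", "plaq_n", "tangles")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  M <- as.matrix(subjects[, need])
  if (sqrt_transform) M <- sqrt(M)
  out <- rowMeans(M)           # NA if any component missing
  if ("subject_id" %in% names(subjects)) names(out) <- subjects$subject_id
  out
}
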