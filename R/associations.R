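# Case/control mega-analysis, single-nucleus variant, phenotype battery,
# marker-gene models, multiple-testing control, and nested-model variance
# partitioning with the 0.632+ bootstrap.

wald_p <- function(est, se) 2 * stats::pnorm(-abs(est / se))

#' Cross-cohort mega-analysis of one cell type
#'
#' Pools subject-level data across studies in a linear mixed model of the
#' z-scored rCTP on AD status with fixed effects of study, age at death,
#' and sex, and a random intercept per subject (absorbing the correlation
#' between repeated regional samples from the same individual). Fit by
#' REML; inference is a Wald z test on the AD coefficient. The outcome is
#' (re-)z-scored so the AD coefficient is a standardized beta: positive
#' means a higher rCTP in AD. A singular random-effect fit falls back to
#' ordinary least squares, flagged in the model tag.
#'
#' @param data Data frame with columns `rctp`, `ad` (0/1), `subject_id`,
#'   `study`, `age_at_death`, `sex`.
#' @param cell_type Label carried into the result.
#' @return One-row data frame: cell_type, beta, se, p, n_subjects,
#'   n_samples, model.
#' @export
mega_model <- function(data, cell_type = "cell_type") {
  req <- c("rctp", "ad", "subject_id", "study", "age_at_death", "sex")
  stopifnot(all(req %in% names(data)))
  d <- data[stats::complete.cases(data[, req]), req, drop = FALSE]
  if (length(unique(d$study)) < 2) stop("need at least 2 studies")
  d$rctp_z <- as.vector(scale(d$rctp))
  d$age_z <- as.vector(scale(d$age_at_death))
  use_lmm <- anyDuplicated(d$subject_id) > 0
  tag <- "lmm"
  if (use_lmm) {
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(rctp_z ~ ad + study + age_z + sex + (1 | subject_id),
                 data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      use_lmm <- FALSE
      tag <- "ols_singular_fallback"
    } else {
      cf <- summary(fit)$coefficients["ad", ]
      est <- cf[["Estimate"]]; se <- cf[["Std. Error"]]
    }
  } else tag <- "ols_no_repeats"
  if (!use_lmm) {
    fit <- stats::lm(rctp_z ~ ad + study + age_z + sex, data = d)
    cf <- summary(fit)$coefficients["ad", ]
    est <- cf[["Estimate"]]; se <- cf[["Std. Error"]]
  }
  data.frame(cell_type = cell_type, beta = est, se = se, p = wald_p(est, se),
             n_subjects = length(unique(d$subject_id)), n_samples = nrow(d),
             model = tag, stringsAsFactors = FALSE)
}

#' Single-nucleus AD association for one cell type
#'
#' Ordinary least squares of the z-scored snCTP on AD status, sn dataset,
#' age at death, sex, and PMI (PMI is a covariate here because, unlike the
#' bulk pipeline, nothing upstream removes it). Subject overlap across sn
#' datasets is assumed negligible, hence no random effect.
#'
#' @param data Data frame with `snctp`, `ad` (0/1), `dataset`,
#'   `age_at_death`, `sex`, `pmi`.
#' @param cell_type Label carried into the result.
#' @return One-row data frame as [mega_model()].
#' @export
sn_model <- function(data, cell_type = "cell_type") {
  req <- c("snctp", "ad", "dataset", "age_at_death", "sex", "pmi")
  stopifnot(all(req %in% names(data)))
  d <- data[stats::complete.cases(data[, req]), req, drop = FALSE]
  d$snctp_z <- as.vector(scale(d$snctp))
  d$age_z <- as.vector(scale(d$age_at_death))
  d$pmi_z <- as.vector(scale(d$pmi))
  X <- stats::model.matrix(~ ad + dataset + age_z + sex + pmi_z, data = d)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design in sn_model")
  fit <- stats::lm(snctp_z ~ ad + dataset + age_z + sex + pmi_z, data = d)
  cf <- summary(fit)$coefficients["ad", ]
  data.frame(cell_type = cell_type, beta = cf[["Estimate"]],
             se = cf[["Std. Error"]], p = cf[["Pr(>|t|)"]],
             n_subjects = nrow(d), n_samples = nrow(d), model = "ols",
             stringsAsFactors = FALSE)
}

#' Bonferroni and Benjamini-Hochberg adjustment within a family
#'
#' Fills `p_bonf = min(1, p * m)` (m = family size) and `p_fdr` (BH step-up)
#' for a family of association results.
#'
#' @param results Data frame with a `p` column.
#' @param family Optional label recorded in a `family` column.
#' @return `results` with `p_bonf` and `p_fdr` columns added.
#' @export
adjust_pvalues <- function(results, family = NULL) {
  stopifnot("p" %in% names(results), nrow(results) > 0)
  p <- results$p
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  results$p_bonf <- pmin(1, p * length(p))
  results$p_fdr <- stats::p.adjust(p, method = "BH")
  if (!is.null(family)) results$family <- family
  results
}

#' Cell type x phenotype association battery
#'
#' One OLS model per (subclass, outcome) cell of the battery: 11
#' neuropathology measures plus cognitive slope, cognition proximal to
#' death, and residual cognition (14 outcomes x 19 subclasses = 266 tests
#' when all are present). Pathology models covary for age at death, sex,
#' and PMI; cognitive models covary for sex, education, and age at baseline
#' assessment. Both the outcome (if continuous) and the rCTP are z-scored,
#' so betas are standardized. FDR is applied across the full battery; a
#' missing outcome column removes its row of the grid, shrinking the family
#' size, and is logged in the result's attributes.
#'
#' @param rctp_scores Subjects x subclasses score matrix (rownames =
#'   subject ids).
#' @param subjects Per-subject phenotype data frame (must include
#'   `subject_id`, covariates, and the outcome columns).
#' @param outcomes Character vector of outcome column names (default: the
#'   11 pathologies + `cognitive_slope`, `cog_at_death`,
#'   `residual_cognition`).
#' @param cognitive_outcomes Outcomes treated as cognitive (different
#'   covariate set).
#' @return Data frame with one row per test: cell_type, outcome, beta, se,
#'   p, p_fdr, n; attribute `untested` lists outcomes absent from
#'   `subjects`.
#' @export
phenotype_battery <- function(rctp_scores, subjects,
                              outcomes = c(pathology_measures(),
                                           "cognitive_slope", "cog_at_death",
                                           "residual_cognition"),
                              cognitive_outcomes = c("cognitive_slope",
                                                     "cog_at_death",
                                                     "residual_cognition")) {
  stopifnot(is.matrix(rctp_scores), "subject_id" %in% names(subjects))
  untested <- setdiff(outcomes, names(subjects))
  outcomes <- intersect(outcomes, names(subjects))
  if (length(untested))
    message("outcome(s) absent, family reduced: ",
            paste(untested, collapse = ", "))
  idx <- match(subjects$subject_id, rownames(rctp_scores))
  rows <- list()
  for (outcome in outcomes) {
    is_cog <- outcome %in% cognitive_outcomes
    if (is_cog) {
      covs <- subjects[, c("sex", "educ", "age_baseline")]
    } else {
      covs <- subjects[, c("age_at_death", "sex", "pmi")]
    }
    y <- subjects[[outcome]]
    for (k in colnames(rctp_scores)) {
      x <- rctp_scores[idx, k]
      ok <- stats::complete.cases(cbind(y, x, covs))
      d <- data.frame(y = as.vector(scale(y[ok])), x = as.vector(scale(x[ok])),
                      covs[ok, , drop = FALSE])
      fit <- stats::lm(y ~ ., data = d)
      cf <- summary(fit)$coefficients["x", ]
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = k, outcome = outcome, beta = cf[["Estimate"]],
        se = cf[["Std. Error"]], p = cf[["Pr(>|t|)"]], n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  attr(res, "untested") <- untested
  res
}

#' Per-marker-gene AD association models
#'
#' For each marker gene, OLS of z-scored expression on AD status, age, and
#' sex, with FDR across the marker family; the per-gene heatmap substrate
#' behind a subclass's proportion signal.
#'
#' @param log_expr Genes x samples expression matrix.
#' @param markers Marker gene ids (absent genes are skipped and logged).
#' @param meta Per-sample data frame with `ad` (0/1), `age_at_death`, `sex`.
#' @return Data frame: gene, beta, se, p, p_fdr, n; attribute `skipped`.
#' @export
marker_gene_models <- function(log_expr, markers, meta) {
  stopifnot(all(c("ad", "age_at_death", "sex") %in% names(meta)),
            nrow(meta) == ncol(log_expr))
  skipped <- setdiff(markers, rownames(log_expr))
  markers <- intersect(markers, rownames(log_expr))
  if (length(skipped))
    message("marker gene(s) absent, skipped: ", paste(skipped, collapse = ", "))
  ok <- stats::complete.cases(meta[, c("ad", "age_at_death", "sex")])
  age_z <- as.vector(scale(meta$age_at_death[ok]))
  sexn <- as.numeric(factor(meta$sex[ok]))
  rows <- lapply(markers, function(g) {
    y <- as.vector(scale(log_expr[g, ok]))
    fit <- stats::lm(y ~ meta$ad[ok] + age_z + sexn)
    cf <- summary(fit)$coefficients[2, ]
    data.frame(gene = g, beta = cf[["Estimate"]], se = cf[["Std. Error"]],
               p = cf[["Pr(>|t|)"]], n = sum(ok), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  attr(res, "skipped") <- skipped
  res
}

ols_r2 <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Nested-model variance partitioning with the 0.632+ bootstrap
#'
#' Quantifies the variance in an outcome explained by one added predictor
#' over a baseline covariate set: apparent R-squared from both OLS fits, a
#' likelihood-ratio test of the nested comparison, and
#' generalization-adjusted R-squared via the 0.632+ bootstrap. For each
#' model the 0.632+ prediction error blends the apparent squared error with
#' the out-of-bag bootstrap error using the relative-overfit weight
#' w = 0.632 / (1 - 0.368 R), R = (err_oob - err_app) / (gamma - err_app)
#' clipped to [0, 1], where gamma is the no-information error (mean squared
#' error over all response/prediction pairs); adjusted R-squared is
#' 1 - adjusted error / outcome variance.
#'
#' @param data Data frame containing all columns.
#' @param outcome Outcome column name.
#' @param baseline_covariates Character vector of baseline predictor
#'   columns.
#' @param added_predictor Single predictor column augmenting the baseline.
#' @param n_boot Bootstrap iterations (default 100).
#' @param seed Integer seed for the resampling.
#' @return A `variance_partition` list: r2_baseline, r2_augmented,
#'   delta_r2, lrt_p, r2_baseline_adj, r2_augmented_adj, delta_r2_adj,
#'   n_boot, n.
#' @export
variance_explained <- function(data, outcome, baseline_covariates,
                               added_predictor, n_boot = 100, seed = 1L) {
  cols <- c(outcome, baseline_covariates, added_predictor)
  stopifnot(all(cols %in% names(data)))
  d <- data[stats::complete.cases(data[, cols]), cols, drop = FALSE]
  y <- d[[outcome]]
  to_num <- function(v) if (is.numeric(v)) v else as.numeric(factor(v))
  Xb <- cbind(1, vapply(d[baseline_covariates], to_num, numeric(nrow(d))))
  Xa <- cbind(Xb, to_num(d[[added_predictor]]))
  n <- nrow(d)
  if (n <= ncol(Xa)) stop("need n > number of predictors")
  r2_b <- ols_r2(Xb, y)
  r2_a <- ols_r2(Xa, y)
  # nested-model likelihood ratio: LR = n log(RSS0 / RSS1), df = 1
  rss_b <- sum(stats::lm.fit(Xb, y)$residuals^2)
  rss_a <- sum(stats::lm.fit(Xa, y)$residuals^2)
  lrt <- n * (log(rss_b) - log(rss_a))
  lrt_p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  set.seed(seed)
  boot632 <- function(X) {
    pred_full <- as.vector(X %*% stats::lm.fit(X, y)$coefficients)
    err_app <- mean((y - pred_full)^2)
    gamma <- mean(outer(y, pred_full, function(a, b) (a - b)^2))
    oob_err <- oob_n <- numeric(n)
    b <- 0L
    while (b < n_boot) {
      retry <- 0L
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), idx)
        if (length(oob) == 0) next
        Xi <- X[idx, , drop = FALSE]
        if (qr(Xi)$rank == ncol(X)) break
        retry <- retry + 1L
        if (retry > 10L) stop("rank-deficient bootstrap designs (10 retries)")
      }
      beta <- stats::lm.fit(Xi, y[idx])$coefficients
      pred <- as.vector(X[oob, , drop = FALSE] %*% beta)
      oob_err[oob] <- oob_err[oob] + (y[oob] - pred)^2
      oob_n[oob] <- oob_n[oob] + 1L
      b <- b + 1L
    }
    covered <- oob_n > 0
    err_oob <- mean(oob_err[covered] / oob_n[covered])
    R <- if (err_oob > err_app && gamma > err_app)
      min(1, (err_oob - err_app) / (gamma - err_app)) else 0
    w <- 0.632 / (1 - 0.368 * R)
    err632 <- (1 - w) * err_app + w * err_oob
    1 - err632 / mean((y - mean(y))^2)
  }
  r2_b_adj <- boot632(Xb)
  r2_a_adj <- boot632(Xa)
  structure(list(r2_baseline = r2_b, r2_augmented = r2_a,
                 delta_r2 = r2_a - r2_b, lrt_p = lrt_p,
                 r2_baseline_adj = r2_b_adj, r2_augmented_adj = r2_a_adj,
                 delta_r2_adj = r2_a_adj - r2_b_adj,
                 n_boot = n_boot, n = n),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("Variance partition (n = %d, %d bootstrap iterations):\n", x$n, x$n_boot))
  cat(sprintf("  apparent R2: %.4f -> %.4f (delta %.4f), LRT p = %.3g\n",
              x$r2_baseline, x$r2_augmented, x$delta_r2, x$lrt_p))
  cat(sprintf("  0.632+ adjusted R2: %.4f -> %.4f (delta %.4f)\n",
              x$r2_baseline_adj, x$r2_augmented_adj, x$delta_r2_adj))
  invisible(x)
}
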