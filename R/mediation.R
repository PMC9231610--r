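# Causal mediation decomposition with a nonparametric bootstrap.

#' Fit a linear causal mediation model
#'
#' Fits the mediator model M ~ T + X and the outcome model Y ~ T + M + X by
#' OLS and decomposes the effect of T on Y into the average causal
#' mediation effect (ACME = a * b, the mediator-model treatment coefficient
#' times the outcome-model mediator coefficient), the average direct effect
#' (ADE, the outcome-model treatment coefficient), and the total effect
#' (ACME + ADE; exact for linear models without interaction). Confidence
#' intervals and p-values come from a nonparametric bootstrap: rows are
#' resampled with replacement `n_draws` times, both models refit, and the
#' per-draw effects collected; CIs are percentile intervals and the
#' two-sided p is `2 * min(frac <= 0, frac >= 0)`.
#'
#' @param data Data frame containing all columns.
#' @param treatment,mediator,outcome Column names.
#' @param covariates Character vector of covariate columns (may be empty).
#' @param n_draws Bootstrap draws (default 1000).
#' @param seed Integer seed.
#' @param conf_level CI level (default 0.95).
#' @return A `mediation_fit`: list with `acme`, `ade`, `total` (each a list
#'   with estimate, ci, p), `prop_mediated`, `n`, `n_draws`, `seed`, and
#'   the configuration.
#' @export
fit_mediation <- function(data, treatment, mediator, outcome,
                          covariates = character(0), n_draws = 1000,
                          seed = 1L, conf_level = 0.95) {
  cols <- c(treatment, mediator, outcome, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n < 50) warning("n < 50; mediation estimates will be unstable")
  to_num <- function(v) if (is.numeric(v)) v else as.numeric(factor(v))
  Tv <- to_num(d[[treatment]])
  Mv <- to_num(d[[mediator]])
  Yv <- to_num(d[[outcome]])
  if (stats::sd(Tv) == 0 || stats::sd(Mv) == 0)
    stop("treatment and mediator must be non-constant")
  Xc <- if (length(covariates))
    vapply(d[covariates], to_num, numeric(n)) else NULL
  Xm <- cbind(1, Tv, Xc)
  Xy <- cbind(1, Tv, Mv, Xc)
  if (qr(Xy)$rank < ncol(Xy))
    stop("rank-deficient design; check covariates: ",
         paste(covariates, collapse = ", "))
  decomp <- function(Xm, Xy, Mv, Yv) {
    a <- stats::lm.fit(Xm, Mv)$coefficients[2]
    cy <- stats::lm.fit(Xy, Yv)$coefficients
    b <- cy[3]
    ade <- cy[2]
    c(acme = unname(a * b), ade = unname(ade), total = unname(a * b + ade))
  }
  point <- decomp(Xm, Xy, Mv, Yv)
  set.seed(seed)
  draws <- matrix(NA_real_, n_draws, 3,
                  dimnames = list(NULL, c("acme", "ade", "total")))
  for (i in seq_len(n_draws)) {
    idx <- sample.int(n, n, replace = TRUE)
    draws[i, ] <- decomp(Xm[idx, , drop = FALSE], Xy[idx, , drop = FALSE],
                         Mv[idx], Yv[idx])
  }
  alpha <- (1 - conf_level) / 2
  summarize <- function(eff) {
    v <- draws[, eff]
    list(estimate = unname(point[eff]),
         ci = unname(stats::quantile(v, c(alpha, 1 - alpha))),
         p = min(1, 2 * min(mean(v <= 0), mean(v >= 0))))
  }
  structure(list(
    acme = summarize("acme"), ade = summarize("ade"),
    total = summarize("total"),
    prop_mediated = unname(point["acme"] / point["total"]),
    draws = draws, n = n, n_draws = n_draws, seed = seed,
    config = list(treatment = treatment, mediator = mediator,
                  outcome = outcome, covariates = covariates)),
    class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s (n = %d, %d draws)\n",
              x$config$treatment, x$config$mediator, x$config$outcome,
              x$n, x$n_draws))
  line <- function(nm, e)
    cat(sprintf("  %-6s %8.4f  [%.4f, %.4f]  p = %.4g\n", nm, e$estimate,
                e$ci[1], e$ci[2], e$p))
  line("ACME", x$acme); line("ADE", x$ade); line("Total", x$total)
  cat(sprintf("  proportion mediated: %.3f\n", x$prop_mediated))
  invisible(x)
}

#' The four SST/IT x pathology mediation configurations
#'
#' Runs the 2 x 2 battery of mediation models in which SST and IT relative
#' proportions each take the role of predictor or mediator against global
#' AD pathology, with cognition at the last study visit always the outcome
#' and APOE e4 dose among the covariates.
#'
#' @param data Data frame with columns `SST`, `IT`, `global_pathology`,
#'   `cognition`, plus covariates.
#' @param covariates Covariate columns (default: age at death, sex,
#'   education, APOE e4 dose).
#' @param n_draws Bootstrap draws per model (default 1000).
#' @param seed Integer seed (one per-model offset is derived from it).
#' @return Named list of four `mediation_fit` objects:
#'   `sst_via_pathology`, `pathology_via_sst`, `it_via_pathology`,
#'   `pathology_via_it`.
#' @export
run_four_models <- function(data,
                            covariates = c("age_at_death", "sex", "educ",
                                           "apoe4"),
                            n_draws = 1000, seed = 1L) {
  configs <- list(
    sst_via_pathology = c("SST", "global_pathology"),
    pathology_via_sst = c("global_pathology", "SST"),
    it_via_pathology  = c("IT", "global_pathology"),
    pathology_via_it  = c("global_pathology", "IT"))
  out <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    fit_mediation(data, treatment = cfg[1], mediator = cfg[2],
                  outcome = "cognition", covariates = covariates,
                  n_draws = n_draws, seed = seed + i - 1L)
  })
  names(out) <- names(configs)
  out
}
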