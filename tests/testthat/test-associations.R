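test_that("mega model reduces to OLS without repeated subjects", {
  d <- simulate_mega_data(n_single = 120, n_repeat = 0, shift = -0.3, seed = 2)
  d$study[61:120] <- "B"   # two studies, still no repeats
  res <- mega_model(d, "SST")
  expect_identical(res$model, "ols_no_repeats")
  ols <- lm(scale(rctp) ~ ad + study + scale(age_at_death) + sex, data = d)
  cf <- summary(ols)$coefficients["ad", ]
  expect_equal(res$beta, cf[["Estimate"]], tolerance = 1e-6)
  expect_equal(res$se, cf[["Std. Error"]], tolerance = 1e-6)
  expect_error(mega_model(transform(d, study = "A")), "2 studies")
})

test_that("mega model recovers a planted half-SD deficit", {
  # shift planted directly in the score, in units of its total SD
  d <- simulate_mega_data(n_single = 260, n_repeat = 70, shift = 0, seed = 7)
  sd_tot <- sd(d$rctp)
  d$rctp <- d$rctp - 0.5 * sd_tot * d$ad
  res <- mega_model(d, "SST")
  expect_identical(res$model, "lmm")
  expect_lt(abs(res$beta - (-0.5)), 0.15)
  expect_lt(res$p, 1e-4)
})

test_that("mega-analysis type-I error is nominal over null replicates", {
  p <- vapply(1:200, function(s) {
    d <- simulate_mega_data(n_single = 90, n_repeat = 30, shift = 0, seed = s)
    mega_model(d, "null")$p
  }, numeric(1))
  rate <- mean(p < 0.05)
  # binomial 95% band for 200 replicates at alpha = 0.05
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("sn model recovers planted deficits and flags collinearity", {
  set.seed(9)
  n <- 90
  d <- data.frame(ad = rbinom(n, 1, 0.5),
                  dataset = sample(c("d1", "d2", "d3"), n, replace = TRUE),
                  age_at_death = rnorm(n, 85, 6),
                  sex = sample(c("F", "M"), n, replace = TRUE),
                  pmi = rgamma(n, 2.5, 0.3))
  d$snctp <- 4 - 1.2 * d$ad + rnorm(n, 0, 1)
  res <- sn_model(d, "LAMP5")
  expect_lt(res$beta, 0)
  expect_lt(res$p, 0.01)
  d_null <- transform(d, snctp = rnorm(n, 4, 1))
  expect_gt(sn_model(d_null, "LAMP5")$p, 0.001)
  d_bad <- transform(d, dataset = ifelse(sex == "F", "d1", "d2"))
  expect_error(sn_model(d_bad, "LAMP5"), "rank-deficient")
})

test_that("p-value adjustment matches arithmetic and the BH step-up oracle", {
  res <- adjust_pvalues(data.frame(p = 0.001), family = "one")
  expect_equal(res$p_bonf, 0.001)
  expect_equal(res$p_fdr, 0.001)
  res19 <- adjust_pvalues(data.frame(p = c(0.001, rep(0.5, 18))))
  expect_equal(res19$p_bonf[1], 0.019)
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  set.seed(41)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))
    # duplicate some entries to exercise ties
    if (i %% 3 == 0) p[1:2] <- p[3]
    adj <- adjust_pvalues(data.frame(p = p))
    expect_equal(adj$p_fdr, bh_oracle(p), tolerance = 1e-12)
    expect_equal(adj$p_bonf, pmin(1, p * length(p)), tolerance = 1e-12)
  }
  expect_error(adjust_pvalues(data.frame(p = c(0.5, 1.2))), "0, 1")
})

test_that("phenotype battery instantiates the full grid and localizes planted signal", {
  cohort <- cohort_fixture()
  truth <- cohort$bulk$truth
  ph <- generate_phenotypes(truth, seed = 13)
  subj <- ph$subjects
  ref <- baseline_reference(ph$visits, names(ph$domains))
  vis <- compute_global_cognition(ph$visits, ph$domains, ref)
  slopes <- estimate_cognitive_slope(vis)
  subj$cognitive_slope <- slopes[subj$subject_id]
  subj$residual_cognition <- compute_residual_cognition(subj)[subj$subject_id]
  sc <- cohort$rctp[[1]]$scores
  rownames(sc) <- cohort$bulk$metadata$subject_id[
    match(rownames(sc), cohort$bulk$metadata$sample_id)]
  bat <- phenotype_battery(sc, subj)
  expect_identical(nrow(bat), 266L)
  expect_identical(length(unique(bat$cell_type)), 19L)
  expect_identical(length(unique(bat$outcome)), 14L)
  # SST (negatively loaded on amyloid/tau) is detected against amyloid
  sst_amyloid <- bat[bat$cell_type == "SST" & bat$outcome == "amyloid", ]
  expect_lt(sst_amyloid$beta, 0)
  expect_lt(sst_amyloid$p_fdr, 0.1)
  # a missing outcome shrinks the family and is reported
  expect_message(bat2 <- phenotype_battery(sc, subj[, setdiff(names(subj),
                                                              "tdp43")]),
                 "tdp43")
  expect_identical(nrow(bat2), 19L * 13L)
  expect_identical(attr(bat2, "untested"), "tdp43")
})

test_that("marker gene models match the closed-form regression and detect shifts", {
  set.seed(15)
  n <- 80
  meta <- data.frame(ad = rbinom(n, 1, 0.5), age_at_death = rnorm(n, 85, 6),
                     sex = sample(c("F", "M"), n, replace = TRUE))
  expr <- matrix(rnorm(20 * n, 8, 1), 20, n,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  expr[1:10, ] <- expr[1:10, ] - 0.8 * rep(meta$ad, each = 10)
  res <- marker_gene_models(expr, rownames(expr), meta)
  expect_true(mean(res$beta[1:10] < 0) > 0.8)
  g <- "g01"
  ours <- res[res$gene == g, ]
  fit <- lm(scale(expr[g, ]) ~ meta$ad + scale(meta$age_at_death) +
              as.numeric(factor(meta$sex)))
  cf <- summary(fit)$coefficients[2, ]
  expect_equal(ours$beta, cf[["Estimate"]], tolerance = 1e-9)
  expect_equal(ours$p, cf[["Pr(>|t|)"]], tolerance = 1e-9)
  expect_message(marker_gene_models(expr, c("g01", "zz"), meta), "zz")
})

test_that("0.632+ bootstrap shrinks a pure-noise predictor's contribution", {
  set.seed(17)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), noise = rnorm(n))
  d$y <- 0.5 * d$x1 + 0.3 * d$x2 + rnorm(n)
  vp <- variance_explained(d, "y", c("x1", "x2"), "noise", n_boot = 100,
                           seed = 17)
  expect_gte(vp$delta_r2, 0)                      # nested OLS monotonicity
  expect_lte(vp$delta_r2_adj, vp$delta_r2)        # adjustment never inflates
  expect_lt(abs(vp$delta_r2_adj), 0.02)           # ~0 within Monte-Carlo error
  expect_gt(vp$lrt_p, 0.01)
})

test_that("0.632+ bootstrap recovers a planted 2%-variance predictor", {
  set.seed(18)
  n <- 900
  d <- data.frame(x1 = rnorm(n), extra = rnorm(n))
  # extra explains ~2% of var(y)
  d$y <- 1.0 * d$x1 + sqrt(0.02 / 0.98) * sqrt(1 + 1) * d$extra + rnorm(n)
  vp <- variance_explained(d, "y", "x1", "extra", n_boot = 100, seed = 18)
  truth <- var(sqrt(0.02 / 0.98) * sqrt(2) * d$extra) /
    var(d$y)
  expect_lt(abs(vp$delta_r2 - truth), 0.01)
  expect_lt(abs(vp$delta_r2_adj - truth), 0.01)
  expect_lt(vp$lrt_p, 1e-4)
})

test_that("variance partition hits the perfect-fit limit", {
  set.seed(19)
  n <- 60
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 2 * d$x1 - d$x2          # deterministic
  vp <- variance_explained(d, "y", "x1", "x2", n_boot = 50, seed = 3)
  expect_equal(vp$r2_augmented, 1, tolerance = 1e-12)
  expect_gt(vp$r2_augmented_adj, 0.999)
  expect_lt(vp$lrt_p, 1e-10)
})

test_that("standardized betas are invariant to affine outcome rescaling", {
  d <- simulate_mega_data(n_single = 100, n_repeat = 30, shift = -0.4, seed = 4)
  r1 <- mega_model(d, "SST")
  d2 <- transform(d, rctp = 10 + 7 * rctp)
  r2 <- mega_model(d2, "SST")
  expect_equal(r1$beta, r2$beta, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})
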