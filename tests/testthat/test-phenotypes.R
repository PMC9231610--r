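test_that("consensus diagnosis rule labels interior and mixed profiles", {
  subj <- data.frame(
    braak = c(5, 2, 5, NA, 4),
    cerad = c("frequent", "none", "none", "frequent", "moderate"),
    cogdx = c(4, 1, 4, 4, 1))
  cl <- classify_ad(subj)
  expect_identical(as.character(cl$label),
                   c("AD", "control", "other", "other", "other"))
  expect_match(cl$reasons[4], "missing")
  expect_match(cl$reasons[3], "mixed")
  # total and deterministic: every subject gets exactly one label
  expect_identical(length(cl$label), nrow(subj))
  expect_identical(cl$label, classify_ad(subj)$label)
  # neuropathology-only variant ignores cognition
  cl2 <- classify_ad(subj[, c("braak", "cerad")],
                     default_diagnosis_rule(neuropathology_only = TRUE))
  expect_identical(as.character(cl2$label)[1:2], c("AD", "control"))
})

test_that("global cognition composites average domains against baseline", {
  domains <- setNames(rep(paste0("domain", 1:5), c(4, 4, 3, 3, 3)),
                      sprintf("test_%02d", 1:17))
  n <- 30
  visits <- data.frame(subject_id = sprintf("s%02d", 1:n), visit = 1)
  for (tc in names(domains)) visits[[tc]] <- rnorm(n, 10, 2)
  ref <- baseline_reference(visits, names(domains))
  # all tests at the baseline mean: composite 0
  at_mean <- visits
  for (tc in names(domains)) at_mean[[tc]] <- ref$mean[[tc]]
  out <- compute_global_cognition(at_mean, domains, ref)
  expect_true(all(abs(out$composite_global) < 1e-12))
  # one domain +1 SD, others at mean: global = 0.2
  plus1 <- at_mean
  for (tc in names(domains)[domains == "domain1"])
    plus1[[tc]] <- ref$mean[[tc]] + ref$sd[[tc]]
  out1 <- compute_global_cognition(plus1, domains, ref)
  expect_equal(unique(round(out1$composite_global, 12)), 0.2)
})

test_that("composite matches the brute-force z-score oracle and missingness rules", {
  set.seed(31)
  domains <- setNames(rep(paste0("domain", 1:5), c(4, 4, 3, 3, 3)),
                      sprintf("test_%02d", 1:17))
  visits <- data.frame(subject_id = sprintf("s%02d", 1:40),
                       visit = rep(1:2, each = 20))
  for (tc in names(domains)) visits[[tc]] <- rnorm(40, 10, 2)
  ref <- baseline_reference(visits, names(domains))
  out <- compute_global_cognition(visits, domains, ref)
  for (i in c(1, 17, 40)) {
    z <- (as.numeric(visits[i, names(domains)]) - ref$mean) / ref$sd
    dom <- tapply(z, domains, mean)
    expect_equal(out$composite_global[i], mean(dom), tolerance = 1e-12)
  }
  # a domain with <50% of tests observed goes missing
  sparse <- visits
  sparse[1, names(domains)[domains == "domain1"][1:3]] <- NA
  out2 <- compute_global_cognition(sparse, domains, ref)
  expect_true(is.na(out2$composite_domain1[1]))
  expect_false(is.na(out2$composite_global[1]))   # other domains remain
  # adding an all-missing test column does not change the composite
  dom2 <- c(domains, test_18 = "domain5")
  with_na <- visits; with_na$test_18 <- NA_real_
  ref2 <- ref
  ref2$mean <- c(ref2$mean, test_18 = 0); ref2$sd <- c(ref2$sd, test_18 = 1)
  out3 <- compute_global_cognition(with_na, dom2, ref2)
  expect_equal(out3$composite_global, out$composite_global, tolerance = 1e-12)
})

test_that("cognitive slopes are exact in the noiseless limit and recovered under noise", {
  set.seed(11)
  n <- 150; n_visits <- 8
  slopes <- rnorm(n, -0.08, 0.05)
  inter <- rnorm(n, 0, 0.3)
  d <- expand.grid(subject_id = sprintf("s%03d", 1:n), visit = 1:n_visits)
  d$year <- d$visit - 1
  i <- match(d$subject_id, sprintf("s%03d", 1:n))
  d$composite_global <- inter[i] + slopes[i] * d$year
  exact <- estimate_cognitive_slope(d)
  expect_equal(unname(exact[sprintf("s%03d", 1:n)]), slopes, tolerance = 1e-6)
  # planted slope SD 0.05, visit noise SD 0.1: high-fidelity recovery
  d$composite_global <- d$composite_global + rnorm(nrow(d), 0, 0.1)
  est <- estimate_cognitive_slope(d)
  expect_gte(cor(est[sprintf("s%03d", 1:n)], slopes), 0.8)
  # subjects with < 2 visits receive NA
  d1 <- rbind(d, data.frame(subject_id = "solo", visit = 1, year = 0,
                            composite_global = 0.5))
  est1 <- estimate_cognitive_slope(d1)
  expect_true(is.na(est1[["solo"]]))
})

test_that("zero slope variance yields near-zero random-slope estimates", {
  set.seed(12)
  n <- 80
  d <- expand.grid(subject_id = sprintf("s%03d", 1:n), visit = 1:6)
  d$year <- d$visit - 1
  d$composite_global <- -0.05 * d$year + rnorm(nrow(d), 0, 0.2)
  est <- estimate_cognitive_slope(d)
  expect_lt(sd(est), 0.02)      # heavy shrinkage toward the fixed slope
  expect_lt(abs(mean(est) + 0.05), 0.02)
})

test_that("residual cognition is orthogonal to regressors and zero under perfect fit", {
  set.seed(14)
  n <- 120
  subj <- data.frame(subject_id = sprintf("s%03d", 1:n))
  for (p in pathology_measures()) subj[[p]] <- rnorm(n)
  subj$age_at_death <- rnorm(n, 85, 5)
  subj$sex <- sample(c("F", "M"), n, replace = TRUE)
  subj$educ <- round(rnorm(n, 16, 3))
  # perfectly linear cognition: residuals all 0
  subj$cog_at_death <- 2 - 0.5 * subj$amyloid + 0.3 * subj$tangles +
    0.01 * subj$age_at_death + 0.02 * subj$educ +
    0.1 * (subj$sex == "M")
  r0 <- compute_residual_cognition(subj)
  expect_true(all(abs(r0) < 1e-8))
  # noisy cognition: residuals orthogonal to every regressor
  subj$cog_at_death <- subj$cog_at_death + rnorm(n, 0, 0.5)
  r <- compute_residual_cognition(subj)
  X <- cbind(as.matrix(subj[, pathology_measures()]),
             scale(subj$age_at_death, scale = FALSE),
             as.numeric(factor(subj$sex)) - 1.5,
             scale(subj$educ, scale = FALSE))
  expect_true(all(abs(crossprod(X, unname(r))) < 1e-8))
  # rank deficiency names the offending columns
  bad <- subj
  bad$amyloid <- bad$tangles
  expect_error(compute_residual_cognition(bad), "collinear")
})

test_that("a resilience signal planted on IT survives pathology adjustment", {
  cohort <- cohort_fixture()
  ph <- generate_phenotypes(cohort$bulk$truth, seed = 13)
  subj <- ph$subjects
  resid <- compute_residual_cognition(subj)
  it_z <- cohort$bulk$truth$latent_z[names(resid), "IT"]
  expect_gt(cor(resid, it_z), 0.2)
  expect_lt(cor.test(resid, it_z)$p.value, 1e-3)
})

test_that("global pathology is the symmetric mean of its three components", {
  subj <- data.frame(plaq_d = c(1, 0), plaq_n = c(2, 0), tangles = c(3, 0))
  expect_equal(unname(compute_global_pathology(subj)), c(2, 0))
  perm <- data.frame(plaq_d = subj$tangles, plaq_n = subj$plaq_d,
                     tangles = subj$plaq_n)
  expect_equal(compute_global_pathology(perm), compute_global_pathology(subj))
  subj$tangles[1] <- NA
  expect_true(is.na(compute_global_pathology(subj)[1]))
  expect_error(compute_global_pathology(data.frame(plaq_d = 1)), "missing")
})
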