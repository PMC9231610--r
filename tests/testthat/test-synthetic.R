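test_that("taxonomy has 19 uniquely labeled subclasses in three classes", {
  tax <- cortical_taxonomy()
  expect_identical(nrow(tax), 19L)
  expect_identical(anyDuplicated(tax$subclass), 0L)
  expect_identical(as.vector(table(tax$class)), c(5L, 7L, 7L))
  expect_true(all(c("SST", "IT", "PVALB", "VLMC") %in% tax$subclass))
  expect_silent(validate_taxonomy(tax))
})

test_that("reference generator is seed-deterministic and rejects bad sizes", {
  r1 <- generate_reference(n_nuclei_per_type = 10, n_genes = 400, seed = 5)
  r2 <- generate_reference(n_nuclei_per_type = 10, n_genes = 400, seed = 5)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$labels, r2$labels)
  r3 <- generate_reference(n_nuclei_per_type = 10, n_genes = 400, seed = 6)
  expect_false(identical(r1$counts, r3$counts))
  expect_error(generate_reference(n_nuclei_per_type = 0), "positive")
  expect_error(generate_reference(n_genes = 50, marker_frac = 0.001),
               "marker_frac")
})

test_that("designated markers reach the configured enrichment at low noise", {
  # near-Poisson counts, fold = 8: empirical in/out mean ratio close to 8
  r <- generate_reference(n_nuclei_per_type = 200, fold = 8,
                          dispersion = 1e-8, seed = 1)
  x <- sweep(r$counts, 2, colSums(r$counts), "/") * 1e6
  tax <- r$truth$taxonomy$subclass
  ratios <- vapply(tax, function(k) {
    g <- r$truth$markers[[k]]
    in_mean <- rowMeans(x[g, r$labels == k, drop = FALSE])
    out_mean <- rowMeans(x[g, r$labels != k, drop = FALSE])
    mean(in_mean / out_mean)
  }, numeric(1))
  expect_true(all(ratios >= 6 & ratios <= 10))
})

test_that("NB generator means match analytic expectations within 3 SE", {
  # a handful of (gene, subclass) cells at 1000 draws each
  r <- generate_reference(n_nuclei_per_type = 5, n_genes = 200,
                          marker_frac = 0.05, dispersion = 0.1, seed = 2)
  sig <- r$truth$signatures
  set.seed(99)
  for (cell in list(c(1, 1), c(25, 3), c(180, 19))) {
    g <- cell[1]; k <- cell[2]
    mu <- 5e4 * sig[g, k] / sum(sig[, k])
    draws <- rnbinom(1000, mu = mu, size = 1 / 0.1)
    se <- sqrt((mu + 0.1 * mu^2) / 1000)
    expect_lt(abs(mean(draws) - mu), 3 * se)
  }
})

test_that("true proportion rows are simplex points and AD shifts plant a deficit", {
  cohort <- cohort_fixture()
  P <- cohort$bulk$truth$true_proportions
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  expect_true(all(P >= 0))
  subj <- cohort$bulk$truth$subjects
  sst_ad <- mean(P[subj$subject_id[subj$ad_label == "AD"], "SST"])
  sst_ctrl <- mean(P[subj$subject_id[subj$ad_label == "control"], "SST"])
  expect_lt(sst_ad, sst_ctrl)
  it_ad <- mean(P[subj$subject_id[subj$ad_label == "AD"], "IT"])
  it_ctrl <- mean(P[subj$subject_id[subj$ad_label == "control"], "IT"])
  expect_lt(it_ad, it_ctrl)
})

test_that("a pure single-subclass sample reproduces its signature profile", {
  ref <- generate_reference(n_nuclei_per_type = 5, n_genes = 300,
                            marker_frac = 0.02, seed = 4)
  tax <- ref$truth$taxonomy
  design <- structure(list(studies = list(
    list(name = "A", regions = c("r1", "r2"), n_control = 3, n_case = 3,
         n_other = 0, shared_subjects = TRUE))), class = "study_design")
  P <- matrix(0, 6, nrow(tax), dimnames = list(NULL, tax$subclass))
  P[, "SST"] <- 1
  b <- generate_bulk_cohort(ref$truth, design, dispersion = 1e-9,
                            batch_sd = 0, tech_sd = 0, proportions = P,
                            library_size = 5e6, seed = 11)
  prof <- rowSums(b$counts[[1]])
  expected <- ref$truth$signatures[, "SST"]
  expect_gt(cor(prof, expected), 0.999)
  # shared subjects across the two regions: same subject ids, distinct samples
  m <- b$metadata
  expect_setequal(m$subject_id[m$region == "r1"], m$subject_id[m$region == "r2"])
  expect_identical(anyDuplicated(m$sample_id), 0L)
})

test_that("bulk generator is deterministic and rejects signature mismatch", {
  ref <- ref_fixture()
  d <- default_study_design(60)
  b1 <- generate_bulk_cohort(ref$truth, d, seed = 3)
  b2 <- generate_bulk_cohort(ref$truth, d, seed = 3)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$metadata, b2$metadata)
  bad <- ref$truth
  bad$signatures <- bad$signatures[, 1:5]
  expect_error(generate_bulk_cohort(bad, d, seed = 3), "mismatch")
})

test_that("sn cohort draws match the multinomial model", {
  cohort <- cohort_fixture()
  truth <- cohort$bulk$truth
  # degenerate proportions: all nuclei get the single supported subclass
  t2 <- truth
  P1 <- truth$true_proportions
  P1[] <- 0
  P1[, "IT"] <- 1
  t2$true_proportions <- P1
  sn1 <- generate_sn_cohort(t2, n_subjects = 3,
                            nuclei_per_subject = c(50, 50), seed = 1)
  expect_true(all(sn1$annotations$subclass == "IT"))
  # law of large numbers: 10k nuclei pin empirical fractions within 2 points
  sn <- generate_sn_cohort(truth, n_subjects = 5,
                           nuclei_per_subject = c(10000, 10000), seed = 3)
  ctp <- compute_snctp(sn$annotations, subclasses = truth$taxonomy$subclass)
  for (id in rownames(ctp$percents)) {
    expect_true(all(abs(ctp$percents[id, ] / 100 -
                          truth$true_proportions[id, ]) < 0.02))
  }
  # error path: truth without subjects
  expect_error(generate_sn_cohort(ref_fixture()$truth, n_subjects = 5),
               "no subjects")
})

test_that("phenotype generator honors null configurations and determinism", {
  cohort <- cohort_fixture()
  truth <- cohort$bulk$truth
  p1 <- generate_phenotypes(truth, seed = 13)
  p2 <- generate_phenotypes(truth, seed = 13)
  expect_identical(p1$subjects, p2$subjects)
  expect_identical(p1$visits, p2$visits)
  expect_error(generate_phenotypes(truth, n_visits = 1), "n_visits")
  # zero slope coefficients and zero noise: flat trajectories
  cm <- default_cognition_model()
  cm$slope_intercept <- 0; cm$slope_subclass[] <- 0
  cm$slope_pathology <- 0; cm$slope_sd <- 0
  p0 <- generate_phenotypes(truth, noise_sd = 0, cognition_model = cm,
                            seed = 2)
  per_subj_range <- tapply(p0$visits$composite, p0$visits$subject_id,
                           function(x) diff(range(x)))
  expect_true(all(per_subj_range < 1e-12))
})
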