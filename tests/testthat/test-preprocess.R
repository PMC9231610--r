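test_that("median-count gene filter is strict at the boundary and matches the oracle", {
  m <- rbind(at_threshold = c(15, 15, 15),
             above = c(16, 16, 16),
             below = c(2, 3, 4))
  colnames(m) <- paste0("s", 1:3)
  out <- filter_genes(m)
  expect_identical(rownames(out), "above")
  counts <- small_counts()
  kept <- rownames(filter_genes(counts, 15))
  oracle <- rownames(counts)[apply(counts, 1, median) > 15]
  expect_identical(kept, oracle)
  expect_error(filter_genes(matrix(0, 3, 3,
                                   dimnames = list(letters[1:3], NULL))),
               "all genes removed")
})

test_that("MDS outlier rule flags composition outliers but not pure depth changes", {
  set.seed(2)
  base <- matrix(rpois(300 * 30, 50), 300, 30,
                 dimnames = list(NULL, sprintf("s%02d", 1:30)))
  # identical samples: no outliers
  clones <- matrix(rep(base[, 1], 10), ncol = 10,
                   dimnames = list(NULL, paste0("c", 1:10)))
  expect_identical(detect_outlier_samples(clones), character(0))
  # a pure 100x depth rescaling has identical CPM: not an outlier
  scaled <- base
  scaled[, 5] <- base[, 5] * 100
  expect_false("s05" %in% detect_outlier_samples(scaled))
  # a composition outlier (half the genes doubled) is flagged
  comp <- base
  comp[1:150, 9] <- comp[1:150, 9] * 4
  expect_true("s09" %in% detect_outlier_samples(comp))
})

test_that("outlier flags equal the brute-force per-component IQR rule", {
  counts <- small_counts(n_genes = 150, n_samples = 25, seed = 8)
  counts[, 3] <- counts[, 3] + rpois(150, 40)   # mild shift
  flagged <- detect_outlier_samples(counts, n_components = 5, k_iqr = 3)
  x <- log2(sweep(counts, 2, colSums(counts), "/") * 1e6 + 1)
  emb <- cmdscale(dist(t(x)), k = 5)
  oracle <- colnames(counts)[Reduce(`|`, lapply(1:5, function(j)
    abs(emb[, j] - median(emb[, j])) > 3 * IQR(emb[, j])))]
  expect_identical(flagged, oracle)
})

test_that("winsorization clamps to the per-gene band and is idempotent", {
  # zero-IQR gene untouched
  m0 <- matrix(10, 1, 4)
  expect_identical(winsorize_log2(m0), m0)
  # hand-computed clamp of one extreme value among five
  g <- matrix(c(2, 4, 8, 16, 4096), 1, 5)
  x <- log2(g + 0.5)
  hi <- median(x) + 3 * IQR(x)
  expected <- c(2, 4, 8, 16, 2^hi - 0.5)
  expect_equal(as.vector(winsorize_log2(g)), expected, tolerance = 1e-12)
  # in-band values are bit-identical; idempotence on random fixtures
  set.seed(3)
  for (i in 1:5) {
    m <- matrix(rnbinom(200, mu = 50, size = 2), 20, 10)
    w <- winsorize_log2(m)
    inside <- w == m
    expect_identical(w[inside], m[inside])
    expect_equal(winsorize_log2(w), w, tolerance = 1e-12)
  }
})

test_that("winsorization commutes with sample permutation", {
  set.seed(4)
  m <- matrix(rnbinom(300, mu = 80, size = 1), 30, 10)
  perm <- sample(10)
  expect_equal(winsorize_log2(m)[, perm], winsorize_log2(m[, perm]))
})

test_that("TMM factors: symmetry, pure depth invariance, and edgeR oracle", {
  m <- small_counts(n_genes = 50, n_samples = 4, seed = 5)
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(tmm_factors(same)), rep(1, 3), tolerance = 1e-12)
  # sample B = 2x sample A gene-wise: no composition bias, equal factors
  two <- cbind(a = m[, 1], b = 2 * m[, 1])
  f2 <- tmm_factors(two)
  expect_equal(unname(f2[1]), unname(f2[2]), tolerance = 1e-6)
  # independent implementation oracle on a seeded 200 x 6 matrix
  counts <- small_counts(n_genes = 200, n_samples = 6, seed = 17, mu = 40)
  ours <- tmm_factors(counts)
  theirs <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("observation weights track the mean-variance trend", {
  set.seed(4)
  n_g <- 400; n_s <- 50
  mu <- runif(n_g, 2, 10)
  # homoskedastic: weights near-constant (within 10% of their median)
  hom <- matrix(rnorm(n_g * n_s, mu, 0.5), n_g, n_s)
  w <- observation_weights(hom)
  expect_true(all(abs(w / median(w) - 1) < 0.1))
  # planted decreasing SD in the mean: weights increase with expression
  sd_g <- 1.5 - 0.12 * mu
  het <- matrix(rnorm(n_g * n_s, mu, sd_g), n_g, n_s)
  w2 <- observation_weights(het)
  ord <- order(mu)
  lowm <- rowMeans(w2)[ord[1:100]]
  highm <- rowMeans(w2)[ord[301:400]]
  expect_gt(mean(highm), mean(lowm))
  # fallback for tiny matrices
  expect_warning(w1 <- observation_weights(matrix(rnorm(5), 1, 5)), "unit")
  expect_true(all(w1 == 1))
})

test_that("technical covariate removal eliminates planted effects exactly", {
  set.seed(6)
  n_g <- 80; n_s <- 40
  expr <- matrix(rnorm(n_g * n_s, 8, 1), n_g, n_s)
  batch <- rep(c("a", "b"), each = n_s / 2)
  planted <- expr + outer(rep(2, n_g), as.numeric(batch == "b"))
  clean <- remove_technical(planted, data.frame(batch = batch))
  gap <- rowMeans(clean[, batch == "b"]) - rowMeans(clean[, batch == "a"])
  expect_true(all(abs(gap) < 1e-10))
  # residualized matrix orthogonal to every covariate column (weighted)
  covs <- data.frame(batch = batch, rin = rnorm(n_s))
  w <- matrix(runif(n_g * n_s, 0.5, 2), n_g, n_s)
  out <- remove_technical(planted, covs, weights = w)
  X <- cbind(as.numeric(batch == "b") - 0.5, scale(covs$rin, scale = FALSE))
  for (j in 1:2) {
    # refitting the covariates on the residualized data recovers ~0 effects
    fit_dot <- vapply(seq_len(n_g), function(g) {
      r <- lm.wfit(cbind(1, X), out[g, ], w[g, ])
      abs(r$coefficients[j + 1])
    }, numeric(1))
    expect_true(all(fit_dot < 1e-8))
  }
  # rank deficiency is reported with the offending columns
  covs_bad <- data.frame(rin = covs$rin, rin2 = covs$rin * 2)
  expect_error(remove_technical(planted, covs_bad), "rank-deficient")
})

test_that("null covariates leave expression essentially unchanged", {
  set.seed(7)
  expr <- matrix(rnorm(60 * 200, 8, 1), 60, 200)
  covs <- data.frame(rin = rnorm(200))   # orthogonal to expression
  out <- remove_technical(expr, covs)
  expect_lt(max(abs(out - expr)), 0.5)   # per-gene OLS noise at n = 200
  expect_lt(mean(abs(out - expr)), 0.05)
})

test_that("full preprocessing pipeline runs in order and reports QC", {
  cohort <- cohort_fixture()
  nm <- cohort$norm[[1]]
  expect_s3_class(nm, "normalized_matrix")
  expect_true(all(nm$weights > 0))
  expect_equal(exp(mean(log(nm$tmm))), 1, tolerance = 1e-10)
  expect_identical(nm$qc$n_genes_kept, nrow(nm$log_expr))
})
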