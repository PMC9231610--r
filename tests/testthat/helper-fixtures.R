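# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Default synthetic reference (seed 1) and its selected markers.
ref_fixture <- function() fixture("ref", function() {
  ref <- generate_reference(seed = 1)
  ref$marker_set <- select_markers(ref$counts, ref$labels)
  ref
})

# Default 400-subject bulk cohort at seed 7, fully preprocessed, with
# harmonized markers and per-dataset rCTPs.
cohort_fixture <- function() fixture("cohort", function() {
  ref <- ref_fixture()
  bulk <- generate_bulk_cohort(ref$truth, default_study_design(400), seed = 7)
  norm <- lapply(names(bulk$counts), function(ds) {
    meta <- bulk$metadata[bulk$metadata$dataset == ds, ]
    preprocess_counts(bulk$counts[[ds]],
                      meta[, c("batch", "rin", "pmi", "pct_mapped", "pct_usable")])
  })
  names(norm) <- names(bulk$counts)
  mh <- harmonize_markers(ref$marker_set,
                          lapply(norm, function(x) rownames(x$log_expr)))
  rctp <- lapply(norm, function(x) estimate_all(x$log_expr, mh))
  list(bulk = bulk, norm = norm, markers = mh, rctp = rctp)
})

# Pooled per-subject rCTP/truth Spearman for one subclass across datasets.
pooled_recovery_rho <- function(cohort, subclass) {
  bulk <- cohort$bulk
  sc <- unlist(lapply(names(cohort$rctp), function(ds) {
    s <- cohort$rctp[[ds]]$scores[, subclass]
    names(s) <- bulk$metadata$subject_id[
      match(rownames(cohort$rctp[[ds]]$scores), bulk$metadata$sample_id)]
    s
  }))
  cor(sc, bulk$truth$true_proportions[names(sc), subclass],
      method = "spearman")
}

# Small seeded NB count matrix for oracle tests.
small_counts <- function(n_genes = 100, n_samples = 20, seed = 42,
                         mu = 60, size = 5) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# Model-level mega-analysis data: z-scored proportion scores for subjects in
# two studies, one of which samples the same subjects in two regions, with a
# planted AD group shift.
simulate_mega_data <- function(n_single = 150, n_repeat = 50, shift = 0,
                               subj_sd = 0.6, resid_sd = 0.8, seed = 1) {
  set.seed(seed)
  n <- n_single + n_repeat
  subj <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    study = rep(c("A", "B"), c(n_single, n_repeat)),
    ad = rbinom(n, 1, 0.5),
    age_at_death = rnorm(n, 85, 6),
    sex = sample(c("F", "M"), n, replace = TRUE))
  subj$u <- rnorm(n, 0, subj_sd) + shift * subj$ad
  reps <- ifelse(subj$study == "B", 2L, 1L)
  d <- subj[rep(seq_len(n), reps), ]
  d$rctp <- d$u + rnorm(nrow(d), 0, resid_sd)
  d
}
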