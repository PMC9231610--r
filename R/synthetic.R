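# Synthetic multi-study cohort generator with known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a deeply sequenced single-nucleus reference with subclass-specific
# marker blocks, multi-study bulk cohorts whose expression is a proportion-
# weighted mixture of subclass signatures with negative-binomial noise and
# technical effects, nucleus-level cohorts drawn from the same per-subject
# true proportions, and phenotypes (neuropathology, longitudinal cognition)
# causally linked to the true proportions with configurable effect sizes.

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Default AD proportion shifts on the logit scale
#'
#' Per-subclass shifts applied to AD cases' proportion logits, expressed in
#' units of the between-subject logit SD so an entry of -0.5 plants a
#' half-SD deficit in the latent abundance. Defaults put deficits on SST
#' interneurons (-0.5) and IT pyramidal cells (-0.45), the two subclasses
#' with the strongest reported bulk-tissue AD associations; all other
#' subclasses are left unshifted.
#'
#' @param taxonomy Taxonomy data frame.
#' @return Named numeric vector over subclasses.
#' @export
default_effect_sizes <- function(taxonomy = cortical_taxonomy()) {
  eff <- stats::setNames(rep(0, nrow(taxonomy)), taxonomy$subclass)
  eff["SST"] <- -0.5
  eff["IT"] <- -0.45
  eff
}

#' Default loadings of true proportions on neuropathology
#'
#' An 11-pathology x 19-subclass loading matrix (pathology z-units per SD of
#' the subclass's latent logit). By default only SST carries loadings:
#' negative on every amyloid- and tau-related measure, so lower SST latent
#' abundance implies greater plaque/tangle burden. IT deliberately carries
#' none, making IT a pathology-independent correlate of cognition.
#'
#' @param taxonomy Taxonomy data frame.
#' @return Matrix with rownames the 11 pathology measures and colnames the
#'   subclasses.
#' @export
default_pathology_loadings <- function(taxonomy = cortical_taxonomy()) {
  path_names <- c("amyloid", "plaq_n", "plaq_d", "tau_phf", "tangles",
                  "braak", "infarcts", "atherosclerosis", "synucleinopathy",
                  "tdp43", "hip_sclerosis")
  L <- matrix(0, length(path_names), nrow(taxonomy),
              dimnames = list(path_names, taxonomy$subclass))
  amyloid_tau <- c("amyloid", "plaq_n", "plaq_d", "tau_phf", "tangles", "braak")
  L[amyloid_tau, "SST"] <- c(-0.30, -0.30, -0.25, -0.30, -0.30, -0.25)
  L
}

#' Default longitudinal cognition model
#'
#' Coefficients generating per-subject cognitive trajectories: annual slope
#' depends on SST and IT latent abundance (protective) and on global AD
#' pathology (harmful); baseline level depends on education. Units are
#' population-SD cognition per year.
#'
#' @return A list with elements `slope_intercept`, `slope_subclass` (named
#'   vector), `slope_pathology`, `slope_sd`, `intercept_educ`, `intercept_sd`.
#' @export
default_cognition_model <- function() {
  list(slope_intercept = -0.08,
       slope_subclass = c(SST = 0.03, IT = 0.03),
       slope_pathology = -0.05,
       slope_sd = 0.03,
       intercept_educ = 0.05,
       intercept_sd = 0.30)
}

#' Generate a synthetic single-nucleus reference
#'
#' Builds a labeled nucleus-level count matrix in which each subclass owns a
#' disjoint block of designated marker genes whose mean expression is `fold`
#' times the gene's background level. Counts are negative-binomial around the
#' subclass signature scaled to a per-nucleus library size. The returned
#' truth object carries the signatures, designated markers, and the default
#' phenotype-effect configuration consumed by the cohort generators.
#'
#' @param taxonomy Taxonomy data frame (default [cortical_taxonomy()]).
#' @param n_nuclei_per_type Nuclei simulated per subclass (default 100).
#' @param n_genes Gene-universe size (default 2000).
#' @param marker_frac Fraction of genes designated as markers per subclass
#'   (default 0.01, i.e., 20 markers each at the default gene count).
#' @param fold Marker enrichment of in-type over background mean (> 1 for a
#'   usable reference; `fold = 1` generates a no-signal reference). The
#'   default 50 puts designated markers in the near-exclusive regime typical
#'   of good subclass-defining genes, whose expression is dominated by their
#'   own subclass.
#' @param dispersion Negative-binomial dispersion (0 gives Poisson counts).
#' @param nucleus_library Mean per-nucleus library size (default 5e4,
#'   emulating high-depth full-transcript sequencing).
#' @param seed Integer seed; fully determines the output.
#' @return A list with `counts` (genes x nuclei integer matrix), `labels`
#'   (subclass per nucleus), and `truth` (a `synthetic_truth` object).
#' @export
generate_reference <- function(taxonomy = cortical_taxonomy(),
                               n_nuclei_per_type = 100L,
                               n_genes = 2000L,
                               marker_frac = 0.01,
                               fold = 50,
                               dispersion = 0.05,
                               nucleus_library = 5e4,
                               seed = 1L) {
  validate_taxonomy(taxonomy)
  if (n_nuclei_per_type <= 0 || n_genes <= 0 || nucleus_library <= 0)
    stop("sizes must be positive")
  if (fold < 1) stop("fold must be >= 1")
  n_markers <- round(marker_frac * n_genes)
  K <- nrow(taxonomy)
  if (n_markers < 1 || n_markers * K > n_genes)
    stop("marker_frac incompatible with n_genes and taxonomy size")
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  base <- stats::rlnorm(n_genes, meanlog = 1, sdlog = 1)
  sig <- matrix(base, n_genes, K, dimnames = list(genes, taxonomy$subclass))
  markers <- vector("list", K)
  names(markers) <- taxonomy$subclass
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * n_markers + 1L):(k * n_markers)
    sig[idx, k] <- sig[idx, k] * fold
    markers[[k]] <- genes[idx]
  }
  counts <- matrix(0L, n_genes, K * n_nuclei_per_type)
  labels <- rep(taxonomy$subclass, each = n_nuclei_per_type)
  for (k in seq_len(K)) {
    mu <- nucleus_library * sig[, k] / sum(sig[, k])
    cols <- ((k - 1L) * n_nuclei_per_type + 1L):(k * n_nuclei_per_type)
    counts[, cols] <- rnb(n_genes * n_nuclei_per_type, rep(mu, n_nuclei_per_type),
                          dispersion)
  }
  dimnames(counts) <- list(genes,
                           sprintf("nuc%05d", seq_len(ncol(counts))))
  truth <- structure(
    list(taxonomy = taxonomy,
         signatures = sig,
         markers = markers,
         effect_sizes = default_effect_sizes(taxonomy),
         pathology_loadings = default_pathology_loadings(taxonomy),
         cognition_model = default_cognition_model(),
         params = list(n_genes = n_genes, n_markers = n_markers, fold = fold,
                       dispersion = dispersion),
         seed = seed),
    class = "synthetic_truth")
  list(counts = counts, labels = labels, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth: %d genes, %d subclasses, %d markers each\n",
              x$params$n_genes, nrow(x$taxonomy), x$params$n_markers))
  if (!is.null(x$true_proportions))
    cat(sprintf("  %d subjects with true proportion vectors\n",
                nrow(x$true_proportions)))
  invisible(x)
}

# Mean target proportions of the 19 subclasses in neocortical tissue
# (glutamatergic-dominant neurons, sizeable oligodendrocyte/astrocyte pools,
# rare vascular types). Logit-scale means of the logistic-normal model.
base_proportions <- function(taxonomy) {
  p <- c(LAMP5 = 0.030, PAX6 = 0.010, SST = 0.040, VIP = 0.040, PVALB = 0.050,
         IT = 0.250, `L4 IT` = 0.080, `L5 6 IT Car3` = 0.020,
         `L5 6 NP` = 0.020, `L5 ET` = 0.010, `L6 CT` = 0.060, L6b = 0.030,
         Astrocyte = 0.120, Oligodendrocyte = 0.150, OPC = 0.030,
         Microglia = 0.040, Endothelial = 0.010, Pericyte = 0.005,
         VLMC = 0.005)
  p <- p[taxonomy$subclass]
  if (anyNA(p)) { # non-default taxonomy: uniform
    p <- stats::setNames(rep(1 / nrow(taxonomy), nrow(taxonomy)),
                         taxonomy$subclass)
  }
  p / sum(p)
}

softmax_rows <- function(L) {
  E <- exp(L - apply(L, 1, max))
  E / rowSums(E)
}

# Draw the subject table and logistic-normal true proportions for a design.
draw_subjects <- function(truth, design, logit_sd, proportions = NULL) {
  studies <- design$studies
  subj <- do.call(rbind, lapply(studies, function(s) {
    n <- s$n_control + s$n_case + s$n_other
    data.frame(study = s$name,
               ad_label = rep(c("control", "AD", "other"),
                              c(s$n_control, s$n_case, s$n_other)),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(subj)
  subj$subject_id <- sprintf("subj%04d", seq_len(n))
  subj$age_at_death <- round(stats::rnorm(n, 85, 6), 1)
  subj$sex <- sample(c("F", "M"), n, replace = TRUE)
  subj$pmi <- round(stats::rgamma(n, shape = 2.5, scale = 3.7), 1)
  K <- nrow(truth$taxonomy)
  mu <- log(base_proportions(truth$taxonomy))
  shift_mult <- c(control = 0, AD = 1, other = 0.5)[subj$ad_label]
  Z <- matrix(stats::rnorm(n * K), n, K,
              dimnames = list(subj$subject_id, truth$taxonomy$subclass))
  logits <- matrix(mu, n, K, byrow = TRUE) + logit_sd * Z +
    logit_sd * outer(shift_mult, truth$effect_sizes[truth$taxonomy$subclass])
  P <- if (is.null(proportions)) softmax_rows(logits) else {
    stopifnot(nrow(proportions) == n, ncol(proportions) == K)
    proportions
  }
  dimnames(P) <- list(subj$subject_id, truth$taxonomy$subclass)
  # latent z for phenotype effects: standardized deviation of the realized
  # logit from its subclass mean (includes the planted AD shift)
  Zlat <- (logits - matrix(mu, n, K, byrow = TRUE)) / logit_sd
  dimnames(Zlat) <- dimnames(P)
  list(subjects = subj, proportions = P, latent_z = Zlat)
}

#' Generate multi-study bulk RNA-seq cohorts from a synthetic truth
#'
#' Draws per-subject true subclass proportions from a logistic-normal model
#' (Gaussian on logits, softmax-normalized), shifts AD subjects' logits by
#' `truth$effect_sizes` (in logit-SD units; "other" subjects receive half the
#' shift), and generates one genes x samples expected-count matrix per
#' dataset (study x region). Expected counts are proportional to the
#' proportion-weighted mixture of subclass signatures, scaled to the sample's
#' library size, perturbed by multiplicative log-normal batch effects and
#' log-linear technical-covariate effects, then sampled negative-binomially.
#'
#' @param truth A `synthetic_truth` from [generate_reference()].
#' @param design A `study_design` (default [default_study_design()]).
#' @param library_size Mean library size per sample (default 2e6).
#' @param dispersion NB dispersion (0 = Poisson).
#' @param batch_sd SD of per-(gene, batch) log-normal batch effects.
#' @param tech_sd SD of per-gene log-linear coefficients on the standardized
#'   technical covariates (RIN, PMI, percent mapped/usable bases).
#' @param logit_sd Between-subject SD of proportion logits (default 0.4).
#' @param proportions Optional subjects x subclasses matrix overriding the
#'   logistic-normal draw (rows must lie on the simplex); used for controlled
#'   experiments.
#' @param seed Integer seed.
#' @return A list with `counts` (named list of genes x samples matrices, one
#'   per dataset), `metadata` (one row per sample: ids, dataset, study,
#'   region, AD label, batch and technical covariates, demographics), and
#'   `truth` (the input truth augmented with `subjects`, `true_proportions`,
#'   `latent_z`, and `ad_status`).
#' @export
generate_bulk_cohort <- function(truth,
                                 design = default_study_design(),
                                 library_size = 2e6,
                                 dispersion = 0.05,
                                 batch_sd = 0.1,
                                 tech_sd = 0.03,
                                 logit_sd = 0.4,
                                 proportions = NULL,
                                 seed = 7L) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(design, "study_design"))
  if (library_size <= 0) stop("library_size must be positive")
  set.seed(seed)
  drawn <- draw_subjects(truth, design, logit_sd, proportions)
  subj <- drawn$subjects
  P <- drawn$proportions
  sig <- truth$signatures
  if (!identical(colnames(sig), colnames(P)))
    stop("dimension mismatch between signatures and proportion columns")
  genes <- rownames(sig)
  counts <- list()
  meta <- list()
  for (s in design$studies) {
    in_study <- subj$study == s$name
    ids <- subj$subject_id[in_study]
    for (r in s$regions) {
      dataset <- paste(s$name, r, sep = "_")
      n_i <- length(ids)
      Pd <- P[ids, , drop = FALSE]
      # mixture fractions per sample
      M <- sig %*% t(Pd)                      # genes x samples
      M <- sweep(M, 2, colSums(M), "/")
      n_batches <- max(2L, ceiling(n_i / 60))
      batch <- sample(seq_len(n_batches), n_i, replace = TRUE)
      B <- matrix(stats::rnorm(length(genes) * n_batches, 0, batch_sd),
                  length(genes), n_batches)
      rin <- round(stats::rnorm(n_i, 7, 1), 1)
      pct_mapped <- round(stats::rnorm(n_i, 92, 3), 2)
      pct_usable <- round(stats::rnorm(n_i, 85, 5), 2)
      tech <- scale(cbind(rin, subj$pmi[in_study], pct_mapped, pct_usable))
      G <- matrix(stats::rnorm(length(genes) * 4, 0, tech_sd), length(genes), 4)
      lib <- library_size * exp(stats::rnorm(n_i, 0, 0.3))
      logmult <- B[, batch, drop = FALSE] + G %*% t(tech)
      mu <- sweep(M * exp(logmult), 2, lib / colSums(M * exp(logmult)), "*")
      cnt <- matrix(rnb(length(mu), as.vector(mu), dispersion),
                    nrow(mu), ncol(mu))
      sample_ids <- paste(dataset, ids, sep = ".")
      dimnames(cnt) <- list(genes, sample_ids)
      counts[[dataset]] <- cnt
      meta[[dataset]] <- data.frame(
        sample_id = sample_ids, subject_id = ids, dataset = dataset,
        study = s$name, region = r,
        ad_label = subj$ad_label[in_study],
        batch = paste(dataset, batch, sep = "_b"),
        rin = rin, pmi = subj$pmi[in_study],
        pct_mapped = pct_mapped, pct_usable = pct_usable,
        age_at_death = subj$age_at_death[in_study],
        sex = subj$sex[in_study],
        stringsAsFactors = FALSE)
    }
  }
  truth$subjects <- subj
  truth$true_proportions <- P
  truth$latent_z <- drawn$latent_z
  truth$ad_status <- stats::setNames(as.integer(subj$ad_label == "AD"),
                                     subj$subject_id)
  list(counts = counts, metadata = do.call(rbind, c(meta, make.row.names = FALSE)),
       truth = truth)
}

#' Generate a nucleus-level cohort from the same ground truth
#'
#' Samples subjects from the truth's subject table and draws each subject's
#' nucleus subclass labels multinomially from that subject's true proportion
#' vector, emulating case/control single-nucleus datasets collected from a
#' subset of a bulk cohort.
#'
#' @param truth A `synthetic_truth` augmented by [generate_bulk_cohort()]
#'   (must carry `true_proportions`).
#' @param n_subjects Number of subjects to sample (case/control subjects are
#'   preferred; default 60).
#' @param nuclei_per_subject Integer range (length-2) of nuclei per subject,
#'   drawn uniformly; a single value fixes the count.
#' @param n_datasets Number of sn datasets the subjects are split across.
#' @param seed Integer seed.
#' @return A list with `annotations` (data frame: subject_id, nucleus_id,
#'   subclass, sn_dataset) and `subjects` (per-subject metadata incl. AD
#'   label, age, sex, PMI).
#' @export
generate_sn_cohort <- function(truth, n_subjects = 60L,
                               nuclei_per_subject = c(500L, 2000L),
                               n_datasets = 3L, seed = 3L) {
  if (is.null(truth$true_proportions) || nrow(truth$true_proportions) == 0)
    stop("truth carries no subjects; run generate_bulk_cohort first")
  set.seed(seed)
  subj <- truth$subjects
  cc <- subj$subject_id[subj$ad_label %in% c("control", "AD")]
  pool <- if (length(cc) >= n_subjects) cc else subj$subject_id
  if (n_subjects > length(pool)) stop("n_subjects exceeds available subjects")
  ids <- sample(pool, n_subjects)
  rng <- rep(nuclei_per_subject, length.out = 2)
  K <- ncol(truth$true_proportions)
  out <- vector("list", n_subjects)
  sn_dataset <- paste0("snD", ((seq_len(n_subjects) - 1L) %% n_datasets) + 1L)
  for (i in seq_len(n_subjects)) {
    n_nuc <- if (rng[1] == rng[2]) rng[1] else
      sample(seq(rng[1], rng[2]), 1)
    draws <- stats::rmultinom(1, n_nuc, truth$true_proportions[ids[i], ])
    out[[i]] <- data.frame(
      subject_id = ids[i],
      nucleus_id = sprintf("%s_n%05d", ids[i], seq_len(n_nuc)),
      subclass = rep(colnames(truth$true_proportions), draws[, 1]),
      sn_dataset = sn_dataset[i],
      stringsAsFactors = FALSE)
  }
  meta <- subj[match(ids, subj$subject_id),
               c("subject_id", "study", "ad_label", "age_at_death", "sex", "pmi")]
  meta$sn_dataset <- sn_dataset
  rownames(meta) <- NULL
  list(annotations = do.call(rbind, c(out, make.row.names = FALSE)),
       subjects = meta)
}

#' Generate neuropathology, longitudinal cognition, and demographics
#'
#' Produces the phenotype battery the association modules consume. The 11
#' pathology measures load linearly on the subjects' latent subclass
#' abundances (`truth$pathology_loadings`; by default SST is negatively
#' loaded on every amyloid/tau measure). Each subject's cognitive trajectory
#' is linear in years with a slope depending on latent subclass abundance
#' and global pathology plus Gaussian noise; 17 per-visit test scores across
#' 5 domains are emitted around the true composite. Demographics (education,
#' APOE e4) are generated independently.
#'
#' @param truth Truth augmented by [generate_bulk_cohort()].
#' @param n_visits Number of annual visits (>= 2).
#' @param noise_sd SD of visit-level composite noise (default 0.1).
#' @param pathology_loadings Optional override of `truth$pathology_loadings`.
#' @param cognition_model Optional override of `truth$cognition_model`.
#' @param seed Integer seed.
#' @return A `phenotype_table`: list with `subjects` (one row per subject:
#'   demographics, APOE e4 dose, 11 pathologies, Braak stage, CERAD
#'   category, clinical cognitive diagnosis, CDR, cognition at last visit),
#'   `visits` (long table: subject_id, visit, year, composite, test_01..17),
#'   `true_slopes` (named vector), and `domains` (test-to-domain map).
#' @export
generate_phenotypes <- function(truth, n_visits = 8L, noise_sd = 0.1,
                                pathology_loadings = NULL,
                                cognition_model = NULL, seed = 13L) {
  if (is.null(truth$latent_z))
    stop("truth carries no subjects; run generate_bulk_cohort first")
  if (n_visits < 2) stop("n_visits must be >= 2 for slope estimation")
  set.seed(seed)
  L <- if (is.null(pathology_loadings)) truth$pathology_loadings else pathology_loadings
  cm <- if (is.null(cognition_model)) truth$cognition_model else cognition_model
  Z <- truth$latent_z
  n <- nrow(Z)
  subj <- truth$subjects
  stopifnot(identical(subj$subject_id, rownames(Z)))
  path <- Z %*% t(L[, colnames(Z), drop = FALSE]) +
    matrix(stats::rnorm(n * nrow(L)), n, nrow(L))
  colnames(path) <- rownames(L)
  # ordinal / bounded recodings of selected measures
  path_df <- as.data.frame(path)
  path_df$braak <- as.integer(cut(path[, "braak"],
                                  breaks = stats::quantile(path[, "braak"],
                                                           c(0, .05, .15, .35, .6, .8, .95, 1)),
                                  labels = FALSE, include.lowest = TRUE)) - 1L
  path_df$infarcts <- as.integer(path[, "infarcts"] > stats::quantile(path[, "infarcts"], 0.7))
  path_df$atherosclerosis <- as.integer(cut(path[, "atherosclerosis"],
                                            breaks = stats::quantile(path[, "atherosclerosis"], c(0, .4, .7, .9, 1)),
                                            labels = FALSE, include.lowest = TRUE)) - 1L
  path_df$hip_sclerosis <- as.integer(path[, "hip_sclerosis"] >
                                        stats::quantile(path[, "hip_sclerosis"], 0.9))
  global_path <- rowMeans(path[, c("plaq_d", "plaq_n", "tangles")])
  cerad_q <- stats::quantile(path_df$plaq_n, c(0, .35, .55, .75, 1))
  cerad <- cut(path_df$plaq_n, breaks = cerad_q, include.lowest = TRUE,
               labels = c("none", "sparse", "moderate", "frequent"))
  educ <- round(stats::rnorm(n, 16, 3))
  apoe4 <- stats::rbinom(n, 2, 0.25)
  slope_eff <- as.vector(Z[, names(cm$slope_subclass), drop = FALSE] %*%
                           cm$slope_subclass)
  slope <- cm$slope_intercept + slope_eff +
    cm$slope_pathology * as.vector(scale(global_path)) +
    stats::rnorm(n, 0, cm$slope_sd)
  intercept <- cm$intercept_educ * as.vector(scale(educ)) +
    stats::rnorm(n, 0, cm$intercept_sd)
  years <- seq_len(n_visits) - 1L
  n_tests <- 17L
  domains <- rep(paste0("domain", 1:5), c(4, 4, 3, 3, 3))
  visits <- expand.grid(subject_id = subj$subject_id, visit = seq_len(n_visits),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  visits <- visits[order(visits$subject_id, visits$visit), , drop = FALSE]
  visits$year <- visits$visit - 1L
  idx <- match(visits$subject_id, subj$subject_id)
  g_true <- intercept[idx] + slope[idx] * visits$year
  visits$composite <- g_true + stats::rnorm(nrow(visits), 0, noise_sd)
  dom_noise <- matrix(stats::rnorm(nrow(visits) * 5, 0, 0.15), ncol = 5)
  tests <- matrix(NA_real_, nrow(visits), n_tests)
  for (t in seq_len(n_tests)) {
    d <- match(domains[t], paste0("domain", 1:5))
    tests[, t] <- g_true + dom_noise[, d] + stats::rnorm(nrow(visits), 0, 0.3)
  }
  colnames(tests) <- sprintf("test_%02d", seq_len(n_tests))
  visits <- cbind(visits, as.data.frame(tests))
  rownames(visits) <- NULL
  last <- visits[visits$visit == n_visits, c("subject_id", "composite")]
  cog_death <- last$composite[match(subj$subject_id, last$subject_id)]
  cogdx <- ifelse(cog_death < stats::quantile(cog_death, 0.35), 4L, 1L)
  cdr <- ifelse(cogdx == 4L, 1, 0)
  subjects <- cbind(
    subj[, c("subject_id", "study", "ad_label", "age_at_death", "sex", "pmi")],
    data.frame(educ = educ, apoe4 = apoe4,
               age_baseline = subj$age_at_death - (n_visits - 1L)),
    path_df,
    data.frame(cerad = cerad, cogdx = cogdx, cdr = cdr,
               cog_at_death = cog_death, stringsAsFactors = FALSE))
  rownames(subjects) <- NULL
  structure(list(subjects = subjects, visits = visits,
                 true_slopes = stats::setNames(slope, subj$subject_id),
                 domains = stats::setNames(domains, colnames(tests)),
                 seed = seed),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("Phenotype table: %d subjects, %d visit rows, %d cognitive tests\n",
              nrow(x$subjects), nrow(x$visits), length(x$domains)))
  invisible(x)
}

#' Names of the 11 brain-wide neuropathology measures
#' @return Character vector of length 11.
#' @export
pathology_measures <- function() {
  rownames(default_pathology_loadings())
}
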