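# End-to-end pipeline orchestration over the synthetic cohort, with a
# serializable configuration and a hashed output manifest.

#' Default pipeline configuration
#'
#' Collects every tunable of every stage into one serializable list. The
#' global `seed` is expanded into per-stage seeds by a fixed counter scheme
#' (stage i uses `seed * 100 + i`), giving stage-level reproducibility
#' without seed collisions.
#'
#' @param seed Global integer seed.
#' @param outdir Output directory for result tables and the manifest.
#' @param n_subjects Total subjects of the synthetic design.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("ctp_run_"),
                            n_subjects = 400L) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    synthetic = list(n_subjects = n_subjects, n_nuclei_per_type = 100L,
                     n_genes = 2000L, marker_frac = 0.01, fold = 50,
                     reference_dispersion = 0.05, bulk_dispersion = 0.05,
                     library_size = 2e6, batch_sd = 0.1, tech_sd = 0.03,
                     logit_sd = 0.4, sn_subjects = 60L,
                     sn_nuclei = c(500L, 2000L), n_visits = 8L,
                     noise_sd = 0.1),
    markers = list(fold_threshold = 4, min_detect = 0.3, top_n = 50,
                   pseudocount = 1, min_markers = 3),
    preprocess = list(median_threshold = 15, n_components = 5, k_iqr = 3,
                      winsor_offset = 0.5, cpm_offset = 0.5, span = 0.5),
    snctp = list(min_nuclei = 100),
    associate = list(n_boot = 100),
    mediate = list(n_draws = 1000)),
    class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips losslessly through serialization.
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  template <- pipeline_config()
  missing <- setdiff(names(template), names(cfg))
  if (length(missing))
    stop("config is missing field(s): ", paste(missing, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

stage_seed <- function(config, i) config$seed * 100L + i

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes, in order: reference simulation, marker selection, bulk cohort
#' simulation, per-dataset preprocessing, per-dataset rCTP estimation,
#' cross-cohort mega-analysis, sn cohort simulation + snCTP + sn models,
#' bulk/sn effect concordance, phenotype generation + derivation, the
#' phenotype battery, variance partitioning for SST and IT, and the four
#' mediation models. Result tables are written as TSV/JSON under
#' `config$outdir` along with a manifest recording seeds, per-stage
#' dimensions, and an md5 hash of every output file. Any stage failure
#' halts with the stage name.
#'
#' @param config A `pipeline_config`.
#' @param write_outputs Write tables + manifest to `config$outdir`
#'   (default TRUE; FALSE returns results invisibly without touching disk).
#' @return A list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), write_outputs = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  syn <- config$synthetic
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ref <- stage("simulate_reference",
               generate_reference(n_nuclei_per_type = syn$n_nuclei_per_type,
                                  n_genes = syn$n_genes,
                                  marker_frac = syn$marker_frac,
                                  fold = syn$fold,
                                  dispersion = syn$reference_dispersion,
                                  seed = stage_seed(config, 1L)))
  mk <- config$markers
  markers <- stage("markers",
                   select_markers(ref$counts, ref$labels,
                                  fold_threshold = mk$fold_threshold,
                                  min_detect = mk$min_detect,
                                  top_n = mk$top_n,
                                  pseudocount = mk$pseudocount))
  bulk <- stage("simulate_bulk",
                generate_bulk_cohort(ref$truth,
                                     design = default_study_design(syn$n_subjects),
                                     library_size = syn$library_size,
                                     dispersion = syn$bulk_dispersion,
                                     batch_sd = syn$batch_sd,
                                     tech_sd = syn$tech_sd,
                                     logit_sd = syn$logit_sd,
                                     seed = stage_seed(config, 2L)))
  truth <- bulk$truth
  pp <- config$preprocess
  norm <- stage("preprocess", lapply(names(bulk$counts), function(ds) {
    meta <- bulk$metadata[bulk$metadata$dataset == ds, ]
    covs <- meta[, c("batch", "rin", "pmi", "pct_mapped", "pct_usable")]
    preprocess_counts(bulk$counts[[ds]], covs,
                      median_threshold = pp$median_threshold,
                      n_components = pp$n_components, k_iqr = pp$k_iqr,
                      winsor_offset = pp$winsor_offset,
                      cpm_offset = pp$cpm_offset, span = pp$span)
  }))
  names(norm) <- names(bulk$counts)
  qc_sets <- lapply(norm, function(x) rownames(x$log_expr))
  markers_h <- stage("harmonize",
                     harmonize_markers(markers, qc_sets,
                                       min_markers = mk$min_markers))
  rctp <- stage("rctp", lapply(norm, function(x)
    estimate_all(x$log_expr, markers_h)))
  # stack rCTPs into a long table joined to sample metadata
  long <- do.call(rbind, lapply(names(rctp), function(ds) {
    sc <- rctp[[ds]]$scores
    meta <- bulk$metadata[match(rownames(sc), bulk$metadata$sample_id), ]
    do.call(rbind, lapply(colnames(sc), function(k)
      data.frame(cell_type = k, rctp = sc[, k], meta,
                 stringsAsFactors = FALSE, row.names = NULL)))
  }))
  long$ad <- ifelse(long$ad_label == "AD", 1L,
                    ifelse(long$ad_label == "control", 0L, NA_integer_))
  mega <- stage("mega_analysis", {
    res <- do.call(rbind, lapply(unique(long$cell_type), function(k)
      mega_model(long[long$cell_type == k & !is.na(long$ad), ],
                 cell_type = k)))
    adjust_pvalues(res, family = "bulk_case_control")
  })

  sn <- stage("simulate_sn",
              generate_sn_cohort(truth, n_subjects = syn$sn_subjects,
                                 nuclei_per_subject = syn$sn_nuclei,
                                 seed = stage_seed(config, 3L)))
  snctp <- stage("snctp",
                 compute_snctp(sn$annotations,
                               subclasses = truth$taxonomy$subclass,
                               min_nuclei = config$snctp$min_nuclei))
  sn_meta <- sn$subjects[match(rownames(snctp$percents),
                               sn$subjects$subject_id), ]
  sn_res <- stage("sn_models", {
    res <- do.call(rbind, lapply(colnames(snctp$percents), function(k) {
      d <- data.frame(snctp = snctp$percents[, k],
                      ad = as.integer(sn_meta$ad_label == "AD"),
                      dataset = sn_meta$sn_dataset,
                      age_at_death = sn_meta$age_at_death,
                      sex = sn_meta$sex, pmi = sn_meta$pmi)
      sn_model(d[sn_meta$ad_label %in% c("control", "AD"), ], cell_type = k)
    }))
    adjust_pvalues(res, family = "sn_case_control")
  })
  concord <- stage("concordance", {
    rosmap_ds <- names(rctp)[1]
    sc <- rctp[[rosmap_ds]]$scores
    rownames(sc) <- bulk$metadata$subject_id[match(rownames(sc),
                                                   bulk$metadata$sample_id)]
    bulk_sn_concordance(sc, snctp,
                        effects_bulk = stats::setNames(mega$beta, mega$cell_type),
                        effects_sn = stats::setNames(sn_res$beta, sn_res$cell_type))
  })

  pheno <- stage("simulate_phenotypes",
                 generate_phenotypes(truth, n_visits = syn$n_visits,
                                     noise_sd = syn$noise_sd,
                                     seed = stage_seed(config, 4L)))
  derived <- stage("phenotypes", {
    subj <- pheno$subjects
    ref_base <- baseline_reference(pheno$visits, names(pheno$domains))
    vis <- compute_global_cognition(pheno$visits, pheno$domains, ref_base)
    slopes <- estimate_cognitive_slope(vis)
    subj$cognitive_slope <- slopes[subj$subject_id]
    rc <- compute_residual_cognition(subj)
    subj$residual_cognition <- rc[subj$subject_id]
    subj$global_pathology <- compute_global_pathology(subj)
    subj
  })
  # subject-level rCTPs from the first (largest) dataset for the battery
  battery_scores <- stage("battery_scores", {
    sc <- rctp[[names(rctp)[1]]]$scores
    rownames(sc) <- bulk$metadata$subject_id[match(rownames(sc),
                                                   bulk$metadata$sample_id)]
    sc
  })
  battery <- stage("battery", phenotype_battery(battery_scores, derived))
  varpart <- stage("varpart", {
    idx <- match(derived$subject_id, rownames(battery_scores))
    d <- cbind(derived, SST = battery_scores[idx, "SST"],
               IT = battery_scores[idx, "IT"])
    base_covs <- c(pathology_measures(), "age_at_death", "sex", "educ")
    list(IT = variance_explained(d, "cog_at_death", base_covs, "IT",
                                 n_boot = config$associate$n_boot,
                                 seed = stage_seed(config, 5L)),
         SST = variance_explained(d, "cog_at_death", base_covs, "SST",
                                  n_boot = config$associate$n_boot,
                                  seed = stage_seed(config, 5L)))
  })
  mediation <- stage("mediation", {
    idx <- match(derived$subject_id, rownames(battery_scores))
    d <- data.frame(SST = battery_scores[idx, "SST"],
                    IT = battery_scores[idx, "IT"],
                    global_pathology = derived$global_pathology,
                    cognition = derived$cog_at_death,
                    age_at_death = derived$age_at_death,
                    sex = derived$sex, educ = derived$educ,
                    apoe4 = derived$apoe4)
    run_four_models(d, n_draws = config$mediate$n_draws,
                    seed = stage_seed(config, 6L))
  })

  results <- list(truth = truth, markers = markers_h, normalized = norm,
                  rctp = rctp, mega = mega, snctp = snctp, sn_results = sn_res,
                  concordance = concord, phenotypes = derived,
                  battery = battery, varpart = varpart, mediation = mediation)

  manifest <- list(seed = config$seed,
                   stages = list(
                     simulate_reference = dim(ref$counts),
                     markers = lengths(markers_h$markers),
                     simulate_bulk = vapply(bulk$counts, ncol, integer(1)),
                     preprocess = vapply(norm, function(x) ncol(x$log_expr), integer(1)),
                     rctp = vapply(rctp, function(x) nrow(x$scores), integer(1)),
                     mega_analysis = nrow(mega),
                     snctp = dim(snctp$percents),
                     phenotypes = nrow(derived),
                     battery = nrow(battery),
                     varpart = 2L,
                     mediation = length(mediation)))
  if (write_outputs) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    write_markers_tsv(markers_h, out("markers.tsv"))
    utils::write.table(mega, out("mega_analysis.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sn_res, out("sn_analysis.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(battery, out("battery.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(derived, out("phenotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (ds in names(rctp)) write_rctp_tsv(rctp[[ds]],
                                           out(paste0("rctp_", ds, ".tsv")))
    jsonlite::write_json(
      lapply(mediation, function(m)
        list(acme = m$acme[c("estimate", "p")], ade = m$ade[c("estimate", "p")],
             total = m$total[c("estimate", "p")])),
      out("mediation.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- list.files(config$outdir, full.names = TRUE)
    manifest$files <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  results$manifest <- manifest
  invisible(results)
}
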