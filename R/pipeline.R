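#' Validated pipeline configuration
#'
#' One object holding every threshold the pipeline applies, echoed into
#' the run manifest so no cutoff is implicit. Unknown keys are rejected.
#' Defaults are the analysis' published operating points: hit and
#' association significance 0.05, recurrence across >= 2 screens,
#' inactivation/activation z cuts at -/+2, subtype log2 OR cut 1.5,
#' driver-network |lfc| cut 0.25, proliferation-independence CERES
#' window [-0.25, 0.25], panel prefilter at >= 100 related features, and
#' 500 extreme genes for XSum.
#'
#' @param ... Named overrides of the defaults.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    alpha = 0.05, min_screens = 2, z_cut_inactivation = -2,
    z_cut_activation = 2, lor_cut = 1.5, lfc_cut = 0.25,
    ceres_low = -0.25, ceres_high = 0.25, min_related_features = 100,
    n_extreme = 500, min_events = 5, seed = 1)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown pipeline_config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "pipeline_config")
}

#' Run the integrated analysis end-to-end on a synthetic study
#'
#' Executes the stages in dependency order on generated inputs with
#' planted ground truth: screen integration, functional-status calling,
#' signature scoring, signature association and functional filtering,
#' feature counting, CTIS scoring with survival evaluation, and ensemble
#' drug ranking. When `out_dir` is given, each stage writes its table
#' plus a JSON manifest recording every threshold; a rerun with the same
#' config and spec is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param spec A [synth_spec()] describing the study to generate.
#' @param out_dir Optional output directory.
#' @return List with each stage's outputs and the planted `truth`.
#' @export
run_pipeline <- function(config = pipeline_config(), spec = synth_spec(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  scr <- make_screens(spec, seed = seed)
  classified <- lapply(scr$hits, classify_hits, alpha = config$alpha)
  catalog <- build_catalog(classified, min_screens = config$min_screens)

  sim <- make_cohort(spec, seed = seed)
  cohort <- sim$cohort
  status <- build_status_matrix(cohort, catalog$gene, "inactivation",
                                z_cut = config$z_cut_inactivation)

  scores <- signature_scores(cohort, sim$truth$gene_sets)
  assoc <- associate_signatures(scores, status,
                                cohort$annotations$cancer_type,
                                min_events = config$min_events)
  functional <- filter_functional_regulators(assoc, catalog,
                                             alpha = config$alpha)

  feat_catalog <- read_feature_catalog()
  abundance <- feature_abundance(cohort$expr_z, feat_catalog)
  feat_assoc <- associate_features(abundance, status,
                                   cohort$annotations$cancer_type,
                                   min_events = config$min_events)
  related <- count_related_features(feat_assoc, catalog, alpha = config$alpha)

  ctis <- ctis_score(cohort$expr)
  surv <- make_survival(spec, ctis, seed = seed)
  surv$age <- cohort$annotations$age
  surv$cancer_type <- cohort$annotations$cancer_type
  ctis_cox <- cox_screen(ctis, surv)
  ctis_auc <- roc_auc(ctis, surv$response %in% c("CR", "PR"))
  ctis_cindex <- concordance_index(ctis, surv$time, surv$event)

  query <- build_query_signature(
    sensitizers = functional$gene[functional$role == "sensitizer"],
    resistors = functional$gene[functional$role == "resistor"])
  dm <- make_drug_matrix(spec, query, seed = seed)
  dm_filtered <- filter_drugs_by_phase(dm$matrix, dm$annotations)
  drug_ranking <- rank_aggregate(query, dm_filtered,
                                 n_extreme = config$n_extreme)

  result <- list(
    catalog = catalog, status = status, scores = scores, assoc = assoc,
    functional = functional, related_features = related,
    ctis = ctis, survival = surv,
    ctis_eval = list(cox = ctis_cox, auc = ctis_auc, cindex = ctis_cindex),
    query = query, drug_ranking = drug_ranking,
    truth = list(cohort = sim$truth, screens = scr$truth,
                 drugs = dm$truth),
    config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) utils::write.table(
      df, file.path(out_dir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    w(catalog, "catalog.tsv")
    write_matrix_tsv(unclass(status), file.path(out_dir, "status.tsv"))
    w(cbind(sample = rownames(scores), scores), "scores.tsv")
    w(assoc, "associations.tsv")
    w(functional, "functional_regulators.tsv")
    w(related, "related_feature_counts.tsv")
    w(data.frame(sample = names(ctis), ctis = ctis), "ctis.tsv")
    w(drug_ranking, "drug_ranking.tsv")
    manifest <- list(thresholds = unclass(config),
                     stages = c("integrate", "status", "score", "associate",
                                "filter", "features", "ctis", "drugs"),
                     outputs = list.files(out_dir, pattern = "\\.tsv$"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(result)
}
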