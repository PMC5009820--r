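# End-to-end orchestration: simulate (or score files) -> select -> cluster ->
# characterize -> classify, writing diffable plain-text artifacts and a run
# manifest so a rerun with the same config reproduces identical outputs.

#' Pipeline configuration
#'
#' Either a synthetic cohort is generated (`synthetic` given) or variant
#' files are scored (`vcf`, `annotations`, `clinical` paths given).
#'
#' @param out_dir output directory for all artifacts.
#' @param synthetic a [synthetic_config()], or `NULL` to read files.
#' @param vcf,annotations,clinical input paths (minimal VCF, annotation TSV,
#'   clinical TSV) when no synthetic config is given.
#' @param maf_threshold common-polymorphism cutoff (default 0.05).
#' @param gene_grid,k_grid model-selection grids (defaults `c(50, 100)` and
#'   `2:5`).
#' @param runs_per_cell NMF runs per grid cell (default 100).
#' @param classifier classifier plugin (default random forest).
#' @param k_top_features genes selected per CV fold (default 500, capped).
#' @param n_folds CV folds (default 10).
#' @param n_perm permutation-test shuffles; 0 skips the permutation test
#'   (default 0 — the test re-runs the full cross-validation per shuffle).
#' @param seed master seed propagated deterministically to every stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, synthetic = NULL, vcf = NULL,
                            annotations = NULL, clinical = NULL,
                            maf_threshold = 0.05,
                            gene_grid = c(50, 100), k_grid = 2:5,
                            runs_per_cell = 100L,
                            classifier = classifier_random_forest(),
                            k_top_features = 500L, n_folds = 10L,
                            n_perm = 0L, seed = 1L) {
  if (is.null(synthetic) &&
      (is.null(vcf) || is.null(annotations) || is.null(clinical))) {
    stop("give either a synthetic config or vcf + annotations + clinical ",
         "paths", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain the mutation score matrix and clinical table (synthetic
#' cohort or filtered/scored variant files); (2) rank genes by variance; (3)
#' scan gene-count x rank configurations by consensus NMF and silhouette; (4)
#' characterize the selected clustering by stage distribution, exact stage
#' enrichment, and differentially mutated genes between the most
#' early-enriched and most late-enriched clusters; (5) cross-validate a
#' cluster classifier (and optionally permutation-test it). Every artifact is
#' a TSV/JSON file under `config$out_dir`; `manifest.json` records seeds, the
#' applied score offset, filter audit, selected model, and file checksums.
#'
#' @param config a [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(seed = config$seed,
                   r_version = as.character(getRversion()))

  # stage 1: matrix + clinical
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    mat <- cohort$score_matrix
    clinical <- cohort$stage_table
    manifest$input <- "synthetic"
    manifest$score_offset <- attr(mat, "offset")
  } else {
    records <- read_vcf_records(config$vcf)
    annotations <- utils::read.delim(config$annotations)
    clinical <- utils::read.delim(config$clinical,
                                  colClasses = "character")
    mat <- score_matrix(records, annotations,
                        maf_threshold = config$maf_threshold,
                        patients = sort(unique(clinical$patient_id)))
    manifest$input <- list(vcf = config$vcf,
                           annotations = config$annotations,
                           clinical = config$clinical)
    manifest$score_offset <- attr(mat, "offset")
    manifest$filter_audit <- as.list(attr(mat, "filter_audit"))
  }
  mat <- drop_empty_genes(mat)
  manifest$zero_fraction <- zero_fraction(mat)
  write_matrix_tsv(mat, out("score_matrix.tsv"))

  # stage 2: variance ranking
  ranking <- rank_by_variance(mat)
  write_tsv_file(ranking, out("variance_ranking.tsv"))

  # stage 3: consensus NMF model scan
  scan <- scan_models(mat, config$gene_grid, config$k_grid,
                      runs_per_cell = config$runs_per_cell,
                      seed = derive_seed(config$seed, 31L))
  write_tsv_file(scan$grid, out("scan_grid.tsv"))
  cons <- scan$best$consensus
  write_matrix_tsv(cons, out("consensus_matrix.tsv"))
  labels <- scan$best$labels
  write_tsv_file(data.frame(patient_id = names(labels), cluster = labels),
                 out("assignments.tsv"))
  jsonlite::write_json(
    list(selected = as.list(scan$selected),
         average_silhouette_width = scan$best$silhouette$average_width,
         per_sample = scan$best$silhouette$s),
    out("silhouette.json"), auto_unbox = TRUE, digits = NA)
  manifest$selected_model <- as.list(scan$selected)

  # stage 4: characterization
  stage_tab <- stage_by_cluster(labels, clinical)
  write_tsv_file(stage_tab, out("stage_by_cluster.tsv"))
  enrich_p <- tryCatch(stage_enrichment_exact(stage_tab),
                       error = function(e) NA_real_)
  ok <- stage_tab$n_late > 0 & !is.na(stage_tab$ratio)
  early_cl <- stage_tab$cluster[which.max(ifelse(ok, stage_tab$ratio, -Inf))]
  late_cl <- stage_tab$cluster[which.min(ifelse(ok, stage_tab$ratio, Inf))]
  diff <- differential_mutation(
    mat,
    group_a = names(labels)[labels == late_cl],
    group_b = names(labels)[labels == early_cl]
  )
  write_tsv_file(diff, out("differential_genes.tsv"))
  jsonlite::write_json(
    list(exact_p = enrich_p,
         excluded_unknown = attr(stage_tab, "excluded_unknown"),
         early_enriched_cluster = early_cl, late_enriched_cluster = late_cl,
         n_significant_genes = sum(diff$significant)),
    out("enrichment.json"), auto_unbox = TRUE, digits = NA)
  manifest$stage_enrichment_p <- enrich_p

  # stage 5: classification
  X <- t(mat)
  cv <- cross_validate(X, labels, classifier = config$classifier,
                       n_folds = config$n_folds,
                       k_top = min(config$k_top_features, ncol(X)),
                       seed = derive_seed(config$seed, 53L))
  jsonlite::write_json(
    list(accuracy = cv$accuracy, confusion = as.data.frame.matrix(cv$confusion),
         per_class = cv$per_class, macro = cv$macro, auc = as.list(cv$auc)),
    out("cv_report.json"), auto_unbox = TRUE, digits = NA)
  for (cl in names(cv$roc)) {
    write_tsv_file(cv$roc[[cl]], out(sprintf("roc_class%s.tsv", cl)))
  }
  manifest$cv_accuracy <- cv$accuracy
  if (config$n_perm > 0) {
    perm <- permutation_test(X, labels, classifier = config$classifier,
                             n_perm = config$n_perm,
                             n_folds = config$n_folds,
                             k_top = min(config$k_top_features, ncol(X)),
                             seed = derive_seed(config$seed, 71L))
    write_tsv_file(data.frame(shuffle = seq_len(perm$n_perm),
                              accuracy = perm$perm_accuracies),
                   out("permutation_trace.tsv"))
    jsonlite::write_json(
      list(observed_accuracy = perm$observed_accuracy,
           count_better = perm$count_better, p_value = perm$p_value,
           p_label = perm$p_label, n_perm = perm$n_perm),
      out("permutation.json"), auto_unbox = TRUE, digits = NA)
    manifest$permutation_p <- perm$p_value
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- setdiff(files, out("manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
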