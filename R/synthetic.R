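# Synthetic cohort generator.
#
# Emulates the data regime of an exome somatic-mutation burden study: a very
# sparse (~96% zeros) non-negative gene x patient score matrix with
# heavy-tailed per-event C-scores, k planted patient clusters marked by
# cluster-specific signature genes, and clinical stage labels whose early:late
# odds differ by cluster. Every downstream stage of the pipeline is testable
# against the planted truth without any patient data.

#' Configuration for a synthetic mutation cohort
#'
#' @param n_genes,n_patients matrix dimensions.
#' @param n_clusters number of planted clusters (>= 2).
#' @param background_sparsity target zero fraction of the matrix (default
#'   0.96, the regime typical of exome somatic burden matrices).
#' @param signature_genes_per_cluster signature genes planted per cluster;
#'   signature gene sets are disjoint across clusters.
#' @param signature_hit_prob probability a signature gene is mutated in a
#'   patient of its own cluster (on top of the background rate).
#' @param background_hit_prob probability any gene is mutated in any patient;
#'   `NULL` (default) derives it from `background_sparsity` given the
#'   signature structure, so the realized zero fraction matches the target in
#'   expectation.
#' @param score_shape,score_scale gamma parameters of the heavy-tailed
#'   positive per-event score magnitude (defaults 2 and 8).
#' @param score_offset constant subtracted from the gamma draw so raw C-scores
#'   can be negative, as CADD raw scores are (default 3).
#' @param early_late_odds per-cluster odds of early (stage I/II) vs late
#'   (stage III/IV) disease; default is a geometric gradient from 3.74 down to
#'   1.58 across clusters, so the first cluster is early-enriched and the last
#'   late-enriched.
#' @param unknown_stage_prob probability a patient's stage is missing
#'   (default 5/358).
#' @param seed integer RNG seed; one master stream split into substreams for
#'   events, scores, stages and variant-record annotation so that, e.g.,
#'   adding genes does not perturb the stage labels.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 200, n_patients = 90, n_clusters = 3,
                             background_sparsity = 0.96,
                             signature_genes_per_cluster = 6,
                             signature_hit_prob = 0.7,
                             background_hit_prob = NULL,
                             score_shape = 2, score_scale = 8,
                             score_offset = 3,
                             early_late_odds = NULL,
                             unknown_stage_prob = 5 / 358,
                             seed = 1L) {
  stopifnot_count(n_genes, "n_genes")
  stopifnot_count(n_patients, "n_patients")
  stopifnot_count(n_clusters, "n_clusters", min = 2L)
  stopifnot_count(signature_genes_per_cluster, "signature_genes_per_cluster",
                  min = 0L)
  stopifnot_prob(background_sparsity, "background_sparsity")
  stopifnot_prob(signature_hit_prob, "signature_hit_prob")
  stopifnot_prob(unknown_stage_prob, "unknown_stage_prob")
  if (n_clusters > n_patients) {
    stop("n_clusters must not exceed n_patients", call. = FALSE)
  }
  if (signature_genes_per_cluster * n_clusters > n_genes) {
    stop("signature gene sets must fit disjointly within n_genes",
         call. = FALSE)
  }
  if (score_shape <= 0 || score_scale <= 0) {
    stop("score_shape and score_scale must be positive", call. = FALSE)
  }
  f_sig <- signature_genes_per_cluster / n_genes
  if (is.null(background_hit_prob)) {
    background_hit_prob <-
      1 - background_sparsity / (1 - f_sig * signature_hit_prob)
    if (background_hit_prob < 0) {
      stop("signature structure alone exceeds the nonzero budget implied by ",
           "background_sparsity; lower signature_hit_prob or ",
           "signature_genes_per_cluster", call. = FALSE)
    }
  }
  stopifnot_prob(background_hit_prob, "background_hit_prob")
  if (is.null(early_late_odds)) {
    early_late_odds <- exp(seq(log(3.74), log(1.58),
                               length.out = n_clusters))
  }
  if (length(early_late_odds) == 1L) {
    early_late_odds <- rep(early_late_odds, n_clusters)
  }
  if (length(early_late_odds) != n_clusters || any(early_late_odds <= 0)) {
    stop("early_late_odds must be one positive odds value per cluster",
         call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes), n_patients = as.integer(n_patients),
    n_clusters = as.integer(n_clusters),
    background_sparsity = background_sparsity,
    signature_genes_per_cluster = as.integer(signature_genes_per_cluster),
    signature_hit_prob = signature_hit_prob,
    background_hit_prob = background_hit_prob,
    score_shape = score_shape, score_scale = score_scale,
    score_offset = score_offset,
    early_late_odds = early_late_odds,
    unknown_stage_prob = unknown_stage_prob,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Planted structure shared by the matrix and the variant-record paths.
planted_structure <- function(config) {
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  patients <- sprintf("P%03d", seq_len(config$n_patients))
  true_cluster <- rep_len(seq_len(config$n_clusters), config$n_patients)
  names(true_cluster) <- patients
  spc <- config$signature_genes_per_cluster
  signature_genes <- lapply(seq_len(config$n_clusters), function(c) {
    if (spc == 0) character() else genes[((c - 1) * spc + 1):(c * spc)]
  })
  names(signature_genes) <- paste0("cluster", seq_len(config$n_clusters))
  list(genes = genes, patients = patients, true_cluster = true_cluster,
       signature_genes = signature_genes)
}

# Per-cell event counts (0/1/2): independent background and own-cluster
# signature Bernoulli events. Drawn in the events substream.
simulate_events <- function(config, st) {
  m <- config$n_genes; n <- config$n_patients
  spc <- config$signature_genes_per_cluster
  with_seed(derive_seed(config$seed, 1L), {
    bg <- matrix(stats::rbinom(m * n, 1L, config$background_hit_prob), m, n)
    sig <- matrix(0L, m, n)
    if (spc > 0) {
      for (c in seq_len(config$n_clusters)) {
        rows <- match(st$signature_genes[[c]], st$genes)
        cols <- which(st$true_cluster == c)
        sig[rows, cols] <-
          stats::rbinom(length(rows) * length(cols), 1L,
                        config$signature_hit_prob)
      }
    }
    bg + sig
  })
}

# Raw per-event C-scores: gamma magnitude shifted down so scores can be
# negative. Drawn in the scores substream, in fixed column-major event order.
simulate_raw_scores <- function(config, n_events) {
  with_seed(derive_seed(config$seed, 2L), {
    stats::rgamma(n_events, shape = config$score_shape,
                  scale = config$score_scale) - config$score_offset
  })
}

simulate_stages <- function(config, st) {
  with_seed(derive_seed(config$seed, 3L), {
    n <- config$n_patients
    odds <- config$early_late_odds[st$true_cluster]
    early <- stats::runif(n) < odds / (1 + odds)
    sub <- stats::runif(n)
    stage <- ifelse(early,
                    ifelse(sub < 0.3, "I", "II"),
                    ifelse(sub < 0.8, "III", "IV"))
    stage[stats::runif(n) < config$unknown_stage_prob] <- "unknown"
    data.frame(patient_id = st$patients, stage = stage,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic cohort with planted cluster structure
#'
#' The score matrix is built exactly as the scoring pipeline builds it from
#' variant records: per-event raw C-scores of all mutation events are shifted
#' by the absolute value of their minimum (or 0) and summed per (gene,
#' patient) cell, so [generate_variant_records()] followed by [score_matrix()]
#' reproduces this matrix on its nonzero genes.
#'
#' @param config a [synthetic_config()].
#' @return A `synthetic_cohort` list: `score_matrix` (n_genes x n_patients,
#'   attribute `"offset"` = applied score shift), `true_cluster` (named
#'   integer vector), `stage_table` (data.frame `patient_id`, `stage`),
#'   `signature_genes` (list per cluster), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  st <- planted_structure(config)
  events <- simulate_events(config, st)
  raw <- simulate_raw_scores(config, sum(events))
  offset <- if (length(raw)) abs(min(c(raw, 0))) else 0
  shifted <- raw + offset

  mat <- matrix(0, config$n_genes, config$n_patients,
                dimnames = list(st$genes, st$patients))
  if (length(shifted)) {
    # column-major cell order, events within a cell consecutive
    cell <- rep(seq_along(events), events)
    add <- tapply(shifted, cell, sum)
    mat[as.integer(names(add))] <- add
  }
  attr(mat, "offset") <- offset

  structure(list(
    score_matrix = mat,
    true_cluster = st$true_cluster,
    stage_table = simulate_stages(config, st),
    signature_genes = st$signature_genes,
    config = config
  ), class = "synthetic_cohort")
}

#' Generate variant-level records underlying a synthetic cohort
#'
#' Produces one somatic, nonsynonymous, coding SNV record per mutation event
#' of [generate_cohort()] (same seed, same events), plus decoy records that
#' the filter cascade must remove: germline, synonymous, non-coding, indel,
#' and common-polymorphism (dbSNP MAF >= 0.05) decoys. Each variant gets a
#' globally unique (chrom, pos, ref, alt) key and an annotation row carrying
#' its raw C-score and dbSNP minor allele frequency (mostly absent, sometimes
#' rare).
#'
#' @param config a [synthetic_config()].
#' @return List with `records` (see [filter_variants()]), `annotations`
#'   (`chrom`, `pos`, `ref`, `alt`, `cadd_raw`, `dbsnp_maf`) and `patients`
#'   (full roster).
#' @export
generate_variant_records <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  st <- planted_structure(config)
  events <- simulate_events(config, st)
  raw <- simulate_raw_scores(config, sum(events))

  m <- config$n_genes
  idx <- which(events > 0)
  gi <- ((idx - 1) %% m) + 1L          # gene row
  pj <- ((idx - 1) %/% m) + 1L         # patient column
  gi <- rep(gi, events[idx]); pj <- rep(pj, events[idx])
  # order events column-major to align with the score stream
  ord <- order(rep(idx, events[idx]))
  gi <- gi[ord]; pj <- pj[ord]

  # unique positions: one 10000-bp block per gene, events numbered within it
  if (length(gi)) {
    within <- stats::ave(seq_along(gi), gi, FUN = seq_along)
    pos <- (gi - 1L) * 10000L + within
    alts <- c("C", "G", "T")
    records <- data.frame(
      chrom = "chr1", pos = pos, ref = "A",
      alt = alts[(within - 1L) %% 3L + 1L],
      patient_id = st$patients[pj],
      somatic = TRUE, consequence = "nonsynonymous", region = "coding",
      gene = st$genes[gi], stringsAsFactors = FALSE
    )
  } else {
    records <- data.frame(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), patient_id = character(), somatic = logical(),
      consequence = character(), region = character(), gene = character(),
      stringsAsFactors = FALSE
    )
  }

  with_seed(derive_seed(config$seed, 4L), {
    n_ev <- nrow(records)
    maf <- rep(NA_real_, n_ev)
    has_maf <- stats::runif(n_ev) < 0.3
    maf[has_maf] <- stats::runif(sum(has_maf), 0, 0.049)

    # decoys occupy a reserved block after the gene blocks
    n_dec <- max(5L, round(0.25 * n_ev))
    types <- rep_len(c("common_maf", "germline", "synonymous", "noncoding",
                       "indel"), n_dec)
    dgi <- sample.int(m, n_dec, replace = TRUE)
    dpj <- sample.int(config$n_patients, n_dec, replace = TRUE)
    decoys <- data.frame(
      chrom = "chr1", pos = m * 10000L + seq_len(n_dec), ref = "A",
      alt = "G", patient_id = st$patients[dpj],
      somatic = types != "germline",
      consequence = ifelse(types == "synonymous", "synonymous",
                           "nonsynonymous"),
      region = ifelse(types == "noncoding", "intron", "coding"),
      gene = st$genes[dgi], stringsAsFactors = FALSE
    )
    decoys$ref[types == "indel"] <- "AT"
    decoy_raw <- stats::rgamma(n_dec, config$score_shape,
                               scale = config$score_scale) - config$score_offset
    decoy_maf <- ifelse(types == "common_maf",
                        stats::runif(n_dec, 0.05, 0.5), NA_real_)

    all_rec <- rbind(records, decoys)
    annotations <- data.frame(
      chrom = all_rec$chrom, pos = all_rec$pos, ref = all_rec$ref,
      alt = all_rec$alt, cadd_raw = c(raw, decoy_raw),
      dbsnp_maf = c(maf, decoy_maf), stringsAsFactors = FALSE
    )
    list(records = all_rec, annotations = annotations,
         patients = st$patients)
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the score matrix TSV, clinical TSV (`patient_id`, `stage`), a truth
#' JSON (planted cluster labels and signature genes), and optionally the
#' variant records as a minimal VCF plus an annotation TSV.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param variants also write `variants.vcf` and `annotations.tsv`
#'   regenerated from the cohort's config (default `TRUE`).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, variants = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "score_matrix.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_matrix_tsv(cohort$score_matrix, paths[["matrix"]])
  write_tsv_file(cohort$stage_table, paths[["clinical"]])
  jsonlite::write_json(
    list(true_cluster = as.list(cohort$true_cluster),
         signature_genes = cohort$signature_genes,
         score_offset = attr(cohort$score_matrix, "offset")),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  if (variants) {
    vr <- generate_variant_records(cohort$config)
    paths[["vcf"]] <- file.path(dir, "variants.vcf")
    paths[["annotations"]] <- file.path(dir, "annotations.tsv")
    write_minimal_vcf(vr$records, paths[["vcf"]])
    write_tsv_file(vr$annotations, paths[["annotations"]])
  }
  invisible(paths)
}

write_minimal_vcf <- function(records, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=PATIENT,Number=1,Type=String,Description=\"Patient id\">",
    "##INFO=<ID=SOMATIC,Number=1,Type=Integer,Description=\"1 somatic, 0 germline\">",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Region class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- sprintf("PATIENT=%s;SOMATIC=%d;CSQ_CLASS=%s;REGION=%s;GENE=%s",
                  records$patient_id, as.integer(records$somatic),
                  records$consequence, records$region, records$gene)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  records$chrom, records$pos, records$ref, records$alt, info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Drop genes with no mutation in any patient
#'
#' The factorization requires every gene row to carry at least one mutation;
#' this removes all-zero rows while preserving attributes of interest.
#'
#' @param mat score matrix.
#' @return The matrix restricted to rows with at least one nonzero entry.
#' @export
drop_empty_genes <- function(mat) {
  keep <- rowSums(mat != 0) > 0
  mat[keep, , drop = FALSE]
}
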