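# Shared fixtures, built in code.

# Default-condition cohort: the study regime (96% zeros, moderate signatures).
default_cohort <- function(seed = 1L, ...) {
  generate_cohort(synthetic_config(seed = seed, ...))
}

# Strong-signal cohort: dense cluster-specific signatures so clustering and
# classification recover the planted structure essentially surely.
strong_config <- function(seed = 1L, n_genes = 200, n_patients = 90,
                          n_clusters = 3) {
  synthetic_config(
    n_genes = n_genes, n_patients = n_patients, n_clusters = n_clusters,
    signature_genes_per_cluster = 10, signature_hit_prob = 0.9,
    background_sparsity = 0.9, seed = seed
  )
}

# Small matrices cannot hold 96% zeros once signatures are planted; relax the
# sparsity target for miniature fixtures.
small_config <- function(n_genes, n_patients, seed, ...) {
  synthetic_config(n_genes = n_genes, n_patients = n_patients,
                   background_sparsity = 0.9,
                   signature_genes_per_cluster = 3, seed = seed, ...)
}

# Tiny variant-record table for scoring tests.
make_record <- function(pos, patient = "P1", gene = "G1", somatic = TRUE,
                        consequence = "nonsynonymous", region = "coding",
                        ref = "A", alt = "T") {
  data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
             patient_id = patient, somatic = somatic,
             consequence = consequence, region = region, gene = gene,
             stringsAsFactors = FALSE)
}

make_annotation <- function(records, cadd_raw, dbsnp_maf = NA_real_) {
  data.frame(chrom = records$chrom, pos = records$pos, ref = records$ref,
             alt = records$alt, cadd_raw = cadd_raw,
             dbsnp_maf = rep_len(dbsnp_maf, nrow(records)),
             stringsAsFactors = FALSE)
}

# Nearest-centroid classifier: fast deterministic plugin for CV tests.
classifier_centroid <- function() {
  structure(list(
    name = "nearest_centroid",
    fit = function(X, y) {
      cent <- rowsum(X, y) / as.vector(table(y))
      list(centroids = cent, levels = levels(y))
    },
    predict_scores = function(model, X) {
      d <- vapply(rownames(model$centroids), function(cl) {
        rowSums((X - rep(model$centroids[cl, ], each = nrow(X)))^2)
      }, numeric(nrow(X)))
      if (!is.matrix(d)) d <- matrix(d, nrow = nrow(X),
                                     dimnames = list(NULL,
                                                     rownames(model$centroids)))
      -d
    }
  ), class = "mutclust_classifier")
}

# Labeled dataset with planted class-specific features, for classification
# tests: class c patients have features in its block shifted by `effect`.
make_labeled_data <- function(n_per_class = 20, n_classes = 3,
                              n_features = 60, effect = 3, seed = 1) {
  withr_seed <- function(s, e) { set.seed(s); e }
  set.seed(seed)
  n <- n_per_class * n_classes
  y <- factor(rep(seq_len(n_classes), each = n_per_class))
  X <- matrix(rnorm(n * n_features), n, n_features,
              dimnames = list(sprintf("P%02d", 1:n),
                              sprintf("f%03d", 1:n_features)))
  block <- floor(n_features / (n_classes + 1))
  for (c in seq_len(n_classes)) {
    cols <- ((c - 1) * block + 1):(c * block)
    X[y == c, cols] <- X[y == c, cols] + effect
  }
  list(X = X, y = y, block = block)
}
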