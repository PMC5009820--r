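# Clinical characterization of clusters.
#
# AJCC stages I-II are dichotomized as "early", III-IV as "late"; patients
# with unknown stage are excluded from all stage statistics. Stage tendency
# of clusters is assessed by an exact conditional test on the cluster x
# (early, late) contingency table; differential mutation burden between two
# clusters is tested gene-wise by the Wilcoxon rank-sum test with
# Benjamini-Hochberg FDR control.

STAGE_LEVELS <- c("I", "II", "III", "IV", "unknown")

#' Dichotomize AJCC stage
#'
#' @param stage character vector of stages (`I`, `II`, `III`, `IV`,
#'   `unknown`).
#' @return Character vector: `"early"` (I, II), `"late"` (III, IV), or `NA`
#'   for unknown.
#' @export
dichotomize_stage <- function(stage) {
  if (!all(stage %in% STAGE_LEVELS)) {
    stop("stages must be one of ", paste(STAGE_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  out <- ifelse(stage %in% c("I", "II"), "early",
                ifelse(stage %in% c("III", "IV"), "late", NA))
  out
}

#' Stage distribution of each cluster
#'
#' @param assignments cluster label per patient (named vector).
#' @param stage_table data.frame with `patient_id` and `stage`.
#' @return data.frame per cluster: `cluster`, `n_patients`, `n_early`,
#'   `n_late`, `ratio` (early/late, `NA` when no late patient); attribute
#'   `"excluded_unknown"` counts unknown-stage patients excluded.
#' @export
stage_by_cluster <- function(assignments, stage_table) {
  miss <- setdiff(names(assignments), stage_table$patient_id)
  if (length(miss)) {
    stop("patients missing from the stage table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  stage <- stage_table$stage[match(names(assignments),
                                   stage_table$patient_id)]
  dich <- dichotomize_stage(stage)
  clusters <- sort(unique(assignments))
  rows <- lapply(clusters, function(c) {
    in_c <- assignments == c
    n_early <- sum(in_c & dich == "early", na.rm = TRUE)
    n_late <- sum(in_c & dich == "late", na.rm = TRUE)
    data.frame(cluster = c, n_patients = sum(in_c), n_early = n_early,
               n_late = n_late,
               ratio = if (n_late > 0) n_early / n_late else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded_unknown") <- sum(is.na(dich))
  out
}

# Recursive enumeration of all r x 2 tables with fixed margins; sums the
# multivariate hypergeometric probabilities of tables no more probable than
# the observed one (classic two-sided exact convention). Probabilities are
# compared on the log scale with a small relative tolerance.
fh_enumerate <- function(row_sums, e_total, logp_obs, tol = 1e-7) {
  r <- length(row_sums)
  total_p <- 0
  recurse <- function(i, remaining, logp_acc) {
    if (i == r) {
      if (remaining < 0 || remaining > row_sums[r]) return()
      lp <- logp_acc + lchoose(row_sums[r], remaining)
      if (lp <= logp_obs + tol) total_p <<- total_p + exp(lp)
      return()
    }
    lo <- max(0L, remaining - sum(row_sums[(i + 1):r]))
    hi <- min(row_sums[i], remaining)
    if (lo > hi) return()
    for (e in lo:hi) {
      recurse(i + 1L, remaining - e, logp_acc + lchoose(row_sums[i], e))
    }
  }
  recurse(1L, e_total, 0)
  total_p
}

#' Exact test of stage enrichment across clusters
#'
#' Two-sided exact conditional test on an r x 2 (cluster x early/late) count
#' table: the classic Fisher exact test for 2 x 2, and its Freeman-Halton
#' generalization for r > 2 — all tables with the observed margins are
#' enumerated and the multivariate hypergeometric probabilities of those no
#' more probable than the observed table are summed.
#'
#' @param counts matrix (or `stage_by_cluster` result) with one row per
#'   cluster and columns of early / late counts.
#' @param clusters optional subset of cluster rows to test (>= 2).
#' @return The two-sided exact p-value.
#' @export
stage_enrichment_exact <- function(counts, clusters = NULL) {
  if (is.data.frame(counts) && all(c("n_early", "n_late") %in% names(counts))) {
    m <- as.matrix(counts[, c("n_early", "n_late")])
    rownames(m) <- counts$cluster
  } else {
    m <- as.matrix(counts)
  }
  if (!is.null(clusters)) {
    m <- m[match(as.character(clusters), rownames(m)), , drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) != 2L) {
    stop("need an r x 2 table with r >= 2", call. = FALSE)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  row_sums <- rowSums(m)
  col_sums <- colSums(m)
  if (any(row_sums == 0) || any(col_sums == 0)) {
    stop("degenerate margin: a row or column sums to zero", call. = FALSE)
  }
  logp_obs <- sum(lchoose(row_sums, m[, 1]))
  log_denom <- lchoose(sum(row_sums), col_sums[1])
  p <- fh_enumerate(row_sums, col_sums[1], logp_obs) / exp(log_denom)
  min(1, p)
}

#' Differentially mutated genes between two clusters
#'
#' Per gene, a two-sided Wilcoxon rank-sum test compares the mutation score
#' vectors of the two patient groups (exact null when both groups are small
#' and untied, otherwise the normal approximation with tie and continuity
#' correction), followed by Benjamini-Hochberg adjustment across all tested
#' genes.
#'
#' @param mat mutation score matrix (genes x patients).
#' @param group_a,group_b disjoint patient id sets, each of size >= 2.
#' @param fdr_threshold genes with adjusted p below this are flagged
#'   (default 0.1).
#' @param exact_max use the exact null when both group sizes are at most this
#'   and there are no ties (default 25).
#' @return data.frame sorted by p-value: `gene`, `p_value`, `fdr`, `mean_a`,
#'   `mean_b`, `direction` (group with the larger mean), `significant`.
#' @export
differential_mutation <- function(mat, group_a, group_b, fdr_threshold = 0.1,
                                  exact_max = 25L) {
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 patients", call. = FALSE)
  }
  miss <- setdiff(c(group_a, group_b), colnames(mat))
  if (length(miss)) {
    stop("patients not in the matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  A <- mat[, group_a, drop = FALSE]
  B <- mat[, group_b, drop = FALSE]
  want_exact <- min(length(group_a), length(group_b)) <= exact_max
  p <- vapply(seq_len(nrow(mat)), function(i) {
    x <- A[i, ]; y <- B[i, ]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
    suppressWarnings(
      stats::wilcox.test(x, y, exact = want_exact, correct = TRUE)$p.value
    )
  }, numeric(1))
  mean_a <- rowMeans(A); mean_b <- rowMeans(B)
  out <- data.frame(
    gene = rownames(mat), p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    direction = ifelse(mean_a >= mean_b, "a", "b"),
    stringsAsFactors = FALSE
  )
  out$significant <- out$fdr < fdr_threshold
  out[order(out$p_value, out$gene), ]
}
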