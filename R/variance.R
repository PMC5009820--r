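# Variance-based feature selection.
#
# With tens of thousands of genes and only hundreds of patients, clustering
# runs on the top-n most variable genes. Genes are ranked by the sample
# variance of their (shifted) scores across patients, S^2 = sum((x - mean)^2)
# / (n - 1), in decreasing order.

#' Rank genes by score variance across patients
#'
#' @param mat mutation score matrix (genes x patients), `n >= 2` patients.
#' @return data.frame with columns `gene`, `variance`, `rank` (1-based,
#'   decreasing variance; ties broken by gene symbol so rankings are
#'   reproducible).
#' @export
rank_by_variance <- function(mat) {
  n <- ncol(mat)
  if (n < 2L) stop("variance ranking needs at least 2 patients", call. = FALSE)
  mu <- rowMeans(mat)
  v <- rowSums((mat - mu)^2) / (n - 1)
  ord <- order(-v, rownames(mat))
  data.frame(gene = rownames(mat)[ord], variance = unname(v[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Keep the top-n most variable genes
#'
#' @param mat mutation score matrix.
#' @param ranking result of [rank_by_variance()] on `mat`.
#' @param n_top number of genes to keep, `1 <= n_top <= nrow(mat)`.
#' @return Matrix with `n_top` rows in ranking order; columns unchanged.
#' @export
select_top <- function(mat, ranking, n_top) {
  stopifnot_count(n_top, "n_top")
  if (n_top > nrow(mat)) {
    stop("n_top exceeds the number of genes", call. = FALSE)
  }
  mat[ranking$gene[seq_len(n_top)], , drop = FALSE]
}
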