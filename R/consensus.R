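# Consensus clustering and model selection.
#
# NMF starts from a random initialization, so repeated runs need not agree.
# Stability is measured by averaging binary connectivity matrices over many
# runs into a consensus matrix C-bar whose (i, j) entry estimates the
# probability that samples i and j co-cluster. The average silhouette width
# of the consensus (on the dissimilarity 1 - C-bar) scores a (n_top_genes, k)
# configuration; the scan over a grid picks the most stable one.

#' Binary connectivity matrix of one clustering
#'
#' @param assignments cluster label per sample (vector, possibly named).
#' @return n x n symmetric 0/1 matrix with unit diagonal; entry (i, j) is 1
#'   iff samples i and j share a cluster.
#' @export
connectivity_matrix <- function(assignments) {
  cm <- outer(assignments, assignments, `==`) * 1
  dimnames(cm) <- list(names(assignments), names(assignments))
  cm
}

#' Consensus matrix over repeated clustering runs
#'
#' @param runs list of `nmf_fit` objects (or plain assignment vectors) over
#'   the same sample set.
#' @return n x n matrix of co-clustering frequencies in `[0, 1]` with unit
#'   diagonal; attribute `"run_count"`.
#' @export
consensus_matrix <- function(runs) {
  if (length(runs) < 1L) stop("need at least one run", call. = FALSE)
  get_assign <- function(r) if (inherits(r, "nmf_fit")) r$assignments else r
  a1 <- get_assign(runs[[1]])
  acc <- matrix(0, length(a1), length(a1))
  for (r in runs) {
    a <- get_assign(r)
    if (length(a) != length(a1) || !identical(names(a), names(a1))) {
      stop("all runs must cover the same sample set", call. = FALSE)
    }
    acc <- acc + connectivity_matrix(a)
  }
  cm <- acc / length(runs)
  dimnames(cm) <- list(names(a1), names(a1))
  attr(cm, "run_count") <- length(runs)
  cm
}

#' Cut the consensus into k groups
#'
#' Hierarchical clustering (average linkage) of the dissimilarity
#' `1 - consensus`, cut at k. These consensus-derived labels are used both to
#' score stability (silhouette) and as the final reported patient assignment,
#' since they summarize all runs rather than any single one.
#'
#' @param cons consensus matrix.
#' @param k number of clusters.
#' @return Integer labels named by sample.
#' @export
consensus_labels <- function(cons, k) {
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  stats::cutree(hc, k = k)
}

#' Average silhouette width of a consensus matrix
#'
#' For each sample i, with dissimilarity `d = 1 - consensus`: `a(i)` is the
#' mean dissimilarity to the other members of its own cluster, `b(i)` the
#' smallest mean dissimilarity to any other cluster, and
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `s(i) = 0` when
#' `a(i) = b(i)`. Samples in singleton clusters get `s(i) = 0`.
#'
#' @param cons consensus matrix.
#' @param labels cluster label per sample (>= 2 distinct clusters).
#' @return List with per-sample `s`, `a`, `b`, the `average_width`, and the
#'   `labels` used.
#' @export
consensus_silhouette <- function(cons, labels) {
  if (length(labels) != nrow(cons)) {
    stop("labels and consensus matrix disagree in size", call. = FALSE)
  }
  cl <- unique(labels)
  if (length(cl) < 2L) {
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  }
  d <- 1 - cons
  n <- nrow(d)
  a <- b <- s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    own <- own[own != i]
    if (length(own) == 0L) {           # singleton cluster
      a[i] <- 0; b[i] <- 0; s[i] <- 0
      next
    }
    a[i] <- mean(d[i, own])
    b[i] <- min(vapply(setdiff(cl, labels[i]),
                       function(c) mean(d[i, labels == c]), numeric(1)))
    s[i] <- if (a[i] == b[i]) 0 else (b[i] - a[i]) / max(a[i], b[i])
  }
  list(s = s, a = a, b = b, average_width = mean(s), labels = labels)
}

# Deterministic, order-invariant seed for run r of a grid cell.
cell_seed <- function(seed, n_top, k, r) derive_seed(seed, n_top, k, r)

#' Repeated NMF runs and their consensus for one configuration
#'
#' @param mat score matrix restricted to the genes to use.
#' @param k rank.
#' @param runs number of randomly initialized runs.
#' @param seed master seed; run seeds are derived deterministically.
#' @param n_top tag entering seed derivation (the gene count of the cell).
#' @param ... passed to [run_nmf()].
#' @return List with the consensus matrix `consensus`, consensus-derived
#'   `labels`, `silhouette` result, and the assignment matrix `runs_assign`
#'   (runs x samples).
#' @export
consensus_cluster <- function(mat, k, runs = 100L, seed = 1L,
                              n_top = nrow(mat), ...) {
  fits <- lapply(seq_len(runs), function(r) {
    run_nmf(mat, k, seed = cell_seed(seed, n_top, k, r), ...)$assignments
  })
  cons <- consensus_matrix(fits)
  labels <- consensus_labels(cons, k)
  list(consensus = cons, labels = labels,
       silhouette = consensus_silhouette(cons, labels),
       runs_assign = do.call(rbind, fits))
}

#' Scan gene-count x rank configurations for the most stable clustering
#'
#' For every `(n_top, k)` cell: keep the `n_top` most variable genes, run
#' `runs_per_cell` randomly initialized NMF runs, average their connectivity
#' matrices into a consensus, derive labels by average-linkage cutting of
#' `1 - consensus`, and score the cell by the average silhouette width of the
#' consensus. The cell with the largest width is selected (ties broken toward
#' smaller k, then fewer genes).
#'
#' @param mat full mutation score matrix (all-zero gene rows are dropped).
#' @param gene_grid gene counts to scan (e.g. `c(10, 50, ..., 1000)`).
#' @param k_grid ranks to scan (e.g. `2:10`).
#' @param runs_per_cell NMF runs per cell (default 100).
#' @param seed master seed; every run seed derives from `(seed, n_top, k,
#'   run)` so the scan is invariant to grid order.
#' @param ... passed to [run_nmf()].
#' @return `model_scan` list: `grid` (data.frame `n_top`, `k`, `silhouette`),
#'   `selected` (row of the chosen cell), and `best` (the
#'   [consensus_cluster()] result of the chosen cell).
#' @export
scan_models <- function(mat, gene_grid, k_grid, runs_per_cell = 100L,
                        seed = 1L, ...) {
  if (!length(gene_grid) || !length(k_grid)) {
    stop("gene_grid and k_grid must be non-empty", call. = FALSE)
  }
  if (runs_per_cell < 2L) stop("runs_per_cell must be >= 2", call. = FALSE)
  mat <- drop_empty_genes(mat)
  ranking <- rank_by_variance(mat)
  gene_grid <- sort(unique(pmin(gene_grid, nrow(mat))))
  cells <- expand.grid(n_top = gene_grid, k = sort(unique(k_grid)))
  results <- vector("list", nrow(cells))
  sil <- rep(NA_real_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    n_top <- cells$n_top[i]; k <- cells$k[i]
    if (k >= ncol(mat)) {
      warning(sprintf("skipping cell (n_top=%d, k=%d): k >= n_patients",
                      n_top, k), call. = FALSE)
      next
    }
    sub <- drop_empty_genes(select_top(mat, ranking, n_top))
    if (k >= nrow(sub)) {
      warning(sprintf("skipping cell (n_top=%d, k=%d): k >= usable genes",
                      n_top, k), call. = FALSE)
      next
    }
    cc <- consensus_cluster(sub, k, runs = runs_per_cell, seed = seed,
                            n_top = n_top, ...)
    results[[i]] <- cc
    sil[i] <- cc$silhouette$average_width
  }
  if (all(is.na(sil))) stop("no grid cell could be evaluated", call. = FALSE)
  grid <- data.frame(n_top = cells$n_top, k = cells$k, silhouette = sil)
  ord <- order(-grid$silhouette, grid$k, grid$n_top)
  best_i <- ord[1]
  structure(list(grid = grid, selected = grid[best_i, ],
                 best = results[[best_i]]),
            class = "model_scan")
}

#' @export
print.model_scan <- function(x, ...) {
  cat("Consensus NMF model scan\n")
  print(x$grid, row.names = FALSE)
  cat(sprintf("selected: %d genes, k = %d (average silhouette width %.3f)\n",
              x$selected$n_top, x$selected$k, x$selected$silhouette))
  invisible(x)
}
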