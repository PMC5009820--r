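# Non-negative matrix factorization by Kullback-Leibler multiplicative
# updates (Brunet-style), the clustering engine of the pipeline.
#
# A (m x n, non-negative) is approximated by W (m x k basis, metagenes in
# columns) times H (k x n coefficients, metagene load per sample). Samples
# are assigned to the metagene with the largest coefficient in their H
# column. The objective is the generalized KL divergence
#   D(A || WH) = sum_ij [ A_ij log(A_ij / (WH)_ij) - A_ij + (WH)_ij ],
# with 0 log 0 = 0 and an epsilon floor inside divisions and logs.

#' Generalized Kullback-Leibler divergence D(A || WH)
#'
#' @param A non-negative matrix.
#' @param W,H factor matrices with conforming shapes.
#' @param eps numerical floor applied to `(WH)_ij` (default 1e-12).
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(A, W, H, eps = 1e-12) {
  if (nrow(W) != nrow(A) || ncol(H) != ncol(A) || ncol(W) != nrow(H)) {
    stop("shape mismatch between A, W, H", call. = FALSE)
  }
  WH <- pmax(W %*% H, eps)
  lg <- ifelse(A > 0, A * log(A / WH), 0)
  sum(lg - A + WH)
}

#' One coupled multiplicative update of (W, H)
#'
#' Applies the KL-divergence updates
#' \deqn{W_{ia} \leftarrow W_{ia} \frac{\sum_u H_{au} A_{iu}/(WH)_{iu}}{\sum_v H_{av}}}
#' \deqn{H_{au} \leftarrow H_{au} \frac{\sum_i W_{ia} A_{iu}/(WH)_{iu}}{\sum_k W_{ka}}}
#' where the H update uses the already-updated W. Non-negativity is preserved
#' and the divergence does not increase.
#'
#' @inheritParams kl_divergence
#' @return List with updated `W` and `H`.
#' @export
nmf_update <- function(A, W, H, eps = 1e-12) {
  WH <- pmax(W %*% H, eps)
  W <- W * ((A / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = nrow(W))
  WH <- pmax(W %*% H, eps)
  H <- H * (t(W) %*% (A / WH)) / pmax(colSums(W), eps)
  if (any(!is.finite(W)) || any(!is.finite(H))) {
    stop("non-finite values produced by the multiplicative update",
         call. = FALSE)
  }
  list(W = W, H = H)
}

#' Cluster assignments from the coefficient matrix
#'
#' Sample j is assigned to metagene i if `H[i, j]` is the largest entry of
#' column j; ties go to the smallest metagene index.
#'
#' @param H coefficient matrix (k x n).
#' @return Integer vector of length n (named by colnames of `H` if present).
#' @export
assign_clusters <- function(H) {
  a <- max.col(t(H), ties.method = "first")
  names(a) <- colnames(H)
  a
}

#' Run one seeded NMF factorization
#'
#' Initializes W and H with i.i.d. uniform entries on `(0, max(A)]` and
#' iterates [nmf_update()]. Every `check_every` iterations the sample
#' connectivity (co-assignment) matrix is computed; the run stops when it has
#' been unchanged for `stop_window` consecutive checks, or at `max_iter`.
#'
#' @param A non-negative matrix with no all-zero row (genes carrying no
#'   mutation must be removed upstream).
#' @param k factorization rank, `k < min(dim(A))` (k = 1 is allowed and
#'   assigns every sample to one cluster).
#' @param seed integer seed for the initialization.
#' @param max_iter iteration cap (default 2000).
#' @param check_every convergence-check period in iterations (default 10).
#' @param stop_window consecutive unchanged connectivity checks required to
#'   stop (default 40).
#' @param eps numerical floor (default 1e-12).
#' @return `nmf_fit` list: `W`, `H`, `k`, `assignments`, `divergence_trace`
#'   (objective at each check), `iterations`, `seed`.
#' @export
run_nmf <- function(A, k, seed = 1L, max_iter = 2000L, check_every = 10L,
                    stop_window = 40L, eps = 1e-12) {
  stopifnot_count(k, "k")
  if (any(A < 0)) stop("A must be non-negative", call. = FALSE)
  if (k > 1 && k >= min(dim(A))) {
    stop("rank k must be smaller than both dimensions of A", call. = FALSE)
  }
  if (any(rowSums(A) == 0)) {
    stop("A has all-zero rows; remove genes without mutations first",
         call. = FALSE)
  }
  if (any(colSums(A) == 0)) {
    warning("A has all-zero columns; their assignment follows the tie rule",
            call. = FALSE)
  }
  m <- nrow(A); n <- ncol(A)
  amax <- max(A)
  fit <- with_seed(seed, {
    W <- matrix(stats::runif(m * k) * amax + eps, m, k)
    H <- matrix(stats::runif(k * n) * amax + eps, k, n)
    trace <- numeric(0)
    conn_prev <- NULL
    stable <- 0L
    iter <- 0L
    while (iter < max_iter) {
      for (s in seq_len(check_every)) {
        up <- nmf_update(A, W, H, eps)
        W <- up$W; H <- up$H
      }
      iter <- iter + check_every
      trace <- c(trace, kl_divergence(A, W, H, eps))
      # canonical labeling: connectivity is unchanged iff the partition is
      a <- assign_clusters(H)
      conn <- match(a, unique(a))
      if (!is.null(conn_prev) && identical(conn, conn_prev)) {
        stable <- stable + 1L
        if (stable >= stop_window) break
      } else {
        stable <- 0L
      }
      conn_prev <- conn
    }
    list(W = W, H = H, trace = trace, iterations = iter)
  })
  dimnames(fit$W) <- list(rownames(A), NULL)
  dimnames(fit$H) <- list(NULL, colnames(A))
  structure(list(W = fit$W, H = fit$H, k = as.integer(k),
                 assignments = assign_clusters(fit$H),
                 divergence_trace = fit$trace,
                 iterations = fit$iterations, seed = as.integer(seed)),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("KL-NMF fit: rank %d, %d x %d, %d iterations, divergence %.6g\n",
              x$k, nrow(x$W), ncol(x$H), x$iterations,
              utils::tail(x$divergence_trace, 1)))
  invisible(x)
}
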