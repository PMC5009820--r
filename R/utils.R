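#' mutclust: somatic mutation burden subtyping by consensus NMF
#'
#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation. Keeps every derived seed a positive
# 32-bit integer so the same master seed reproduces the same stream on any
# platform, and stages (events / scores / stages / runs) stay decoupled:
# perturbing one stage's draw count cannot shift another stage's stream.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) {
    h <- (h * 48271 + (as.double(t) %% 2147483647) + 11) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Fraction of zero entries in a matrix
#'
#' @param x numeric matrix.
#' @return Scalar in `[0, 1]`.
#' @export
zero_fraction <- function(x) {
  mean(x == 0)
}

# Shannon entropy (bits) of a label vector.
entropy_bits <- function(y) {
  p <- tabulate(y)
  p <- p[p > 0] / length(y)
  -sum(p * log2(p))
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
}

stopifnot_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a mutation score matrix as TSV
#'
#' Genes in rows, patients in columns; the first column holds the gene symbol.
#'
#' @param mat numeric matrix with gene rownames and patient colnames.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write_tsv_file(df, path)
}

#' Read a mutation score matrix written by [write_matrix_tsv()]
#'
#' @param path TSV file with a `gene` column followed by one column per patient.
#' @return Numeric matrix, genes in rows.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
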