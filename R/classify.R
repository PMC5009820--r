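# Cluster-label prediction from the mutation score matrix.
#
# Each patient is labeled with its cluster; a classifier is evaluated by
# stratified 10-fold cross-validation where, in every fold, the top-k genes
# by information gain are selected on the training patients only (no test
# leakage). Information gain uses supervised entropy-minimization
# discretization with the Fayyad-Irani MDL stopping rule. Significance of the
# observed accuracy is assessed by re-running the whole procedure on
# label-shuffled datasets.

# entropy (bits) of a class-count vector
count_entropy <- function(cnt) {
  tot <- sum(cnt)
  if (tot == 0) return(0)
  p <- cnt[cnt > 0] / tot
  -sum(p * log2(p))
}

# Recursive MDL cut search on a sorted segment. Returns cut values.
mdl_segment <- function(x, ycode, K) {
  n <- length(x)
  if (n < 2L) return(numeric(0))
  # cumulative class counts; candidate cuts between distinct adjacent x
  cum <- vapply(seq_len(K), function(c) cumsum(ycode == c),
                numeric(n))
  if (!is.matrix(cum)) cum <- matrix(cum, nrow = n)
  total <- cum[n, ]
  if (sum(total > 0) < 2L) return(numeric(0))   # one class only
  cand <- which(x[-n] < x[-1])
  if (!length(cand)) return(numeric(0))
  left <- cum[cand, , drop = FALSE]
  right <- rep(total, each = length(cand)) - left
  hl <- apply(left, 1, count_entropy)
  hr <- apply(right, 1, count_entropy)
  w <- cand / n
  info <- w * hl + (1 - w) * hr
  best <- which.min(info)
  i <- cand[best]
  hs <- count_entropy(total)
  gain <- hs - info[best]
  k0 <- sum(total > 0)
  k1 <- sum(left[best, ] > 0)
  k2 <- sum(right[best, ] > 0)
  delta <- log2(3^k0 - 2) -
    (k0 * hs - k1 * hl[best] - k2 * hr[best])
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  cut <- (x[i] + x[i + 1]) / 2
  c(mdl_segment(x[1:i], ycode[1:i], K), cut,
    mdl_segment(x[(i + 1):n], ycode[(i + 1):n], K))
}

#' Information gain of a feature under MDL discretization
#'
#' Discretizes the feature by recursive supervised entropy minimization with
#' the Fayyad-Irani minimum-description-length stopping rule, then returns
#' `H(labels) - sum_bins (|bin|/n) H(labels | bin)` in bits. A feature the
#' MDL rule leaves unsplit has zero information gain.
#'
#' @param x numeric feature vector.
#' @param labels class label per sample (>= 2 classes).
#' @return Non-negative scalar (bits).
#' @export
information_gain <- function(x, labels) {
  y <- as.integer(factor(labels))
  K <- max(y)
  if (K < 2L) stop("labels must contain at least 2 classes", call. = FALSE)
  ord <- order(x)
  cuts <- mdl_segment(x[ord], y[ord], K)
  if (!length(cuts)) return(0)
  bins <- findInterval(x, sort(cuts))
  n <- length(x)
  cond <- 0
  for (b in unique(bins)) {
    in_b <- bins == b
    cond <- cond + sum(in_b) / n * count_entropy(tabulate(y[in_b], K))
  }
  max(0, count_entropy(tabulate(y, K)) - cond)
}

#' Top-k genes by training-set information gain
#'
#' @param X feature matrix, patients in rows and genes in columns
#'   (training patients only — selection must never see the test fold).
#' @param labels class label per training patient.
#' @param k_top number of genes to keep (capped at `ncol(X)`); ties broken by
#'   gene name.
#' @return Character vector of selected gene names, decreasing information
#'   gain.
#' @export
select_by_information_gain <- function(X, labels, k_top) {
  ig <- vapply(seq_len(ncol(X)), function(j) information_gain(X[, j], labels),
               numeric(1))
  ord <- order(-ig, colnames(X))
  colnames(X)[ord][seq_len(min(k_top, ncol(X)))]
}

#' Random-forest classifier plugin
#'
#' Classifiers are pluggable behind a fit / predict-scores contract: `fit(X,
#' y)` returns a model and `predict_scores(model, X)` a patients x classes
#' score matrix (here: forest vote fractions).
#'
#' @param ntree number of trees (default 500).
#' @param ... further arguments to [randomForest::randomForest()].
#' @return A `mutclust_classifier` list with `fit` and `predict_scores`.
#' @export
classifier_random_forest <- function(ntree = 500, ...) {
  structure(list(
    name = "random_forest",
    fit = function(X, y) randomForest::randomForest(X, y, ntree = ntree, ...),
    predict_scores = function(model, X) {
      stats::predict(model, X, type = "prob")
    }
  ), class = "mutclust_classifier")
}

#' Stratified fold assignment
#'
#' Patients of each class are shuffled and dealt round-robin across folds
#' (continuing the deal across classes), so every fold's class proportions
#' are within one patient of the stratified ideal.
#'
#' @param labels class label per patient.
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @return Integer fold id per patient.
#' @export
stratified_folds <- function(labels, n_folds, seed = 1L) {
  y <- factor(labels)
  if (any(table(y) < n_folds)) {
    warning("a class has fewer members than folds; stratification is ",
            "best-effort", call. = FALSE)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    pos <- 0L
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- (pos + seq_along(idx) - 1L) %% n_folds + 1L
      pos <- pos + length(idx)
    }
  })
  fold
}

# Pooled confusion matrix and one-vs-rest metrics.
confusion_metrics <- function(conf) {
  n <- sum(conf)
  classes <- rownames(conf)
  per <- lapply(classes, function(c) {
    tp <- conf[c, c]
    fn <- sum(conf[c, ]) - tp
    fp <- sum(conf[, c]) - tp
    tn <- n - tp - fn - fp
    tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(tpr) && prec + tpr > 0) {
      2 * prec * tpr / (prec + tpr)
    } else NA_real_
    data.frame(class = c, tpr = tpr, fpr = fpr, tnr = 1 - fpr,
               fnr = 1 - tpr, precision = prec, f_measure = f1)
  })
  per <- do.call(rbind, per)
  macro <- colMeans(per[, -1], na.rm = TRUE)
  list(per_class = per, macro = as.list(macro),
       accuracy = sum(diag(conf)) / n)
}

#' ROC curve points and trapezoid AUC for one class
#'
#' @param score numeric classifier score for the positive class.
#' @param positive logical; `TRUE` for positives.
#' @return List with `points` (data.frame `fpr`, `tpr`, stepping through
#'   distinct score thresholds from high to low) and `auc`.
#' @export
roc_curve <- function(score, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) stop("need both positives and negatives",
                               call. = FALSE)
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; pos <- positive[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- c(s[-1] != s[-length(s)], TRUE)   # keep last index of tied scores
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

cv_core <- function(X, y, classifier, n_folds, k_top, seed,
                    compute_roc = TRUE) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (nrow(X) < n_folds) stop("fewer patients than folds", call. = FALSE)
  fold <- stratified_folds(y, n_folds, seed = derive_seed(seed, 97L))
  classes <- levels(y)
  conf <- matrix(0L, nlevels(y), nlevels(y),
                 dimnames = list(true = classes, predicted = classes))
  scores <- matrix(NA_real_, nrow(X), nlevels(y),
                   dimnames = list(rownames(X), classes))
  fold_acc <- numeric(n_folds)
  sel_genes <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    genes <- select_by_information_gain(X[tr, , drop = FALSE], y[tr], k_top)
    sel_genes[[f]] <- genes
    # classifier fits may consume RNG (e.g. forests); seed them per fold so
    # a rerun with the same seed reproduces the report bit for bit
    sc <- with_seed(derive_seed(seed, f, 11L), {
      model <- classifier$fit(X[tr, genes, drop = FALSE], droplevels(y[tr]))
      classifier$predict_scores(model, X[te, genes, drop = FALSE])
    })
    sc <- sc[, match(classes, colnames(sc)), drop = FALSE]
    sc[is.na(sc)] <- 0
    colnames(sc) <- classes
    pred <- classes[max.col(sc, ties.method = "first")]
    conf_f <- table(factor(y[te], classes), factor(pred, classes))
    conf <- conf + conf_f
    fold_acc[f] <- sum(diag(conf_f)) / sum(conf_f)
    if (compute_roc) scores[te, ] <- sc
  }
  mets <- confusion_metrics(conf)
  roc <- auc <- NULL
  if (compute_roc) {
    roc <- lapply(classes, function(c) roc_curve(scores[, c], y == c))
    names(roc) <- classes
    auc <- vapply(roc, `[[`, numeric(1), "auc")
    roc <- lapply(roc, `[[`, "points")
  }
  structure(list(
    confusion = conf, accuracy = mets$accuracy, per_class = mets$per_class,
    macro = mets$macro, auc = auc, roc = roc, fold = fold,
    fold_accuracy = fold_acc, selected_genes = sel_genes,
    scores = if (compute_roc) scores else NULL,
    n_folds = n_folds, k_top = k_top, seed = seed
  ), class = "cv_report")
}

#' Stratified cross-validation with per-fold feature selection
#'
#' In each fold the test patients are withdrawn, the `k_top` genes with the
#' highest information gain are selected on the remaining training patients,
#' the classifier is fit on those genes, and the held-out patients are
#' predicted. The confusion matrix is pooled over folds; accuracy, per-class
#' one-vs-rest rates (TPR, FPR, TNR, FNR, precision, F-measure) with macro
#' averages, and per-class one-vs-rest ROC curves with trapezoid AUC are
#' reported.
#'
#' @param X feature matrix, patients x genes.
#' @param labels class (cluster) label per patient.
#' @param classifier a classifier plugin such as
#'   [classifier_random_forest()].
#' @param n_folds number of folds (default 10).
#' @param k_top genes selected per fold (default 500, capped at the gene
#'   count).
#' @param seed RNG seed (fold assignment).
#' @return A `cv_report` list: pooled `confusion` matrix, `accuracy`,
#'   `per_class` metrics, `macro` averages, per-class `auc` and `roc` points,
#'   fold assignment and per-fold accuracies, and the genes selected per fold.
#' @export
cross_validate <- function(X, labels, classifier = classifier_random_forest(),
                           n_folds = 10L, k_top = 500L, seed = 1L) {
  cv_core(X, labels, classifier, n_folds, k_top, seed, compute_roc = TRUE)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: accuracy %.4f\n", x$n_folds,
              x$accuracy))
  print(x$confusion)
  if (!is.null(x$auc)) {
    cat("one-vs-rest AUC:",
        paste(sprintf("%s=%.3f", names(x$auc), x$auc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Permutation test of classification accuracy
#'
#' Builds an empirical null for the cross-validated accuracy: labels are
#' shuffled uniformly at random (class sizes fixed) and the full
#' cross-validation — including per-fold feature selection — is re-run on
#' each shuffled dataset. The p-value is the fraction of shuffles with
#' strictly greater accuracy than observed; when no shuffle beats the
#' observed accuracy it is reported as the bound `< 1/N`.
#'
#' @inheritParams cross_validate
#' @param n_perm number of label shuffles.
#' @return `permutation_result` list: `observed_accuracy`,
#'   `perm_accuracies`, `count_better`, `p_value` (= count/N),
#'   `p_label` (`"< 1/N"` when the count is 0), `n_perm`, `seed`.
#' @export
permutation_test <- function(X, labels,
                             classifier = classifier_random_forest(),
                             n_perm = 200L, n_folds = 10L, k_top = 500L,
                             seed = 1L) {
  stopifnot_count(n_perm, "n_perm")
  observed <- cv_core(X, labels, classifier, n_folds, k_top,
                      seed = derive_seed(seed, 0L), compute_roc = FALSE)
  perm_acc <- vapply(seq_len(n_perm), function(b) {
    yb <- with_seed(derive_seed(seed, b, 1L), sample(labels))
    cv_core(X, yb, classifier, n_folds, k_top,
            seed = derive_seed(seed, b, 2L), compute_roc = FALSE)$accuracy
  }, numeric(1))
  count <- sum(perm_acc > observed$accuracy)
  structure(list(
    observed_accuracy = observed$accuracy, perm_accuracies = perm_acc,
    count_better = count, p_value = count / n_perm,
    p_label = if (count == 0) sprintf("< %g", 1 / n_perm) else
      sprintf("%g", count / n_perm),
    n_perm = as.integer(n_perm), seed = as.integer(seed)
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation test: observed accuracy %.4f, %d/%d shuffles better, p %s\n",
    x$observed_accuracy, x$count_better, x$n_perm, x$p_label))
  invisible(x)
}
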