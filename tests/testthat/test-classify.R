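test_that("information gain matches closed-form cases", {
  y <- rep(1:2, each = 4)
  expect_equal(information_gain(rep(1, 8), y), 0)       # constant feature
  expect_equal(information_gain(c(1, 1, 2, 2, 5, 5, 6, 6), y), 1)
  expect_error(information_gain(rnorm(8), rep(1, 8)), "2 classes")
})

test_that("MDL leaves label-independent features unsplit", {
  set.seed(28)
  y <- rep(1:2, each = 100)
  ig <- replicate(100, information_gain(rnorm(200), y))
  expect_gte(mean(ig == 0), 0.95)
})

test_that("top-k selection is ordered, capped, and tie-stable", {
  d <- make_labeled_data(n_per_class = 15, n_classes = 2, n_features = 30,
                         effect = 4, seed = 29)
  sel <- select_by_information_gain(d$X, d$y, 5)
  expect_length(sel, 5)
  informative <- colnames(d$X)[seq_len(2 * d$block)]
  expect_true(all(sel %in% informative))
  all_sel <- select_by_information_gain(d$X, d$y, 999)
  expect_setequal(all_sel, colnames(d$X))
})

test_that("stratified folds keep class proportions within one patient", {
  y <- factor(rep(1:3, times = c(17, 23, 10)))
  fold <- stratified_folds(y, 5, seed = 30)
  tab <- table(fold, y)
  for (c in 1:3) expect_lte(diff(range(tab[, c])), 1)
  expect_equal(sum(tab), length(y))
})

test_that("feature selection never sees the test fold", {
  set.seed(31)
  n <- 40
  y <- factor(rep(1:2, each = n / 2))
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("P%02d", 1:n), sprintf("f%d", 1:6)))
  X[, 1:3] <- X[, 1:3] + 4 * (as.integer(y) - 1)   # honestly informative
  seed <- 7L
  fold <- stratified_folds(y, 4, seed = mutclust:::derive_seed(seed, 97L))
  # canary: perfectly predictive on fold-1 test patients, constant elsewhere
  canary <- numeric(n)
  canary[fold == 1] <- as.integer(y)[fold == 1] * 10
  X <- cbind(X, canary = canary)
  cv <- cross_validate(X, y, classifier_centroid(), n_folds = 4, k_top = 3,
                       seed = seed)
  expect_false("canary" %in% cv$selected_genes[[1]])
  expect_setequal(cv$selected_genes[[1]], c("f1", "f2", "f3"))
})

test_that("a constant classifier scores chance accuracy with one-hot rates", {
  d <- make_labeled_data(n_per_class = 12, n_classes = 3, n_features = 20,
                         effect = 0, seed = 32)
  always_first <- structure(list(
    name = "always_first",
    fit = function(X, y) levels(y),
    predict_scores = function(model, X) {
      s <- matrix(0, nrow(X), length(model), dimnames = list(NULL, model))
      s[, 1] <- 1
      s
    }
  ), class = "mutclust_classifier")
  cv <- cross_validate(d$X, d$y, always_first, n_folds = 4, k_top = 5,
                       seed = 33)
  expect_equal(cv$accuracy, 1 / 3)
  expect_equal(cv$per_class$tpr, c(1, 0, 0))
  expect_equal(sum(cv$confusion), length(d$y))
  expect_equal(unname(rowSums(cv$confusion)), as.vector(table(d$y)))
})

test_that("pooled accuracy equals the fold-size-weighted mean", {
  d <- make_labeled_data(n_per_class = 11, n_classes = 2, n_features = 20,
                         effect = 1, seed = 34)
  cv <- cross_validate(d$X, d$y, classifier_centroid(), n_folds = 4,
                       k_top = 5, seed = 35)
  fold_sizes <- as.vector(table(cv$fold))
  expect_equal(cv$accuracy,
               sum(cv$fold_accuracy * fold_sizes) / sum(fold_sizes))
})

test_that("ROC/AUC: perfect scorer gives 1, monotone transforms are neutral", {
  pos <- c(rep(TRUE, 5), rep(FALSE, 5))
  perfect <- c(6:10, 1:5)
  r <- roc_curve(perfect, pos)
  expect_equal(r$auc, 1)
  set.seed(36)
  s <- rnorm(40); p <- runif(40) < 0.4
  expect_equal(roc_curve(s, p)$auc, roc_curve(exp(s), p)$auc)
  expect_equal(roc_curve(s, p)$auc, roc_curve(rank(s), p)$auc)
})

test_that("trapezoid AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(37)
  for (i in 1:5) {
    s <- round(rnorm(30), 1)        # ties included
    p <- runif(30) < 0.5
    if (!any(p) || all(p)) next
    ref <- suppressMessages(pROC::auc(pROC::roc(p, s, quiet = TRUE,
                                                direction = "<")))
    expect_equal(roc_curve(s, p)$auc, as.numeric(ref))
  }
})

test_that("separable synthetic data is classified essentially perfectly", {
  co <- generate_cohort(strong_config(seed = 38, n_genes = 100,
                                      n_patients = 60))
  X <- t(drop_empty_genes(co$score_matrix))
  cv <- cross_validate(X, co$true_cluster,
                       classifier_random_forest(ntree = 100),
                       n_folds = 5, k_top = 15, seed = 39)
  expect_gte(cv$accuracy, 0.95)
  expect_true(all(cv$auc >= 0.95))
})

test_that("permutation machinery counts strictly better shuffles", {
  co <- generate_cohort(strong_config(seed = 40, n_genes = 100,
                                      n_patients = 36))
  X <- t(drop_empty_genes(co$score_matrix))
  pt <- permutation_test(X, co$true_cluster, classifier_centroid(),
                         n_perm = 19, n_folds = 4, k_top = 10, seed = 41)
  expect_equal(pt$p_value, pt$count_better / 19)
  expect_equal(pt$count_better, 0)
  expect_match(pt$p_label, "^< ")
  expect_length(pt$perm_accuracies, 19)
  expect_true(all(pt$perm_accuracies >= 0 & pt$perm_accuracies <= 1))
})
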