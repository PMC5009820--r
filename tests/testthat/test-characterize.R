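# build an assignment + stage table realizing given per-cluster counts
make_staged_cohort <- function(counts) {
  # counts: list of c(early, late, unknown) per cluster
  ids <- character(); cl <- integer(); stage <- character()
  for (c in seq_along(counts)) {
    n <- sum(counts[[c]])
    pid <- sprintf("c%d_p%03d", c, seq_len(n))
    ids <- c(ids, pid); cl <- c(cl, rep(c, n))
    stage <- c(stage, rep(c("II", "III", "unknown"), counts[[c]]))
  }
  list(assignments = stats::setNames(cl, ids),
       stage_table = data.frame(patient_id = ids, stage = stage,
                                stringsAsFactors = FALSE))
}

test_that("stage dichotomization follows the early/late convention", {
  expect_equal(dichotomize_stage(c("I", "II", "III", "IV", "unknown")),
               c("early", "early", "late", "late", NA))
  expect_error(dichotomize_stage("IIb"), "stages")
})

test_that("per-cluster stage counts, ratios, and exclusions are correct", {
  x <- make_staged_cohort(list(c(131, 35, 3), c(86, 34, 1), c(41, 26, 1)))
  tab <- stage_by_cluster(x$assignments, x$stage_table)
  expect_equal(tab$n_early, c(131, 86, 41))
  expect_equal(tab$n_late, c(35, 34, 26))
  expect_equal(tab$n_patients, c(169, 121, 68))
  expect_equal(round(tab$ratio, 2), c(3.74, 2.53, 1.58))
  expect_equal(attr(tab, "excluded_unknown"), 5)
})

test_that("a cluster with no late patients has an undefined ratio", {
  x <- make_staged_cohort(list(c(10, 0, 0), c(5, 5, 0)))
  tab <- stage_by_cluster(x$assignments, x$stage_table)
  expect_true(is.na(tab$ratio[1]))
  expect_equal(tab$ratio[2], 1)
})

test_that("patients without a stage entry raise an informative error", {
  x <- make_staged_cohort(list(c(2, 2, 0), c(2, 2, 0)))
  expect_error(
    stage_by_cluster(x$assignments, x$stage_table[-1, ]),
    "c1_p001")
})

test_that("exact enrichment test handles canonical tables", {
  expect_equal(stage_enrichment_exact(rbind(c(10, 10), c(10, 10))), 1.0)
  expect_equal(stage_enrichment_exact(rbind(c(5, 0), c(0, 5))),
               2 / choose(10, 5))
  expect_error(stage_enrichment_exact(rbind(c(0, 0), c(1, 2))), "degenerate")
  expect_error(stage_enrichment_exact(rbind(c(1, 0), c(2, 0))), "degenerate")
})

test_that("exact test matches an independent hypergeometric oracle on 2x2", {
  # oracle: enumerate e (top-left cell), sum hypergeometric probabilities of
  # tables no more probable than the observed one
  oracle_2x2 <- function(m) {
    r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
    es <- max(0, c1 - r2):min(r1, c1)
    pr <- dhyper(es, r1, r2, c1)
    p_obs <- dhyper(m[1, 1], r1, r2, c1)
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
  set.seed(24)
  for (i in 1:25) {
    tb <- matrix(rpois(4, sample(3:15, 1)) + 1, 2, 2)
    expect_equal(stage_enrichment_exact(tb), oracle_2x2(tb),
                 tolerance = 1e-10)
  }
})

test_that("r x 2 exact test agrees with fisher.test and subsetting works", {
  set.seed(25)
  for (i in 1:10) {
    tb <- matrix(rpois(6, 7) + 1, 3, 2)
    expect_equal(stage_enrichment_exact(tb),
                 stats::fisher.test(tb)$p.value, tolerance = 1e-7)
  }
  x <- make_staged_cohort(list(c(12, 3, 0), c(8, 8, 0), c(3, 12, 0)))
  tab <- stage_by_cluster(x$assignments, x$stage_table)
  p_all <- stage_enrichment_exact(tab)
  p_13 <- stage_enrichment_exact(tab, clusters = c(1, 3))
  m13 <- rbind(c(12, 3), c(3, 12))
  expect_equal(p_13, stats::fisher.test(m13)$p.value, tolerance = 1e-10)
  expect_lt(p_13, p_all)
})

test_that("rank-sum p for {1,2,3} vs {4,5,6} matches full enumeration", {
  # oracle: every C(6,3) split of the pooled ranks
  splits <- utils::combn(6, 3)
  sums <- colSums(matrix((1:6)[splits], nrow = 3))
  obs <- sum(1:3)
  dev <- abs(sums - mean(sums))
  p_oracle <- mean(dev >= abs(obs - mean(sums)))
  expect_equal(p_oracle, 0.1)
  mat <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  colnames(mat) <- paste0("P", 1:6)
  res <- differential_mutation(mat, paste0("P", 1:3), paste0("P", 4:6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$direction, "b")
})

test_that("identical score vectors give p = 1", {
  mat <- rbind(g1 = rep(2, 8), g2 = c(1, 2, 3, 4, 1, 2, 3, 4))
  colnames(mat) <- paste0("P", 1:8)
  res <- differential_mutation(mat, paste0("P", 1:4), paste0("P", 5:8))
  expect_equal(res$p_value[res$gene == "g1"], 1)
  expect_equal(res$p_value[res$gene == "g2"], 1)
})

test_that("BH adjustment follows the step-up formula and is monotone", {
  mat <- rbind(g1 = 1:10, g2 = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9),
               g3 = 10:1, g4 = c(1, 3, 2, 4, 6, 5, 7, 9, 8, 10))
  colnames(mat) <- paste0("P", 1:10)
  res <- differential_mutation(mat, paste0("P", 1:5), paste0("P", 6:10))
  expect_equal(res$fdr, p.adjust(res$p_value, "BH"))
  expect_true(!is.unsorted(res$fdr))
  # frozen example of the step-up formula
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("null data yields approximately uniform p-values", {
  set.seed(26)
  mat <- matrix(rgamma(200 * 30, 2, 1), 200, 30,
                dimnames = list(sprintf("g%03d", 1:200), paste0("P", 1:30)))
  res <- differential_mutation(mat, paste0("P", 1:15), paste0("P", 16:30))
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("planted signature genes are recovered at FDR < 0.1", {
  co <- default_cohort(seed = 27)
  late <- names(co$true_cluster)[co$true_cluster == 3]
  early <- names(co$true_cluster)[co$true_cluster == 1]
  res <- differential_mutation(co$score_matrix, late, early)
  sig3 <- co$signature_genes[[3]]
  hits <- res$gene[res$significant & res$direction == "a"]
  expect_gte(mean(sig3 %in% hits), 0.8)
})

test_that("group preconditions are enforced", {
  mat <- matrix(1:12, 2, 6,
                dimnames = list(c("g1", "g2"), paste0("P", 1:6)))
  expect_error(differential_mutation(mat, c("P1", "P2"), c("P2", "P3")),
               "disjoint")
  expect_error(differential_mutation(mat, "P1", c("P2", "P3")),
               "at least 2")
})
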