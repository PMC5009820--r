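# mutclust

Somatic mutation burden subtyping by consensus non-negative matrix
factorization.

Most molecular subtyping of tumors rests on expression, methylation or copy
number. `mutclust` implements the complementary route: discover clinically
meaningful patient subgroups **from somatic point-mutation profiles alone**.
It is aimed at cancer genomics analysts who have per-patient somatic variant
calls (e.g. whole-exome VarScan2 VCFs), variant deleteriousness annotations
(CADD raw scores via dbNSFP) and clinical stage, and want a reproducible,
fully testable pipeline from variants to validated subgroups.

## The method

1. **Burden matrix.** Variants are filtered to somatic, nonsynonymous,
   coding point mutations with dbSNP minor allele frequency < 0.05 (common
   polymorphisms removed). Because CADD raw scores (C-scores) can be
   negative, all scores are shifted by the absolute value of the dataset
   minimum so the smallest maps to 0. The matrix *A* (genes × patients) has
   entries *a(i, j)* = Σ shifted C-scores of the passing mutations of gene
   *i* in patient *j* — non-negative and typically ~96% zeros.
2. **Feature selection.** Genes are ranked by the sample variance
   *S² = Σ(x − x̄)²/(n − 1)* of their scores across patients; the top *n*
   enter clustering.
3. **Clustering.** *A ≈ WH* by NMF with multiplicative updates that minimize
   the generalized Kullback–Leibler divergence
   *D(A‖WH) = Σ [a·log(a/(WH)) − a + WH]*; patient *j* joins the metagene
   with the largest coefficient in column *j* of *H*.
4. **Model selection.** Because NMF is randomly initialized, each
   (gene count, rank *k*) cell is run many times (default 100); binary
   connectivity matrices are averaged into a consensus matrix *C̄*, and the
   average silhouette width *s(i) = (b(i) − a(i))/max(a(i), b(i))* on the
   dissimilarity 1 − *C̄* scores stability. The scan picks the most stable
   cell; final labels come from average-linkage clustering of 1 − *C̄*.
5. **Characterization.** Stages I–II are dichotomized as early, III–IV as
   late (unknown excluded). Stage tendency across clusters is tested by the
   exact conditional test on the cluster × early/late table (Fisher for
   2×2, Freeman–Halton enumeration for r×2); differentially mutated genes
   between clusters by Wilcoxon rank-sum with Benjamini–Hochberg FDR.
6. **Class prediction.** A pluggable classifier (default random forest) is
   evaluated by stratified 10-fold cross-validation; in every fold the top
   500 genes by information gain (Fayyad–Irani MDL discretization) are
   selected on the training patients only. Reports include the pooled
   confusion matrix, per-class TPR/FPR/TNR/FNR/precision/F-measure,
   one-vs-rest ROC/AUC, and a permutation test that re-runs the full
   cross-validation on label-shuffled data.

A seeded synthetic-cohort generator (`synthetic_config()`,
`generate_cohort()`, `generate_variant_records()`) emulates the sparse
heavy-tailed burden regime with planted clusters, signature genes and
cluster-dependent stage odds, so the whole pipeline is testable end to end
without patient data.

## Worked example

```r
library(mutclust)

cfg <- synthetic_config(n_genes = 200, n_patients = 90, n_clusters = 3,
                        signature_genes_per_cluster = 10,
                        signature_hit_prob = 0.9,
                        background_sparsity = 0.9, seed = 42)
cohort <- generate_cohort(cfg)
mat <- drop_empty_genes(cohort$score_matrix)

scan <- scan_models(mat, gene_grid = 60, k_grid = 2:4,
                    runs_per_cell = 20, seed = 7)
scan
#> Consensus NMF model scan
#>  n_top k silhouette
#>     60 2  0.7970792
#>     60 3  0.9911187
#>     60 4  0.7612181
#> selected: 60 genes, k = 3 (average silhouette width 0.991)

stage_by_cluster(scan$best$labels, cohort$stage_table)
#>   cluster n_patients n_early n_late    ratio
#> 1       1         30      23      6 3.833333
#> 2       2         30      19     11 1.727273
#> 3       3         30      18     12 1.500000

cv <- cross_validate(t(mat), scan$best$labels,
                     classifier_random_forest(ntree = 200),
                     n_folds = 10, k_top = 30, seed = 7)
cv
#> 10-fold cross-validation: accuracy 1.0000
#> one-vs-rest AUC: 1=1.000, 2=1.000, 3=1.000
```

The scan selects the planted rank *k* = 3 with a near-ideal consensus
silhouette (0.991: almost every patient pair either always or never
co-clusters over the 20 runs). Cluster 1 is early-stage-enriched (ratio
3.83, i.e. 23 early vs 6 late patients) and cluster 3 the most late-leaning
(1.50); the cluster labels are then perfectly recoverable from the burden
profiles (accuracy 1.0, AUC 1.0), as expected at this planted signal
strength. `run_full(pipeline_config(...))` chains the same stages and
writes every table as TSV/JSON plus a checksummed manifest.

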