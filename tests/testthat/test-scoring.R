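test_that("the filter cascade keeps only somatic nonsynonymous coding SNVs", {
  rec <- rbind(
    make_record(1),                                   # passes
    make_record(2, somatic = FALSE),                  # germline
    make_record(3, consequence = "synonymous"),       # wrong class
    make_record(4, region = "intron"),                # non-coding
    make_record(5),                                   # common polymorphism
    make_record(6, ref = "AT"),                       # indel
    make_record(7, consequence = "stop_gain")         # excluded by default
  )
  ann <- make_annotation(rec, cadd_raw = 1:7)
  ann$dbsnp_maf <- c(NA, NA, NA, NA, 0.2, NA, NA)
  out <- filter_variants(rec, ann)
  expect_equal(out$pos, 1)
  audit <- attr(out, "filter_audit")
  expect_equal(unname(audit[c("germline", "consequence", "noncoding",
                              "common_maf", "indel")]),
               c(1, 2, 1, 1, 1))
  # stop-gain is kept when asked for
  out2 <- filter_variants(rec, ann, include_stop = TRUE)
  expect_setequal(out2$pos, c(1, 7))
})

test_that("variants below the MAF threshold or absent from dbSNP are kept", {
  rec <- rbind(make_record(1), make_record(2), make_record(3))
  ann <- make_annotation(rec, cadd_raw = c(1, 2, 3),
                         dbsnp_maf = c(NA, 0.049, 0.05))
  out <- filter_variants(rec, ann)
  expect_equal(out$pos, c(1, 2))
})

test_that("records missing from the annotation follow the chosen policy", {
  rec <- rbind(make_record(1), make_record(2))
  ann <- make_annotation(make_record(1), cadd_raw = 5)
  expect_warning(out <- filter_variants(rec, ann), "missing")
  expect_equal(out$pos, 1)
  expect_error(filter_variants(rec, ann, on_missing = "error"), "missing")
})

test_that("filtering is idempotent and order-preserving", {
  cfg <- small_config(40, 15, seed = 8)
  vr <- generate_variant_records(cfg)
  once <- filter_variants(vr$records, vr$annotations)
  twice <- filter_variants(once[names(vr$records)], vr$annotations)
  expect_equal(once$pos, twice$pos)
  expect_false(is.unsorted(match(once$pos, vr$records$pos)))
})

test_that("score shifting maps the minimum to zero and records the offset", {
  s <- shift_scores(c(-3, 0, 2))
  expect_equal(as.numeric(s), c(0, 3, 5))
  expect_equal(attr(s, "offset"), 3)
  s2 <- shift_scores(c(1, 2))
  expect_equal(as.numeric(s2), c(1, 2))
  expect_equal(attr(s2, "offset"), 0)
  expect_equal(as.numeric(shift_scores(c(-1, -1))), c(0, 0))
  expect_error(shift_scores(numeric(0)), "empty")
})

test_that("matrix entries sum shifted scores per gene and patient", {
  rec <- rbind(make_record(1), make_record(2),
               make_record(3, patient = "P2", gene = "G2"))
  mat <- build_matrix(rec, c(4.1, 2.9, 1.5), patients = c("P1", "P2", "P3"))
  expect_equal(mat["G1", "P1"], 7.0)
  expect_equal(mat["G2", "P2"], 1.5)
  expect_equal(unname(mat[, "P3"]), c(0, 0))    # roster keeps empty patients
  # permutation invariance to record order
  perm <- c(3, 1, 2)
  mat2 <- build_matrix(rec[perm, ], c(4.1, 2.9, 1.5)[perm],
                       patients = c("P1", "P2", "P3"))
  expect_equal(mat, mat2)
})

test_that("degenerate build inputs are rejected", {
  rec <- make_record(1)
  expect_error(build_matrix(rec, c(1, 2)), "one-to-one")
  rec$gene <- NA_character_
  expect_error(build_matrix(rec, 1), "gene symbol")
})

test_that("score_matrix records run metadata", {
  cfg <- small_config(60, 20, seed = 12)
  vr <- generate_variant_records(cfg)
  mat <- score_matrix(vr$records, vr$annotations, patients = vr$patients)
  expect_true(attr(mat, "offset") >= 0)
  expect_true(attr(mat, "zero_fraction") > 0.5)
  expect_true(all(rowSums(mat != 0) >= 1))   # no empty gene rows
})

test_that("minimal VCF written by the generator parses back losslessly", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  cfg <- small_config(30, 10, seed = 21)
  co <- generate_cohort(cfg)
  paths <- write_cohort(co, dir)
  rec <- read_vcf_records(paths[["vcf"]])
  vr <- generate_variant_records(cfg)
  expect_equal(rec[order(rec$pos), ]$pos, vr$records[order(vr$records$pos), ]$pos)
  ann <- read.delim(paths[["annotations"]])
  scored <- score_matrix(rec, ann, patients = vr$patients)
  expect_equal(scored[, ], co$score_matrix[rownames(scored), ],
               ignore_attr = TRUE)
})
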