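# Variant filtering and construction of the mutation score matrix.
#
# The burden matrix has genes in rows and patients in columns; entry (i, j) is
# the sum of shifted CADD raw scores (C-scores) of the somatic, nonsynonymous,
# coding point mutations of gene i observed in patient j. CADD raw scores are
# real-valued and can be negative, so they are shifted to be non-negative
# before summation (NMF requires non-negative input).

CONSEQUENCE_LEVELS <- c("nonsynonymous", "synonymous", "stop_gain",
                        "stop_loss", "other")
REGION_LEVELS <- c("coding", "intron", "utr", "intergenic", "other")

validate_records <- function(records) {
  needed <- c("chrom", "pos", "ref", "alt", "patient_id", "somatic",
              "consequence", "region", "gene")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("variant records are missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) && any(records$pos < 1)) {
    stop("variant positions must be 1-based (pos >= 1)", call. = FALSE)
  }
  if (nrow(records) && any(records$ref == records$alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  records
}

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Filter somatic variant records for burden scoring
#'
#' Applies the filter cascade used to define scorable mutations: keep somatic
#' point mutations only (indels dropped), keep the nonsynonymous consequence
#' class (optionally also stop gain/loss), keep coding-region variants, and
#' remove common polymorphisms with dbSNP minor allele frequency at or above
#' `maf_threshold`. Variants absent from dbSNP cannot exceed the threshold and
#' are retained. Input order is preserved and the number of records removed at
#' each stage is attached as the `"filter_audit"` attribute.
#'
#' @param records data.frame of variant records with columns `chrom`, `pos`,
#'   `ref`, `alt`, `patient_id`, `somatic` (logical), `consequence` (one of
#'   `r paste(CONSEQUENCE_LEVELS, collapse = ", ")`), `region` (one of
#'   `r paste(REGION_LEVELS, collapse = ", ")`), `gene`.
#' @param annotations data.frame keyed by (`chrom`, `pos`, `ref`, `alt`) with
#'   columns `cadd_raw` and `dbsnp_maf` (`NA` when the variant has no dbSNP
#'   frequency).
#' @param maf_threshold variants with `dbsnp_maf >= maf_threshold` are removed
#'   as common polymorphisms (default 0.05).
#' @param include_stop also keep `stop_gain` / `stop_loss` consequences
#'   (default `FALSE`: only the nonsynonymous class is scored).
#' @param on_missing what to do with records that have no annotation entry:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return The retained records with a `cadd_raw` column appended, attribute
#'   `"filter_audit"` (named counts removed per stage).
#' @export
filter_variants <- function(records, annotations, maf_threshold = 0.05,
                            include_stop = FALSE,
                            on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  records <- validate_records(records)
  stopifnot_prob(maf_threshold, "maf_threshold")

  audit <- c(input = nrow(records))
  ann_key <- variant_key(annotations)
  if (anyDuplicated(ann_key)) {
    stop("annotation table has duplicated (chrom, pos, ref, alt) keys",
         call. = FALSE)
  }
  idx <- match(variant_key(records), ann_key)
  if (anyNA(idx)) {
    n_missing <- sum(is.na(idx))
    if (on_missing == "error") {
      stop(n_missing, " record(s) missing from the annotation lookup",
           call. = FALSE)
    }
    warning(n_missing, " record(s) missing from the annotation lookup; dropped",
            call. = FALSE)
  }
  keep <- !is.na(idx)
  audit["unannotated"] <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  ann <- annotations[idx[keep], , drop = FALSE]

  # point mutations only
  snv <- nchar(records$ref) == 1L & nchar(records$alt) == 1L
  audit["indel"] <- sum(!snv)
  records <- records[snv, , drop = FALSE]; ann <- ann[snv, , drop = FALSE]

  som <- records$somatic
  audit["germline"] <- sum(!som)
  records <- records[som, , drop = FALSE]; ann <- ann[som, , drop = FALSE]

  kept_csq <- if (include_stop) {
    c("nonsynonymous", "stop_gain", "stop_loss")
  } else "nonsynonymous"
  csq <- records$consequence %in% kept_csq
  audit["consequence"] <- sum(!csq)
  records <- records[csq, , drop = FALSE]; ann <- ann[csq, , drop = FALSE]

  cod <- records$region == "coding"
  audit["noncoding"] <- sum(!cod)
  records <- records[cod, , drop = FALSE]; ann <- ann[cod, , drop = FALSE]

  common <- !is.na(ann$dbsnp_maf) & ann$dbsnp_maf >= maf_threshold
  audit["common_maf"] <- sum(common)
  records <- records[!common, , drop = FALSE]; ann <- ann[!common, , drop = FALSE]

  audit["retained"] <- nrow(records)
  records$cadd_raw <- ann$cadd_raw
  rownames(records) <- NULL
  attr(records, "filter_audit") <- audit
  records
}

#' Shift scores to be non-negative
#'
#' Adds the absolute value of the smallest observed score (or 0 if all scores
#' are already non-negative) so that the minimum maps to 0 and all shifted
#' scores are non-negative. The applied offset is attached as the `"offset"`
#' attribute so a run can be reproduced.
#'
#' @param scores numeric vector of raw C-scores (may be negative).
#' @return Non-negative numeric vector of the same length, attribute `"offset"`.
#' @export
shift_scores <- function(scores) {
  if (length(scores) == 0L) stop("cannot shift an empty score vector",
                                 call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  offset <- abs(min(c(scores, 0)))
  out <- scores + offset
  attr(out, "offset") <- offset
  out
}

#' Build the gene-by-patient mutation score matrix
#'
#' Entry (gene, patient) is the sum of the shifted scores of that gene and
#' patient's records. Genes with no passing record anywhere are excluded (every
#' retained row has at least one nonzero-count cell); patients with no passing
#' record are kept as all-zero columns when listed in `patients`.
#'
#' @param records passing variant records (one row per scored mutation).
#' @param shifted_scores non-negative score per record, aligned with `records`.
#' @param patients full patient roster (default: patients seen in `records`).
#' @return Numeric matrix with gene rownames (sorted) and patient colnames.
#' @export
build_matrix <- function(records, shifted_scores,
                         patients = sort(unique(records$patient_id))) {
  if (nrow(records) != length(shifted_scores)) {
    stop("records and shifted_scores must be aligned one-to-one", call. = FALSE)
  }
  if (any(shifted_scores < 0)) stop("shifted scores must be non-negative",
                                    call. = FALSE)
  if (nrow(records) && any(is.na(records$gene) | records$gene == "")) {
    stop("record without a gene symbol", call. = FALSE)
  }
  genes <- sort(unique(records$gene))
  mat <- matrix(0, nrow = length(genes), ncol = length(patients),
                dimnames = list(genes, patients))
  if (nrow(records)) {
    i <- match(records$gene, genes)
    j <- match(records$patient_id, patients)
    if (anyNA(j)) stop("records contain patients not in the roster",
                       call. = FALSE)
    for (r in seq_along(i)) mat[i[r], j[r]] <- mat[i[r], j[r]] + shifted_scores[r]
  }
  mat
}

#' Score a cohort: filter, shift, and build the matrix in one step
#'
#' Runs [filter_variants()], shifts the C-scores of the passing records with
#' [shift_scores()] (the offset is the dataset minimum of the scores entering
#' the matrix), and assembles the matrix with [build_matrix()].
#'
#' @inheritParams filter_variants
#' @param patients full patient roster (so mutation-free patients keep an
#'   all-zero column).
#' @return Matrix as from [build_matrix()], with attributes `"offset"`,
#'   `"filter_audit"` and `"zero_fraction"` recorded as run metadata.
#' @export
score_matrix <- function(records, annotations, maf_threshold = 0.05,
                         include_stop = FALSE,
                         on_missing = c("drop", "error"),
                         patients = NULL) {
  passing <- filter_variants(records, annotations, maf_threshold,
                             include_stop, on_missing)
  if (is.null(patients)) patients <- sort(unique(passing$patient_id))
  if (nrow(passing) == 0L) {
    mat <- matrix(0, 0, length(patients),
                  dimnames = list(character(), patients))
    attr(mat, "offset") <- 0
  } else {
    shifted <- shift_scores(passing$cadd_raw)
    mat <- build_matrix(passing, shifted, patients = patients)
    # the record carrying the dataset-minimum score maps to 0 after the
    # shift; a gene whose only mutation that is may end up all-zero
    mat <- drop_empty_genes(mat)
    attr(mat, "offset") <- attr(shifted, "offset")
  }
  attr(mat, "filter_audit") <- attr(passing, "filter_audit")
  attr(mat, "zero_fraction") <- if (length(mat)) zero_fraction(mat) else NA_real_
  mat
}

#' Read variant records from a minimal VCF
#'
#' Parses a combined VCF whose INFO field carries `PATIENT`, `SOMATIC`,
#' `CSQ_CLASS`, `REGION` and `GENE` keys (the format written by
#' [write_cohort()]), one record per line. Multi-allelic lines are split into
#' one record per alternate allele.
#'
#' @param path VCF file.
#' @return data.frame of variant records suitable for [filter_variants()].
#' @export
read_vcf_records <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  info <- fix$INFO[idx]
  info_field <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    has <- grepl(paste0("(^|;)", key, "="), info)
    out <- rep(NA_character_, length(info))
    out[has] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  data.frame(
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alt_list),
    patient_id = info_field("PATIENT"),
    somatic = info_field("SOMATIC") == "1",
    consequence = info_field("CSQ_CLASS"),
    region = info_field("REGION"),
    gene = info_field("GENE"),
    stringsAsFactors = FALSE
  )
}
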