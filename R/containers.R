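#' Construct a dosage matrix
#'
#' A `dosage_matrix` holds expected risk-allele counts (dosages in `[0, 2]`)
#' for a set of individuals at a set of SNPs, together with SNP metadata and
#' a cohort label. Dosages may be fractional (e.g. after imputation).
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns.
#'   Row names are individual ids, column names are rsids (supplied via
#'   `individual_ids` / `snp_info` if absent).
#' @param snp_info data.frame with columns `rsid`, `chrom`, `pos`,
#'   `risk_allele`, `other_allele`, one row per dosage column, in column
#'   order. `risk_allele` is the allele the dosage counts.
#' @param cohort single character cohort label.
#' @param individual_ids optional character vector of row ids.
#'
#' @return an object of class `dosage_matrix`: a list with elements
#'   `dosages`, `snp_info`, `cohort`.
#' @export
dosage_matrix <- function(dosages, snp_info, cohort,
                          individual_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(individual_ids)) {
    individual_ids <- sprintf("%s_%06d", cohort, seq_len(nrow(dosages)))
  }
  if (anyDuplicated(individual_ids)) {
    stop("duplicate individual ids in cohort '", cohort, "'")
  }
  if (anyDuplicated(snp_info$rsid)) stop("duplicate rsids in snp_info")
  if (nrow(snp_info) != ncol(dosages)) {
    stop("snp_info rows (", nrow(snp_info), ") != dosage columns (",
         ncol(dosages), ")")
  }
  rng <- range(dosages)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2] with no missing values")
  }
  rownames(dosages) <- individual_ids
  colnames(dosages) <- snp_info$rsid
  structure(
    list(dosages = dosages,
         snp_info = as.data.frame(snp_info),
         cohort = as.character(cohort)),
    class = "dosage_matrix"
  )
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> cohort '%s': %d individuals x %d SNPs\n",
              x$cohort, nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' Validate a per-individual phenotype/covariate table
#'
#' The cohort table carries disease status and the covariates used by all
#' association models: `id`, `status` (0 = control, 1 = case), `age`,
#' `sex` (`"F"`/`"M"`), `pc1`, `pc2`.
#'
#' @param df data.frame with the columns above.
#' @return the validated data.frame (status coerced to integer).
#' @export
cohort_table <- function(df) {
  need <- c("id", "status", "age", "sex", "pc1", "pc2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table missing columns: ",
                         paste(miss, collapse = ", "))
  df$status <- as.integer(df$status)
  if (!all(df$status %in% c(0L, 1L))) stop("status must be 0/1")
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (anyDuplicated(df$id)) stop("duplicate ids in cohort table")
  as.data.frame(df)
}

#' Construct a PRS scoring panel
#'
#' A panel is an ordered table of risk variants (one row per SNP with risk
#' allele, odds ratio, p-value and source study) plus the three named index
#' subsets used throughout the analysis: `full` (all SNPs), `no_hla` (all but
#' the HLA tag SNP) and `hla_only` (the tag SNP alone).
#'
#' @param snps data.frame with columns `rsid`, `chrom`, `pos`, `risk_allele`,
#'   `other_allele`, `or`, `p`, `source`. An optional logical column
#'   `flip_dosage` marks SNPs whose dosage counts the other allele
#'   (scoring then uses `2 - dosage`).
#' @param hla_tag rsid of the designated large-effect HLA tag SNP; must be
#'   present in `snps` (use `NULL` for a panel with no tag, in which case
#'   only the `full` subset is defined).
#' @return object of class `prs_panel` with elements `snps`, `hla_tag`,
#'   `subsets` (named list of integer index vectors).
#' @export
prs_panel <- function(snps, hla_tag = NULL) {
  need <- c("rsid", "chrom", "pos", "risk_allele", "other_allele",
            "or", "p", "source")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("panel missing columns: ", paste(miss, collapse = ", "))
  snps <- as.data.frame(snps)
  if (anyDuplicated(snps$rsid)) stop("panel rsids must be unique")
  if (any(snps$or <= 0)) stop("odds ratios must be > 0")
  if (any(snps$p <= 0 | snps$p > 1)) stop("p-values must lie in (0, 1]")
  if (any(snps$risk_allele == snps$other_allele)) {
    stop("risk and other allele must differ")
  }
  if (is.null(snps$flip_dosage)) snps$flip_dosage <- FALSE
  subsets <- list(full = seq_len(nrow(snps)))
  if (!is.null(hla_tag)) {
    i <- match(hla_tag, snps$rsid)
    if (is.na(i)) stop("hla_tag '", hla_tag, "' not in panel")
    subsets$no_hla <- setdiff(seq_len(nrow(snps)), i)
    subsets$hla_only <- i
  }
  structure(list(snps = snps, hla_tag = hla_tag, subsets = subsets),
            class = "prs_panel")
}

#' @export
print.prs_panel <- function(x, ...) {
  cat(sprintf("<prs_panel> %d SNPs; subsets: %s%s\n",
              nrow(x$snps),
              paste(sprintf("%s(%d)", names(x$subsets),
                            lengths(x$subsets)), collapse = ", "),
              if (is.null(x$hla_tag)) "" else paste0("; HLA tag ", x$hla_tag)))
  invisible(x)
}
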