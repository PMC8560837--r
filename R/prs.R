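# Polygenic risk scoring: weighted dosage sums and cross-cohort z-scoring.

#' Compute raw polygenic risk scores
#'
#' The raw score is the unnormalised weighted sum
#' `raw_i = sum_j ln(OR_j) * d_ij` over the SNPs of the requested panel
#' subset, where `d_ij` counts the risk allele (dosage columns flagged
#' `flip_dosage` are counted as `2 - dosage`). The sum (rather than PRSice's
#' per-SNP average) keeps the additivity `full = no_hla + hla_only` exact;
#' the scale is irrelevant after z-scoring.
#'
#' Any subset SNP absent from the dosages is an error: no silent
#' mean-imputation, mirroring the inclusion rule that panel SNPs must be
#' present in every cohort.
#'
#' @param dosages a `dosage_matrix`.
#' @param panel a `prs_panel`.
#' @param subset_name one of the panel's subset names (default `"full"`).
#' @return a `score_vector` data.frame with columns
#'   `id, cohort, subset, raw, z` (`z` is `NA` until [pooled_zscore()]).
#' @export
prs_score <- function(dosages, panel, subset_name = "full") {
  if (!subset_name %in% names(panel$subsets)) {
    stop("unknown subset '", subset_name, "'")
  }
  sub <- panel$subsets[[subset_name]]
  snps <- panel$snps[sub, , drop = FALSE]
  idx <- match(snps$rsid, colnames(dosages$dosages))
  if (anyNA(idx)) {
    stop("subset SNP(s) missing from dosages: ",
         paste(snps$rsid[is.na(idx)], collapse = ", "))
  }
  d <- dosages$dosages[, idx, drop = FALSE]
  if (any(snps$flip_dosage)) {
    d[, snps$flip_dosage] <- 2 - d[, snps$flip_dosage, drop = FALSE]
  }
  w <- log(snps$or)
  out <- data.frame(id = rownames(dosages$dosages),
                    cohort = dosages$cohort,
                    subset = subset_name,
                    raw = as.numeric(d %*% w),
                    z = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_vector", class(out))
  out
}

#' Standardise scores by pooled z-scoring across cohorts
#'
#' All supplied score vectors (one per cohort, same subset) are pooled; the
#' pooled mean and SD define the z-transform, so per-cohort z means may
#' differ from 0 — this is what makes between-population mean comparisons
#' meaningful.
#'
#' @param scores a single `score_vector` or a list of them.
#' @return list of score vectors with the `z` column filled (a single input
#'   is returned as a single score vector).
#' @export
pooled_zscore <- function(scores) {
  single <- inherits(scores, "data.frame")
  if (single) scores <- list(scores)
  raw <- unlist(lapply(scores, function(s) s$raw))
  if (length(raw) < 2) stop("need >= 2 individuals to z-score")
  m <- mean(raw)
  s <- stats::sd(raw)
  if (s == 0) stop("zero pooled SD: scores cannot be z-scored")
  scores <- lapply(scores, function(sc) { sc$z <- (sc$raw - m) / s; sc })
  if (single) scores[[1]] else scores
}

#' Risk-allele frequency among controls
#'
#' Dosage-based frequency of the counted (risk) allele in individuals
#' without the disease: `sum(dosages) / (2 * n_controls)`.
#'
#' @param dosages a `dosage_matrix`.
#' @param tab the cohort table keyed to the dosages.
#' @param rsid SNP to evaluate.
#' @return frequency in `[0, 1]`.
#' @export
control_raf <- function(dosages, tab, rsid) {
  j <- match(rsid, colnames(dosages$dosages))
  if (is.na(j)) stop("rsid '", rsid, "' not in dosages")
  ctrl <- tab$id[tab$status == 0L]
  if (!length(ctrl)) stop("no controls in cohort table")
  d <- dosages$dosages[match(ctrl, rownames(dosages$dosages)), j]
  if (anyNA(d)) stop("control ids missing from dosage matrix")
  sum(d) / (2 * length(ctrl))
}
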