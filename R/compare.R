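# Between-population comparisons: control PRS means and per-SNP risk-allele
# frequencies.

#' Welch two-sample t test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value, for comparing control PRS
#' distributions between cohorts.
#'
#' @param a,b numeric samples (each n >= 2, nonzero variance).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("both samples have zero variance")
  sa <- va / na; sb <- vb / nb
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_a = mean(a), mean_b = mean(b))
}

#' Compare a SNP's control risk-allele frequency between two cohorts
#'
#' Control RAFs are computed from dosages ([control_raf()]); because imputed
#' dosages are fractional, allele "counts" for the contingency table are the
#' rounded `2n * RAF` (and its complement). The 2x2 risk/other x cohort
#' table is tested with Pearson's chi-squared (df = 1, no continuity
#' correction).
#'
#' @param dosages_a,dosages_b `dosage_matrix` per cohort.
#' @param tab_a,tab_b matching cohort tables.
#' @param rsid SNP to compare.
#' @return object of class `freq_comparison`: list with `rsid`, `cohort_a`,
#'   `cohort_b`, `raf_a`, `raf_b`, `allele_counts` (2x2), `chi2`, `p`.
#' @export
raf_chi2 <- function(dosages_a, tab_a, dosages_b, tab_b, rsid) {
  raf_a <- control_raf(dosages_a, tab_a, rsid)
  raf_b <- control_raf(dosages_b, tab_b, rsid)
  na <- 2 * sum(tab_a$status == 0L)
  nb <- 2 * sum(tab_b$status == 0L)
  counts <- rbind(risk = c(round(na * raf_a), round(nb * raf_b)),
                  other = c(na - round(na * raf_a), nb - round(nb * raf_b)))
  colnames(counts) <- c(dosages_a$cohort, dosages_b$cohort)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero margin in allele count table for ", rsid)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi2 <- sum((counts - expected)^2 / expected)
  structure(list(rsid = rsid,
                 cohort_a = dosages_a$cohort, cohort_b = dosages_b$cohort,
                 raf_a = raf_a, raf_b = raf_b,
                 allele_counts = counts, chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE)),
            class = "freq_comparison")
}

#' Per-SNP frequency comparison report across cohort pairs
#'
#' Runs [raf_chi2()] for every panel SNP and cohort pair and returns a tidy
#' table with a convenience Bonferroni column (raw p-values remain the
#' primary output; no adjustment is applied to conclusions).
#'
#' @param cohorts named list of `list(dosages =, table =)` per cohort.
#' @param panel a `prs_panel`.
#' @return data.frame
#'   `rsid cohort_a cohort_b raf_a raf_b chi2 p p_bonferroni`.
#' @export
raf_comparison_report <- function(cohorts, panel) {
  pairs <- utils::combn(names(cohorts), 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    a <- cohorts[[pr[1]]]; b <- cohorts[[pr[2]]]
    for (rs in panel$snps$rsid) {
      fc <- raf_chi2(a$dosages, a$table, b$dosages, b$table, rs)
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = rs, cohort_a = fc$cohort_a, cohort_b = fc$cohort_b,
        raf_a = fc$raf_a, raf_b = fc$raf_b, chi2 = fc$chi2, p = fc$p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(panel$snps))
  out
}
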