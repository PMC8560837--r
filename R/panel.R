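# Panel construction: allele harmonisation, inverse-variance meta-analysis of
# duplicated SNPs, p-value filtering and LD clumping.

# SE of the log-OR recovered from a two-sided p-value: |z| = qnorm(1 - p/2),
# SE = |log OR| / |z|. Undefined when p = 1 (z = 0) or log OR = 0.
se_from_p <- function(log_or, p) {
  z <- stats::qnorm(1 - p / 2)
  ifelse(z <= 0 | log_or == 0, NA_real_, abs(log_or) / z)
}

#' Pool duplicated SNP effect entries by inverse-variance meta-analysis
#'
#' Entries sharing one rsid (already harmonised to a common risk allele) are
#' combined on the log-OR scale with weights `1/SE^2`, where each entry's SE
#' is recovered from its p-value. Entries with undefined SE (p = 1 or
#' OR = 1) are dropped with a warning.
#'
#' @param effects data.frame of SNP effect rows sharing one rsid (columns as
#'   in [read_effect_table()]).
#' @return a single-row data.frame with the pooled `or` and `p`; `source`
#'   concatenates the input sources. A single input row is returned
#'   unchanged.
#' @export
meta_dedupe <- function(effects) {
  effects <- as.data.frame(effects)
  if (nrow(effects) == 0) stop("meta_dedupe: no entries")
  if (length(unique(effects$rsid)) != 1) {
    stop("meta_dedupe: entries must share one rsid")
  }
  if (length(unique(effects$risk_allele)) != 1) {
    stop("meta_dedupe: entries must be harmonised to one risk allele")
  }
  if (nrow(effects) == 1) return(effects)
  b <- log(effects$or)
  se <- se_from_p(b, effects$p)
  bad <- !is.finite(se)
  if (any(bad)) {
    warning(sum(bad), " entr", if (sum(bad) == 1) "y" else "ies",
            " for ", effects$rsid[1],
            " with undefined SE (p = 1 or OR = 1) excluded from meta-analysis")
    effects <- effects[!bad, , drop = FALSE]
    b <- b[!bad]; se <- se[!bad]
  }
  if (!nrow(effects)) stop("meta_dedupe: all entries for ",
                           effects$rsid[1], " had undefined SE")
  if (nrow(effects) == 1) return(effects)
  w <- 1 / se^2
  beta <- sum(w * b) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- beta / pooled_se
  out <- effects[1, , drop = FALSE]
  out$or <- exp(beta)
  out$p <- 2 * stats::pnorm(-abs(z))
  out$source <- paste(unique(effects$source), collapse = ";")
  rownames(out) <- NULL
  out
}

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Harmonise one SNP effect to the allele counted by the dosage data
#'
#' If the stated risk allele is the dosage's counted allele the entry is
#' returned unchanged. If it matches the non-counted allele, the entry is
#' re-expressed on the counted-allele scale: the risk allele and OR are kept
#' (risk OR stays > the flip of itself) and `flip_dosage = TRUE` marks that
#' scoring must use `2 - dosage`. Strand-ambiguous (A/T, C/G) SNPs are
#' excluded (returns `NULL` with a warning), as are entries whose allele pair
#' does not match the dosage alleles at all.
#'
#' @param effect single-row SNP effect data.frame.
#' @param counted_allele allele the dosage column counts.
#' @param other_allele the dosage's non-counted allele.
#' @return the harmonised single-row data.frame with a `flip_dosage` logical
#'   column, or `NULL` if the SNP is excluded.
#' @export
harmonise_alleles <- function(effect, counted_allele, other_allele) {
  effect <- as.data.frame(effect)
  if (is_palindromic(effect$risk_allele, effect$other_allele)) {
    warning("palindromic SNP ", effect$rsid, " (",
            effect$risk_allele, "/", effect$other_allele, ") excluded")
    return(NULL)
  }
  if (effect$risk_allele == counted_allele &&
      effect$other_allele == other_allele) {
    effect$flip_dosage <- FALSE
    return(effect)
  }
  if (effect$risk_allele == other_allele &&
      effect$other_allele == counted_allele) {
    effect$flip_dosage <- TRUE
    return(effect)
  }
  warning("SNP ", effect$rsid, ": alleles ", effect$risk_allele, "/",
          effect$other_allele, " do not match dosage alleles ",
          counted_allele, "/", other_allele, "; excluded")
  NULL
}

#' Greedy LD clumping of a panel
#'
#' Standard greedy clumping: visit SNPs by ascending p-value (ties broken by
#' larger `|log OR|`, then rsid); keep the best remaining SNP and drop every
#' unkept SNP on the same chromosome within `window_bp` of it whose squared
#' Pearson correlation of dosages exceeds `r2_max` (strictly). The window is
#' centred: `|pos difference| <= window_bp`. Survivors keep their input
#' order. Zero-variance dosage columns are treated as uncorrelated with
#' everything (with a message).
#'
#' @param panel a `prs_panel`.
#' @param dosages a `dosage_matrix` covering every panel SNP (the r2 is
#'   always computed from these dosages, never from an external reference).
#' @param r2_max retained maximum squared correlation (default 0.25).
#' @param window_bp window half-width in bp (default 200,000).
#' @return the clumped `prs_panel`; attribute `"clump_report"` is a
#'   data.frame `kept_rsid dropped_rsid r2 distance_bp`.
#' @export
ld_clump <- function(panel, dosages, r2_max = 0.25, window_bp = 200000) {
  snps <- panel$snps
  idx <- match(snps$rsid, colnames(dosages$dosages))
  if (anyNA(idx)) {
    stop("panel SNP(s) missing from dosages: ",
         paste(snps$rsid[is.na(idx)], collapse = ", "))
  }
  d <- dosages$dosages[, idx, drop = FALSE]
  sds <- apply(d, 2, stats::sd)
  if (any(sds == 0)) {
    message("zero-variance dosage column(s) treated as r2 = 0: ",
            paste(snps$rsid[sds == 0], collapse = ", "))
  }
  ord <- order(snps$p, -abs(log(snps$or)), snps$rsid)
  alive <- rep(TRUE, nrow(snps))
  kept <- logical(nrow(snps))
  report <- list()
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive &
                    snps$chrom == snps$chrom[i] &
                    abs(snps$pos - snps$pos[i]) <= window_bp)
    for (j in near) {
      if (sds[i] == 0 || sds[j] == 0) next
      r2 <- stats::cor(d[, i], d[, j])^2
      if (r2 > r2_max) {
        alive[j] <- FALSE
        report[[length(report) + 1L]] <- data.frame(
          kept_rsid = snps$rsid[i], dropped_rsid = snps$rsid[j],
          r2 = r2, distance_bp = abs(snps$pos[j] - snps$pos[i]))
      }
    }
  }
  out <- prs_panel(snps[kept, , drop = FALSE],
                   hla_tag = if (!is.null(panel$hla_tag) &&
                                 kept[match(panel$hla_tag, snps$rsid)])
                     panel$hla_tag else NULL)
  attr(out, "clump_report") <- if (length(report)) {
    do.call(rbind, report)
  } else {
    data.frame(kept_rsid = character(), dropped_rsid = character(),
               r2 = numeric(), distance_bp = numeric())
  }
  out
}

#' Build a scoring panel from a raw effect table
#'
#' Applies the panel QC pipeline: drop entries without an OR or risk allele,
#' keep entries with `p <= p_max` (default 1e-3), harmonise alleles to the
#' dosage data (palindromic SNPs excluded), pool duplicated rsids by
#' inverse-variance meta-analysis, and (when dosages are supplied) LD-clump
#' at `r2_max` within `window_bp`.
#'
#' @param effects SNP effect data.frame (possibly with duplicated rsids).
#' @param hla_tag rsid of the HLA tag SNP (or `NULL`).
#' @param dosages optional `dosage_matrix` used both to harmonise alleles and
#'   to compute clumping r2; if `NULL`, harmonisation and clumping are
#'   skipped.
#' @param p_max inclusion p-value threshold.
#' @param r2_max,window_bp clumping parameters, see [ld_clump()].
#' @return a `prs_panel`.
#' @export
build_panel <- function(effects, hla_tag = NULL, dosages = NULL,
                        p_max = 1e-3, r2_max = 0.25, window_bp = 200000) {
  effects <- as.data.frame(effects)
  effects <- effects[!is.na(effects$or) & !is.na(effects$risk_allele) &
                       nzchar(effects$risk_allele), , drop = FALSE]
  effects <- effects[effects$p <= p_max, , drop = FALSE]
  if (!nrow(effects)) stop("no SNPs survive the p-value filter")
  if (!is.null(dosages)) {
    si <- dosages$snp_info
    harm <- lapply(seq_len(nrow(effects)), function(i) {
      k <- match(effects$rsid[i], si$rsid)
      if (is.na(k)) return(NULL)  # must be present in the cohort dosages
      if (is.na(si$risk_allele[k])) {
        # plain dosage TSVs carry no allele metadata; by convention they
        # count the effect table's risk allele
        ef <- effects[i, , drop = FALSE]
        ef$flip_dosage <- FALSE
        return(ef)
      }
      harmonise_alleles(effects[i, , drop = FALSE],
                        si$risk_allele[k], si$other_allele[k])
    })
    effects <- do.call(rbind, harm)
    if (is.null(effects) || !nrow(effects)) {
      stop("no SNPs survive allele harmonisation")
    }
  } else {
    effects$flip_dosage <- FALSE
  }
  # align duplicated entries reported in opposite orientation to the first
  # occurrence's risk allele (OR -> 1/OR, alleles swapped) before pooling
  align_group <- function(g) {
    ref_risk <- g$risk_allele[1]; ref_other <- g$other_allele[1]
    for (i in seq_len(nrow(g))[-1]) {
      if (g$risk_allele[i] == ref_other && g$other_allele[i] == ref_risk) {
        g$or[i] <- 1 / g$or[i]
        g$risk_allele[i] <- ref_risk
        g$other_allele[i] <- ref_other
        g$flip_dosage[i] <- g$flip_dosage[1]
      } else if (g$risk_allele[i] != ref_risk ||
                 g$other_allele[i] != ref_other) {
        warning("rsid ", g$rsid[i], ": inconsistent allele pairs across ",
                "sources; extra entry excluded")
        g$or[i] <- NA_real_
      }
    }
    g[!is.na(g$or), , drop = FALSE]
  }
  groups <- lapply(split(effects, effects$rsid), align_group)
  pooled <- do.call(rbind, lapply(groups, meta_dedupe))
  # restore input order of first occurrence
  pooled <- pooled[order(match(pooled$rsid, effects$rsid)), , drop = FALSE]
  rownames(pooled) <- NULL
  panel <- prs_panel(pooled,
                     hla_tag = if (!is.null(hla_tag) &&
                                   hla_tag %in% pooled$rsid) hla_tag else NULL)
  if (!is.null(dosages)) {
    panel <- ld_clump(panel, dosages, r2_max = r2_max, window_bp = window_bp)
  }
  panel
}
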