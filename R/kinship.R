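# Genomic kinship estimation and greedy unrelated-subset selection.

# Standardise dosage columns to (d - 2p)/sqrt(2p(1-p)) using sample allele
# frequencies; monomorphic SNPs are dropped (with a message).
standardise_dosages <- function(d, context = "kinship") {
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    message(sum(!poly), " monomorphic SNP(s) dropped from ", context)
    d <- d[, poly, drop = FALSE]
    p <- p[poly]
  }
  if (!ncol(d)) stop("no polymorphic SNPs available for ", context)
  sweep(sweep(d, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
}

#' Estimate a genomic kinship matrix
#'
#' Method-of-moments estimator on the kinship scale:
#' `phi_ij = (1/2m) * sum_k (d_ik - 2p_k)(d_jk - 2p_k) / (2 p_k (1 - p_k))`
#' with `p_k` the sample allele frequency. Self-kinship is ~0.5 for
#' non-inbred individuals and ~0.25 for full siblings. Monomorphic SNPs are
#' dropped from the sum.
#'
#' @param dosages a `dosage_matrix` with at least two individuals.
#' @return object of class `kinship_matrix`: list with `kinship` (symmetric
#'   matrix with individual ids as dimnames), `individual_ids`, `method`.
#' @export
kinship_estimate <- function(dosages) {
  d <- dosages$dosages
  if (nrow(d) < 2) stop("kinship needs >= 2 individuals")
  z <- standardise_dosages(d)
  k <- tcrossprod(z) / (2 * ncol(z))
  k <- (k + t(k)) / 2  # enforce exact symmetry
  structure(list(kinship = k,
                 individual_ids = rownames(d),
                 method = "dosage_grm_half"),
            class = "kinship_matrix")
}

#' Find related pairs above a kinship threshold, blockwise
#'
#' Memory-safe variant of [kinship_estimate()] for large cohorts: the dense
#' kinship matrix is never materialised; only pairs with
#' `kinship > threshold` are returned.
#'
#' @param dosages a `dosage_matrix`.
#' @param threshold kinship threshold (default 0.05).
#' @param block block size (rows) for the pairwise sweep.
#' @return data.frame `id_a id_b kinship` (possibly empty).
#' @export
related_pairs <- function(dosages, threshold = 0.05, block = 2000L) {
  z <- standardise_dosages(dosages$dosages)
  n <- nrow(z)
  ids <- rownames(z)
  m2 <- 2 * ncol(z)
  out <- list()
  starts <- seq(1L, n, by = block)
  for (a in starts) {
    ae <- min(a + block - 1L, n)
    for (b in seq(a, n, by = block)) {
      be <- min(b + block - 1L, n)
      k <- tcrossprod(z[a:ae, , drop = FALSE],
                      z[b:be, , drop = FALSE]) / m2
      hit <- which(k > threshold, arr.ind = TRUE)
      if (nrow(hit)) {
        ia <- a + hit[, 1] - 1L
        ib <- b + hit[, 2] - 1L
        keep <- ia < ib
        if (any(keep)) {
          out[[length(out) + 1L]] <- data.frame(
            id_a = ids[ia[keep]], id_b = ids[ib[keep]],
            kinship = k[hit][keep], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(id_a = character(), id_b = character(), kinship = numeric())
  }
}

#' Greedy selection of an unrelated subset
#'
#' Iteratively removes the individual with the most pairwise kinships above
#' the threshold until no pair exceeds it. Ties are broken by lexicographic
#' id. Cases are protected: while any flagged control remains, only controls
#' are removed; a case is removed only when every remaining over-threshold
#' pair joins two cases.
#'
#' @param kinship a `kinship_matrix`, or a pair data.frame as returned by
#'   [related_pairs()] (already thresholded pairs are re-thresholded).
#' @param threshold kinship threshold (default 0.05).
#' @param all_ids ids of all individuals under consideration (required when
#'   `kinship` is a pair list; defaults to the kinship matrix ids).
#' @param case_ids ids of cases to protect (default none).
#' @return character vector of retained ids.
#' @export
filter_unrelated <- function(kinship, threshold = 0.05,
                             all_ids = NULL, case_ids = character()) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (inherits(kinship, "kinship_matrix")) {
    k <- kinship$kinship
    if (is.null(all_ids)) all_ids <- kinship$individual_ids
    ut <- upper.tri(k)
    hit <- which(k > threshold & ut, arr.ind = TRUE)
    pairs <- data.frame(id_a = rownames(k)[hit[, 1]],
                        id_b = colnames(k)[hit[, 2]],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(kinship)
    if (!is.null(pairs$kinship)) pairs <- pairs[pairs$kinship > threshold, ]
    if (is.null(all_ids)) stop("all_ids required with a pair list")
  }
  retained <- all_ids
  is_case <- all_ids %in% case_ids
  names(is_case) <- all_ids
  repeat {
    pairs <- pairs[pairs$id_a %in% retained & pairs$id_b %in% retained, ]
    if (!nrow(pairs)) break
    deg <- table(c(pairs$id_a, pairs$id_b))
    flagged <- names(deg)
    ctrl <- flagged[!is_case[flagged]]
    candidates <- if (length(ctrl)) ctrl else flagged
    dmax <- max(deg[candidates])
    drop <- sort(candidates[deg[candidates] == dmax])[1]
    retained <- setdiff(retained, drop)
  }
  retained
}
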