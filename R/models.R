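# Case/control association models and evaluation statistics.

new_model_fit <- function(coefficient, se, stat, p, aic, n_used, model_kind,
                          covariate_names, loglik = NA_real_,
                          null_loglik = NA_real_, null_aic = NA_real_,
                          fitted = NULL, status = NULL) {
  structure(list(coefficient = coefficient, se = se, stat = stat, p = p,
                 aic = aic, n_used = n_used, model_kind = model_kind,
                 covariate_names = covariate_names, loglik = loglik,
                 null_loglik = null_loglik, null_aic = null_aic,
                 fitted = fitted, status = status),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit %s> coef = %.4g (SE %.4g), p = %.3g, AIC = %.2f, n = %d\n",
              x$model_kind, x$coefficient, x$se, x$p, x$aic, x$n_used))
  invisible(x)
}

# merge scores and cohort table by id; errors on mismatch
merge_scores <- function(scores, tab, score_col = "z") {
  i <- match(tab$id, scores$id)
  if (anyNA(i)) stop("cohort table ids missing from scores")
  data.frame(prs = scores[[score_col]][i],
             status = tab$status, age = tab$age,
             sex = factor(tab$sex, levels = c("F", "M")),
             pc1 = tab$pc1, pc2 = tab$pc2)
}

#' Gaussian identity-link group comparison of z-scored PRS
#'
#' Fits `z ~ status + age + sex + pc1 + pc2` with Gaussian errors and an
#' identity link (ordinary least squares). The status coefficient is the
#' covariate-adjusted case-minus-control difference in mean z-PRS, with a
#' two-sided p from its t statistic.
#'
#' @param scores a z-scored `score_vector`.
#' @param tab the cohort table.
#' @param covariates logical; include age/sex/PC covariates (default TRUE).
#' @return a `model_fit` with `model_kind = "gaussian_identity"`.
#' @export
gaussian_group_model <- function(scores, tab, covariates = TRUE) {
  df <- merge_scores(scores, tab)
  if (length(unique(df$status)) < 2) {
    stop("status has no contrast (all cases or all controls)")
  }
  form <- if (covariates) prs ~ status + age + sex + pc1 + pc2 else prs ~ status
  fit <- stats::lm(form, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular design; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  new_model_fit(coefficient = sm["status", 1], se = sm["status", 2],
                stat = sm["status", 3], p = sm["status", 4],
                aic = stats::AIC(fit), n_used = nrow(df),
                model_kind = "gaussian_identity",
                covariate_names = setdiff(all.vars(form), c("prs", "status")),
                loglik = as.numeric(stats::logLik(fit)))
}

#' Logistic regression of disease status on z-scored PRS
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm`) of status
#' on the PRS with age, sex and the first two principal components as
#' covariates, fitted on a supplied unrelated subset. The matching null
#' model (covariates only) is fitted on the same rows; its log-likelihood
#' and AIC are carried in the returned fit for Nagelkerke R2.
#'
#' Non-convergence within `maxit` iterations or quasi-complete separation
#' (diverging coefficient / exploding SE) raises a condition of class
#' `prs_separation_error`, distinguishable from a converged fit.
#'
#' @param scores a z-scored `score_vector`.
#' @param tab the cohort table.
#' @param retained_ids optional ids (e.g. from [filter_unrelated()]) to
#'   restrict the fit to; default all.
#' @param covariates logical; include age/sex/PC covariates (default TRUE).
#' @param score_col which score column to use, `"z"` (default) or `"raw"`.
#' @param maxit IRLS iteration cap (default 100).
#' @return a `model_fit` with `model_kind = "logistic"`.
#' @export
logistic_fit <- function(scores, tab, retained_ids = NULL, covariates = TRUE,
                         score_col = "z", maxit = 100L) {
  if (!is.null(retained_ids)) tab <- tab[tab$id %in% retained_ids, ]
  df <- merge_scores(scores, tab, score_col = score_col)
  if (sum(df$status == 1) < 1 || sum(df$status == 0) < 1) {
    stop("need at least one case and one control")
  }
  form <- if (covariates) {
    status ~ prs + age + sex + pc1 + pc2
  } else {
    status ~ prs
  }
  null_form <- if (covariates) status ~ age + sex + pc1 + pc2 else status ~ 1
  fit <- suppressWarnings(
    stats::glm(form, data = df, family = stats::binomial(),
               control = stats::glm.control(maxit = maxit)))
  sm <- summary(fit)$coefficients
  if (!fit$converged || abs(sm["prs", 1]) > 15 || sm["prs", 2] > 100) {
    stop(structure(class = c("prs_separation_error", "error", "condition"),
                   list(message = paste0(
                     "logistic fit failed: ",
                     if (!fit$converged) "no convergence in "
                     else "apparent separation after ",
                     fit$iter, " IRLS iterations"),
                     call = sys.call(-1))))
  }
  null_fit <- suppressWarnings(
    stats::glm(null_form, data = df, family = stats::binomial(),
               control = stats::glm.control(maxit = maxit)))
  out <- new_model_fit(
    coefficient = sm["prs", 1], se = sm["prs", 2],
    stat = sm["prs", 3], p = sm["prs", 4],
    aic = stats::AIC(fit), n_used = nrow(df),
    model_kind = "logistic",
    covariate_names = setdiff(all.vars(form), c("status", "prs")),
    loglik = as.numeric(stats::logLik(fit)),
    null_loglik = as.numeric(stats::logLik(null_fit)),
    null_aic = stats::AIC(null_fit),
    fitted = stats::fitted(fit), status = df$status)
  out$null_coef <- stats::coef(null_fit)
  out
}

#' Nagelkerke pseudo-R-squared
#'
#' `R2_CS = 1 - exp((2/n) (l0 - l1))`, normalised by its maximum
#' `1 - exp((2/n) l0)` to give Nagelkerke's R2 in `[0, 1]`.
#'
#' @param fit fitted `model_fit` (logistic), or the full-model log-likelihood.
#' @param null_fit the nested null-model `model_fit`, or its log-likelihood.
#'   When `fit` is a logistic `model_fit` carrying its own null, `null_fit`
#'   may be omitted.
#' @param n number of observations (taken from `fit` if a `model_fit`).
#' @return Nagelkerke R2.
#' @export
nagelkerke_r2 <- function(fit, null_fit = NULL, n = NULL) {
  if (inherits(fit, "model_fit")) {
    l1 <- fit$loglik
    l0 <- if (is.null(null_fit)) fit$null_loglik
          else if (inherits(null_fit, "model_fit")) null_fit$loglik
          else null_fit
    if (is.null(n)) n <- fit$n_used
  } else {
    l1 <- fit
    l0 <- if (inherits(null_fit, "model_fit")) null_fit$loglik else null_fit
  }
  if (is.na(l0) || is.na(l1)) stop("log-likelihoods unavailable")
  if (l0 > l1 + 1e-8) {
    stop("null log-likelihood exceeds full (", l0, " > ", l1,
         "): models are not nested on the same data")
  }
  r2_cs <- 1 - exp((2 / n) * (l0 - l1))
  r2_max <- 1 - exp((2 / n) * l0)
  if (r2_max <= 0) return(0)
  r2_cs / r2_max
}

#' ROC AUC with Hanley-McNeil standard error
#'
#' AUC as the Mann-Whitney probability that a randomly chosen case outranks
#' a randomly chosen control (ties counted 1/2), computed from midranks; SE
#' by the Hanley-McNeil (1982) formula.
#'
#' @param pred numeric predicted risk (any monotone score).
#' @param status 0/1 disease status.
#' @return list with `auc` and `auc_se`.
#' @export
roc_auc <- function(pred, status) {
  status <- as.integer(status)
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 < 1 || n0 < 1) stop("need at least one case and one control")
  r <- rank(pred)  # midranks handle ties as 1/2
  auc <- (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  list(auc = auc, auc_se = se)
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools estimates with weights `1/SE^2`: `beta = sum(w b)/sum(w)`,
#' `SE = 1/sqrt(sum(w))`, p from the pooled z. Accepts a list of
#' `model_fit`s or parallel numeric vectors.
#'
#' @param fits list of `model_fit` objects, or a numeric vector of estimates.
#' @param se numeric vector of standard errors (when `fits` is numeric).
#' @return list with `beta`, `se`, `p`.
#' @export
fixed_effect_meta <- function(fits, se = NULL) {
  if (is.list(fits) && inherits(fits[[1]], "model_fit")) {
    b <- vapply(fits, `[[`, numeric(1), "coefficient")
    se <- vapply(fits, `[[`, numeric(1), "se")
  } else {
    b <- as.numeric(fits)
  }
  ok <- is.finite(b) & is.finite(se) & se > 0
  if (any(!ok)) {
    warning(sum(!ok), " estimate(s) with undefined SE excluded from meta-analysis")
    b <- b[ok]; se <- se[ok]
  }
  if (!length(b)) stop("no usable estimates for meta-analysis")
  w <- 1 / se^2
  beta <- sum(w * b) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  list(beta = beta, se = pooled_se,
       p = 2 * stats::pnorm(-abs(beta / pooled_se)))
}

#' Principal components of a dosage matrix
#'
#' Columns are centred at `2p` and scaled by `sqrt(2p(1-p))`; the top-`k`
#' principal components (per-individual scores) are returned, computed via
#' the eigendecomposition of the SNP-by-SNP cross-product (efficient for
#' n >> m). Each component's sign is fixed so that its largest-magnitude SNP
#' loading is positive.
#'
#' @param dosages a `dosage_matrix`, or a list of them (cohorts are row-bound
#'   and decomposed jointly, mirroring a combined-cohort PC plot).
#' @param k number of components (default 2).
#' @return list with `scores` (n x k matrix, rownames = ids), `loadings`
#'   (m x k), `sdev` (length k).
#' @export
genotype_pca <- function(dosages, k = 2) {
  d <- if (inherits(dosages, "dosage_matrix")) dosages$dosages
       else do.call(rbind, lapply(dosages, function(x) x$dosages))
  z <- standardise_dosages(d, context = "PCA")
  if (k > ncol(z)) stop("k exceeds number of polymorphic SNPs")
  zc <- sweep(z, 2, colMeans(z))  # centre individuals
  eg <- eigen(crossprod(zc), symmetric = TRUE)
  pos <- eg$values > max(eg$values, 1) * 1e-10
  if (sum(pos) < k) stop("k = ", k, " exceeds the rank of the dosage matrix")
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  scores <- zc %*% v
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = v,
       sdev = sqrt(eg$values[seq_len(k)] / (nrow(z) - 1)))
}
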