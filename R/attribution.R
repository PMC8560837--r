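# The attribution calculus: PRS mean differences -> expected log odds ratios
# -> equivalent excess cases per 100,000, compared with prevalence-derived
# observed odds.

#' Round half away from zero
#'
#' Reporting convention for equivalent-case integers: full-precision values
#' are rounded half away from zero only at reporting (R's `round()` rounds
#' half to even).
#'
#' @param x numeric.
#' @return rounded numeric.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Expected log odds ratio from a control PRS mean difference
#'
#' The control-mean z-PRS difference (target minus baseline) multiplied by
#' the meta-analysed log-odds-per-z-unit coefficient gives the expected log
#' odds ratio attributable to PRS frequency differences. The CI propagates
#' the beta uncertainty only (the mean difference is treated as fixed).
#'
#' @param delta_mean_z control-mean z-PRS difference, target - baseline.
#' @param beta_meta meta-analysed logistic coefficient (log-odds per z).
#' @param beta_se its standard error (optional; `NA` CI if missing).
#' @return list with `log_or` and `ci` (ordered length-2 vector).
#' @export
expected_log_or <- function(delta_mean_z, beta_meta, beta_se = NA_real_) {
  lo <- delta_mean_z * beta_meta
  ci <- sort(delta_mean_z * (beta_meta + c(-1.96, 1.96) * beta_se))
  list(log_or = lo, ci = ci)
}

prev_odds <- function(prev_per_1e5) prev_per_1e5 / (1e5 - prev_per_1e5)

#' Observed log odds ratio between two population prevalences
#'
#' Contingency-table odds per 100,000: `odds(P) = P / (100000 - P)`;
#' the observed log OR is `ln(odds(target) / odds(baseline))`.
#'
#' @param baseline,target prevalences in cases per 100,000 (numbers, or
#'   prevalence-record lists/rows with a `prevalence_per_1e5` field).
#' @return log odds ratio.
#' @export
observed_log_or <- function(baseline, target) {
  getp <- function(x) if (is.numeric(x)) x else x$prevalence_per_1e5
  p0 <- getp(baseline); p1 <- getp(target)
  if (any(c(p0, p1) <= 0 | c(p0, p1) >= 1e5)) {
    stop("prevalences must lie in (0, 100000) per 100,000")
  }
  log(prev_odds(p1) / prev_odds(p0))
}

#' Convert a log odds ratio into equivalent excess cases per 100,000
#'
#' The baseline prevalence is moved on the odds scale:
#' `odds1 = odds0 * exp(log_or)`, converted back to a prevalence
#' `P1 = 1e5 * odds1 / (1 + odds1)`; the excess is `P1 - P0` (full
#' precision; round only at reporting). Exact inverse of
#' [observed_log_or()].
#'
#' @param log_or log odds ratio (vectorised).
#' @param baseline_prev_per_1e5 baseline prevalence per 100,000.
#' @return signed excess cases per 100,000.
#' @export
log_or_to_excess_cases <- function(log_or, baseline_prev_per_1e5) {
  odds0 <- prev_odds(baseline_prev_per_1e5)
  odds1 <- odds0 * exp(log_or)
  1e5 * odds1 / (1 + odds1) - baseline_prev_per_1e5
}

#' Absolute excess cases in a population
#'
#' @param excess_per_1e5 excess cases per 100,000.
#' @param population_size population count.
#' @return expected absolute case count (unrounded; round at reporting).
#' @export
absolute_excess <- function(excess_per_1e5, population_size) {
  if (any(population_size <= 0)) stop("population_size must be > 0")
  excess_per_1e5 * population_size / 1e5
}

#' Build the expected-vs-observed excess risk report
#'
#' For each target population, produces one row per panel subset with the
#' expected log OR (control z-mean difference times the meta-analysed
#' logistic beta for that subset), plus one row for the observed
#' prevalence-derived log OR; each row carries the equivalent excess cases
#' per 100,000 against the baseline prevalence and the absolute count for
#' the target's population size.
#'
#' @param control_means named list: `control_means[[subset]][[population]]`
#'   is the control-mean z-PRS of that population for that subset.
#' @param meta_betas named list: `meta_betas[[subset]]` is a list with
#'   `beta` and `se` (as from [fixed_effect_meta()]).
#' @param prevalence data.frame with `population`, `prevalence_per_1e5`,
#'   `population_size` covering baseline and targets.
#' @param baseline name of the baseline population.
#' @param targets names of the target populations (default: all
#'   non-baseline populations in `prevalence`).
#' @return data.frame with columns `population subset kind log_or ci_low
#'   ci_high excess_per_1e5 excess_absolute` (4 rows per target when the
#'   three standard subsets are supplied).
#' @export
attribution_report <- function(control_means, meta_betas, prevalence,
                               baseline, targets = NULL) {
  if (!baseline %in% prevalence$population) {
    stop("baseline population '", baseline, "' missing from prevalence table")
  }
  if (is.null(targets)) {
    targets <- setdiff(prevalence$population, baseline)
  }
  subsets <- names(meta_betas)
  miss <- setdiff(subsets, names(control_means))
  if (length(miss)) stop("control means missing for subset(s): ",
                         paste(miss, collapse = ", "))
  p0 <- prevalence$prevalence_per_1e5[prevalence$population == baseline]
  rows <- list()
  for (tg in targets) {
    prow <- prevalence[prevalence$population == tg, ]
    if (!nrow(prow)) stop("target population '", tg, "' missing from prevalence table")
    for (ss in subsets) {
      cm <- control_means[[ss]]
      if (is.null(cm[[tg]]) || is.null(cm[[baseline]])) {
        stop("control means for subset '", ss, "' must cover '", tg,
             "' and '", baseline, "'")
      }
      ex <- expected_log_or(cm[[tg]] - cm[[baseline]],
                            meta_betas[[ss]]$beta, meta_betas[[ss]]$se)
      e1 <- log_or_to_excess_cases(ex$log_or, p0)
      rows[[length(rows) + 1L]] <- data.frame(
        population = tg, subset = ss, kind = "expected",
        log_or = ex$log_or, ci_low = ex$ci[1], ci_high = ex$ci[2],
        excess_per_1e5 = e1,
        excess_absolute = absolute_excess(e1, prow$population_size))
    }
    olo <- observed_log_or(p0, prow$prevalence_per_1e5)
    e1 <- log_or_to_excess_cases(olo, p0)
    rows[[length(rows) + 1L]] <- data.frame(
      population = tg, subset = "all", kind = "observed",
      log_or = olo, ci_low = NA_real_, ci_high = NA_real_,
      excess_per_1e5 = e1,
      excess_absolute = absolute_excess(e1, prow$population_size))
  }
  do.call(rbind, rows)
}
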