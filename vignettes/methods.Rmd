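---
title: "Attributing excess disease prevalence to common risk variants: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing excess disease prevalence to common risk variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsexcess)
```

# The question and the estimand

Two populations share a set of common disease risk variants but may carry
them at different frequencies. Given (i) a curated panel of risk SNPs with
per-allele odds ratios, (ii) genotype dosages for a case/control cohort
from each population, and (iii) observed disease prevalences, we ask how
much of the *observed* excess prevalence in a target population is
*expected* from the panel's frequency differences alone.

The estimand is a log odds ratio. On the observed side, a prevalence $P$
per 100,000 defines odds $P/(10^5 - P)$, and the observed excess risk of a
target population against a baseline is
$\log \mathrm{OR}_{obs} = \log \frac{odds(P_1)}{odds(P_0)}$.
On the expected side, the control-only difference in mean standardised PRS
between target and baseline, $\Delta\bar z$, multiplied by the
meta-analysed logistic coefficient $\beta$ (log-odds per z-unit of PRS),
gives $\log \mathrm{OR}_{exp} = \Delta\bar z \cdot \beta$. Either log OR
converts to "equivalent excess cases per 100,000" by moving the baseline
prevalence on the odds scale:
$odds_1 = odds_0 e^{\log OR}$, $P_1 = 10^5\, odds_1 / (1 + odds_1)$,
excess $= P_1 - P_0$. This conversion is the exact inverse of the
observed-odds computation (a tested round-trip identity), and it
reproduces every printed "equivalent number of cases" integer in the
source material from the printed log ORs and the 145/100,000 baseline —
which is why it was chosen; the source never writes the formula out.

# The models

**Scoring.** The raw PRS is the unnormalised weighted sum
$\mathrm{PRS}_i = \sum_j \ln(\mathrm{OR}_j)\, d_{ij}$ over the panel
subset, with $d_{ij} \in [0,2]$ counting the risk allele. A sum (not a
per-SNP average) keeps the additivity
$\mathrm{full} = \mathrm{no\_hla} + \mathrm{hla\_only}$ exact, and the
scale is irrelevant because scores are z-standardised afterwards.
Standardisation pools **all cohorts jointly**: per-cohort control means
may then differ from zero, which is exactly what makes between-population
mean comparisons meaningful (within-cohort z-scoring would force each
cohort's mean to zero and erase the signal). Whether the original analysis
standardised within or across cohorts is not stated in the source; the
pooled choice reproduces the reported nonzero per-cohort control means and
is switchable in principle (the scoring and standardisation steps are
separate functions).

**Panel QC.** Duplicated SNPs across source studies are pooled by
fixed-effect inverse-variance meta-analysis on the log-OR scale. Because
the input format carries only OR and p, each study's SE is recovered as
$|\log \mathrm{OR}| / \Phi^{-1}(1 - p/2)$; entries with $p = 1$ or
$\mathrm{OR} = 1$ have undefined SE and are dropped with a warning.
Alleles are harmonised to the dosage-counted allele; strand-ambiguous
(A/T, C/G) SNPs are excluded because their orientation cannot be verified
— the source is silent on strand handling, so this conservative standard
policy was adopted. LD clumping is greedy by ascending p-value: the best
remaining SNP is kept and any unkept SNP on the same chromosome within
±200 kb with squared dosage correlation **strictly above** 0.25 is
dropped ("cut-off 0.25" is read as the retained maximum; the comparison is
one switchable line). Ties in p are broken by larger $|\log OR|$, then
rsid. The r² is always computed from user-supplied dosages — the report
records which cohort supplied them — never from an external reference
panel.

**Association.** Two models per cohort and panel subset, both fitted with
`stats::glm`/`lm` as in the original analysis: a Gaussian identity-link
model `z ~ status + age + sex + PC1 + PC2` whose status coefficient is the
covariate-adjusted case−control mean difference, and a logistic model
`status ~ z + covariates` fitted on an unrelated subset. Wald p-values are
reported (matching the source's table style), Nagelkerke's
$R^2 = \frac{1 - e^{(2/n)(\ell_0 - \ell_1)}}{1 - e^{(2/n)\ell_0}}$
against the covariates-only null on the same rows, and AUC as the
Mann–Whitney probability with ties counted ½ and Hanley–McNeil SE (the
source's AUC SE method is unstated). Non-convergence and quasi-complete
separation raise a dedicated condition class rather than returning a
garbage fit.

**Relatedness.** Genomic kinship is the method-of-moments estimator
$\varphi_{ij} = \frac{1}{2m} \sum_k
\frac{(d_{ik} - 2p_k)(d_{jk} - 2p_k)}{2p_k(1-p_k)}$ (self ≈ 0.5, full
sibs ≈ 0.25). Filtering at threshold 0.05 is greedy: repeatedly remove the
individual with the most over-threshold pairs (ties by id), **removing
controls before cases** — a case falls only when every remaining related
pair joins two cases. The greedy rule and the case protection are design
choices (the source states only the threshold); protecting cases mirrors
the source's unrelated subsets, which retain cases preferentially.

One practical caveat governs the pipeline default: with only $m$ panel
SNPs the kinship estimator's sampling SD is roughly $1/(2\sqrt{m})$ —
about 0.044 for 127 SNPs — so thresholding at 0.05 on panel SNPs alone
flags vast numbers of unrelated pairs. Real studies estimate kinship from
genome-wide markers. The synthetic generator therefore produces an
optional separate matrix of effect-free "kinship markers"
(`n_kinship_markers`; a few thousand suffice, SD ≈ 0.007 at 5000), and the
pipeline skips the relatedness filter, with a logged note, when no marker
set is available. At large cohort sizes related pairs are found blockwise
(`related_pairs()`) so no dense $n \times n$ matrix is materialised.

**Meta-analysis and attribution.** The per-cohort logistic coefficients
are pooled by the same inverse-variance rule; the pooled $\beta$ per
subset multiplies the control-mean z difference. The attribution CI
propagates only the $\beta$ uncertainty ($\Delta\bar z$ treated as fixed):
the source's CI method is unstated and this choice approximates, but does
not exactly match, its printed intervals. Equivalent-case integers are
rounded half away from zero at reporting only.

# The synthetic world

The generator is a stated world, not a tuning dial. Dosages are sums of
two Bernoulli($raf$) alleles, optionally correlated within LD blocks
through a shared latent Gaussian factor (a one-parameter copula per
block). Disease status follows
$\mathrm{logit}(p_i) = c + \sum_j \log \mathrm{OR}_j\,(d_{ij} - 2\,
raf^{ref}_j) + \text{covariate terms}$.

Two points deserve emphasis:

* **Centring frequencies are a shared reference.** If each cohort centred
  dosages at its own frequencies, frequency differences could never
  produce prevalence differences. The model therefore centres every cohort
  at one reference vector (the mainland frequencies by default); each
  cohort's intercept is then calibrated by Monte Carlo + `uniroot` so the
  population prevalence hits its target.
* **Two scenarios.** `default_scenario()` calibrates every cohort to its
  *published* prevalence (145 / 402 / 295 per 100,000): as in the real
  populations, the variant-frequency differences then explain only a small
  part of the excess, and the rest is absorbed by the intercepts
  (environment, rare variants, anything not modelled).
  `frequency_driven_scenario()` shares the mainland intercept, so **all**
  excess prevalence is PRS-driven — this is the world in which the
  attribution calculus can be validated as a parameter-recovery exercise
  (the acceptance suite requires ≥ 80% of the designed excess to be
  recovered at 10× cohort sizes, and observes ≈ 87%).

Defaults follow the published cohort descriptions: sizes 30/8708, 97/2118,
15/2090 (cases/controls), HLA-like tag SNP with OR 2.77 at control
frequencies 0.17/0.23/0.21, 126 background SNPs with ORs uniform in
[1.05, 1.20] (the published effect-size range) at frequencies drawn once
from U(0.1, 0.9) and shared across populations, ages Normal with the
published cohort means/SDs, sex ratios as published, PC means separated by
population. Covariate effects default to zero — the source does not state
the effect sizes its models absorbed, so zero is a choice, not an
inference; it keeps PRS-only properties clean. Case/control counts are met
exactly by batched rejection sampling with an explicit failure at
1000× the requested count, guarding specs whose prevalence makes the case
count unreachable. Sib pairs transmit each parental allele independently
with probability ½ (expected kinship 0.25). One integer seed drives
everything; identical inputs give byte-identical outputs.

What the generator does **not** emulate: realistic LD maps or haplotype
structure, imputation uncertainty (dosages are hard calls unless jittered
by the user), population stratification *within* a cohort,
ascertainment-related covariate imbalance, and drift across more loci than
the designated tag SNP. A green test therefore establishes that the
*pipeline arithmetic and inference machinery* behave as specified under
the stated model — not that the original cohort-level estimates (which
depend on private genotypes) are reproduced. Published-scale quantities
that *are* reproduced exactly are the prevalence-derived observed log ORs
and every equivalent-case conversion.

# Numerical choices and degenerate inputs

* Meta-analysis excludes undefined-SE entries with a warning; all-excluded
  is an error.
* Zero-variance dosage columns are treated as r² = 0 in clumping (logged).
* Monomorphic SNPs are dropped from kinship sums and PCA (logged);
  frequencies strictly inside (0,1) are enforced at generation.
* `pooled_zscore` fails on zero pooled SD; `prs_score` fails hard on any
  missing subset SNP (no silent mean-imputation), mirroring the rule that
  panel SNPs must be present in all cohorts.
* Logistic separation is detected by non-convergence, |coef| > 15, or
  SE > 100, and raised as class `prs_separation_error`.
* The χ² frequency test needs integer counts but imputed dosages are
  fractional; allele counts are the rounded `2n·RAF` (documented; the
  source is silent). No continuity correction, df = 1.
* The pipeline config is JSON (`jsonlite`), since no YAML parser is part
  of the supported dependency set; flag overrides win over the file.
* Rounding of reported integers is half-away-from-zero, applied only at
  reporting.

A known arithmetic tension in the source is reproduced rather than forced:
its printed Orkney all-variant equivalent-case value (8) is not what its
own rounded printed log OR (0.05) converts to (7.42 → 7); the unprinted
full-precision log OR evidently rounds to 0.05 from above. The package
implements the stated procedure and leaves the discrepancy visible.

# Limitations

The attribution is odds-scale arithmetic on control means: it assumes the
logistic β is transportable between populations, ignores gene–environment
interaction, and treats the PRS mean difference as fixed when propagating
uncertainty. The kinship filter is greedy, not a maximum-independent-set
solver (the clique test shows it achieves the minimum on small graphs but
this is not guaranteed). With few cases (the smallest default cohort has
15) the logistic fits are fragile by nature; the separation guard makes
that explicit instead of hiding it.
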