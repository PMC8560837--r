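# prsexcess

Polygenic risk score (PRS) attribution of excess disease prevalence between
populations, with a synthetic-cohort generator for fully reproducible
testing.

## The scientific problem

Population isolates can carry common disease risk alleles at frequencies
that drifted away from their source population. When such an isolate also
shows an unusually high disease prevalence, a natural question is: **how
much of the excess burden do the known common risk variants explain?**
The motivating setting is multiple sclerosis (MS) in island populations:
an isolate with observed prevalence `P1` per 100,000 versus a mainland
baseline `P0`, three case/control cohorts with genotype dosages, and a
curated panel of ~127 GWAS risk SNPs dominated by one large-effect
HLA-class-II tag SNP (OR ≈ 2.77).

`prsexcess` implements the full analysis chain:

1. **Panel QC** — harmonise risk alleles to the dosage data (palindromic
   A/T, C/G SNPs excluded), pool duplicated SNPs by inverse-variance
   meta-analysis on the log-OR scale (SE recovered from the p-value via
   `|z| = Φ⁻¹(1 − p/2)`), filter at `p ≤ 10⁻³`, and LD-clump greedily by
   ascending p-value at `r² > 0.25` within a ±200-kb window.
2. **Scoring** — raw PRS as the weighted dosage sum
   `PRS_i = Σ_j ln(OR_j) · d_ij`, z-scored over the pooled cohorts, for
   three panel subsets: `full`, `no_hla`, `hla_only`.
3. **Association** — per cohort, a Gaussian identity-link group comparison
   (`z ~ status + age + sex + PC1 + PC2`) and a logistic regression on a
   kinship-filtered unrelated subset (genomic kinship > 0.05 removed,
   cases protected), with Nagelkerke pseudo-R², ROC AUC (Mann–Whitney,
   Hanley–McNeil SE) and AIC.
4. **Population comparison** — Welch t tests on control z-PRS means and
   per-SNP Pearson χ² tests on control risk-allele frequencies.
5. **Attribution** — the core calculus. Control-mean z-PRS difference ×
   meta-analysed logistic β gives the *expected* log OR attributable to
   common-variant frequency differences; prevalences give the *observed*
   log OR via `odds(P) = P/(100000 − P)`; any log OR converts into
   equivalent excess cases per 100,000 by
   `odds1 = odds0·e^{logOR}`, `P1 = 10⁵·odds1/(1+odds1)`, excess
   `= P1 − P0` — the exact inverse of the observed-odds computation.

Because the real cohort genotypes are not public, a first-class synthetic
module generates three cohorts (mainland 30/8708, one isolate 97/2118, one
isolate 15/2090 cases/controls) with the HLA-like tag SNP at control
frequencies 0.17 / 0.23 / 0.21, 126 background SNPs (ORs uniform in
[1.05, 1.20]) at shared frequencies, covariates, optional LD blocks,
sib-pair families and effect-free kinship markers.

## Worked example

```r
library(prsexcess)
res <- run_pipeline(list(seed = 1, scale = 1, out_dir = "run1"))
res$attribution
```

which prints (seed 1, default paper-shaped scenario):

```
 population   subset     kind log_or excess_per_1e5 excess_absolute
     orkney     full expected  0.112           17.2             3.8
     orkney   no_hla expected  0.004            0.6             0.1
     orkney hla_only expected  0.106           16.2             3.6
     orkney      all observed  1.022          257.0            56.5
   shetland     full expected  0.074           11.1             2.5
   shetland   no_hla expected  0.020            2.9             0.7
   shetland hla_only expected  0.053            7.9             1.8
   shetland      all observed  0.712          150.0            34.5
```

Reading the Orkney-like isolate rows: the common variants as a group are
*expected* to add ≈ 17 cases per 100,000 (≈ 4 absolute cases in a
population of 22,000), almost all of it from the HLA tag SNP alone
(`hla_only` ≈ 16 per 100,000), while the *observed* excess is 257 per
100,000 — i.e. common risk variants explain only a few percent of the
excess burden, which is the study-level conclusion this pipeline
reproduces in its synthetic world. The per-cohort model report is in
`res$models$report` (logistic β per z-PRS with SE, p, AIC, Nagelkerke R²,
AUC), e.g. for the same run:

```
            model estimate    se        p r2_nagelkerke   auc
   mainland: full    0.916 0.177 2.18e-07        0.0690 0.768
     orkney: full    1.093 0.107 2.15e-24        0.1721 0.790
 orkney: hla_only    0.617 0.084 2.06e-13        0.0779 0.698
```

The same run is available from the command line:

```sh
exec/prsexcess all --seed 1 --out run1 --scale 1
```

with verbs `simulate`, `build-panel`, `score`, `fit`, `compare`,
`attribute`, `all`, and an optional `--config config.json` (JSON mirror of
the `run_pipeline()` list).

## Layout

- `R/` — implementation (containers, io, panel, prs, kinship, models,
  compare, attribution, synthetic, pipeline).
- `tests/testthat/` — unit, property and acceptance tests; all fixtures
  are generated in code.
- `vignettes/methods.Rmd` — the model, its assumptions, parameter
  defaults, numerical choices and limitations.
- `scripts/acceptance.R` — the acceptance report above.
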