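# Shared fixtures, all built in code at test time.

# small panel builder: n SNPs with given ORs/p-values, far apart by default
tiny_panel <- function(or, p = rep(1e-6, length(or)),
                       chrom = as.character(seq_along(or)),
                       pos = rep(1e6L, length(or)),
                       rsid = sprintf("rs%03d", seq_along(or)),
                       hla_tag = NULL) {
  prs_panel(data.frame(rsid = rsid, chrom = chrom, pos = as.integer(pos),
                       risk_allele = "A", other_allele = "G",
                       or = or, p = p, source = "test",
                       stringsAsFactors = FALSE),
            hla_tag = hla_tag)
}

# dosage matrix whose columns match a panel
tiny_dosages <- function(mat, panel, cohort = "test") {
  dosage_matrix(mat, panel$snps[c("rsid", "chrom", "pos",
                                  "risk_allele", "other_allele")],
                cohort = cohort)
}

# minimal covariate table for n individuals
tiny_table <- function(status, ids = sprintf("id%03d", seq_along(status)),
                       age = NULL, sex = NULL, pc1 = NULL, pc2 = NULL) {
  n <- length(status)
  cohort_table(data.frame(
    id = ids, status = status,
    age = if (is.null(age)) seq(40, 60, length.out = n) else age,
    sex = if (is.null(sex)) rep(c("F", "M"), length.out = n) else sex,
    pc1 = if (is.null(pc1)) seq(-1, 1, length.out = n) else pc1,
    pc2 = if (is.null(pc2)) seq(1, -1, length.out = n) else pc2,
    stringsAsFactors = FALSE))
}

# independent greedy clumping oracle written with plain loops
clump_oracle <- function(snps, d, r2_max = 0.25, window = 2e5) {
  remaining <- seq_len(nrow(snps))
  kept <- integer(0)
  while (length(remaining)) {
    o <- remaining[order(snps$p[remaining],
                         -abs(log(snps$or[remaining])),
                         snps$rsid[remaining])]
    best <- o[1]
    kept <- c(kept, best)
    remaining <- setdiff(remaining, best)
    for (j in remaining) {
      if (snps$chrom[j] == snps$chrom[best] &&
          abs(snps$pos[j] - snps$pos[best]) <= window &&
          sd(d[, j]) > 0 && sd(d[, best]) > 0 &&
          cor(d[, j], d[, best])^2 > r2_max) {
        remaining <- setdiff(remaining, j)
      }
    }
  }
  sort(snps$rsid[kept])
}

# one half-size paper-shaped scenario shared across test files (built once)
.scenario_cache <- new.env(parent = emptyenv())
shared_scenario <- function() {
  if (is.null(.scenario_cache$sc)) {
    .scenario_cache$sc <- default_scenario(42, scale = 0.5)
  }
  .scenario_cache$sc
}
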