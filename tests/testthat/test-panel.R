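# SNP panel construction: meta-analysis of duplicates, allele harmonisation,
# LD clumping.

effect_row <- function(or, p, rsid = "rs1", risk = "A", other = "G",
                       source = "study1", chrom = "1", pos = 1000L) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos, risk_allele = risk,
             other_allele = other, or = or, p = p, source = source,
             stringsAsFactors = FALSE)
}

test_that("meta_dedupe: single entry, identical pair, and WLS oracle", {
  one <- effect_row(1.3, 1e-5)
  expect_identical(meta_dedupe(one), one)

  # two identical entries: beta unchanged, SE shrinks by sqrt(2), so the
  # pooled z is sqrt(2) times the single-study z
  two <- rbind(effect_row(1.2, 1e-4), effect_row(1.2, 1e-4, source = "study2"))
  pooled <- meta_dedupe(two)
  expect_equal(pooled$or, 1.2, tolerance = 1e-12)
  z1 <- qnorm(1 - 1e-4 / 2)
  expect_equal(pooled$p, 2 * pnorm(-sqrt(2) * z1), tolerance = 1e-12)

  # derived case: OR 1.2 (p 1e-4) + OR 1.4 (p 1e-6), oracle by numerical
  # weighted least squares (minimise sum w * (b - beta)^2)
  ef <- rbind(effect_row(1.2, 1e-4), effect_row(1.4, 1e-6, source = "study2"))
  pooled <- meta_dedupe(ef)
  b <- log(ef$or)
  se <- abs(b) / qnorm(1 - ef$p / 2)
  w <- 1 / se^2
  beta_oracle <- optimize(function(beta) sum(w * (b - beta)^2),
                          interval = range(b), tol = 1e-12)$minimum
  se_oracle <- 1 / sqrt(sum(w))
  expect_equal(log(pooled$or), beta_oracle, tolerance = 1e-8)
  expect_equal(pooled$p, 2 * pnorm(-abs(beta_oracle / se_oracle)),
               tolerance = 1e-8)
})

test_that("meta_dedupe is permutation-invariant and excludes undefined SEs", {
  ef <- rbind(effect_row(1.2, 1e-4), effect_row(1.4, 1e-6, source = "s2"),
              effect_row(0.9, 1e-3, source = "s3"))
  p1 <- meta_dedupe(ef)
  p2 <- meta_dedupe(ef[c(3, 1, 2), ])
  expect_equal(p1$or, p2$or, tolerance = 1e-12)
  expect_equal(p1$p, p2$p, tolerance = 1e-12)

  # p = 1 (z = 0) and OR = 1 (logOR = 0) both give undefined SE
  with_bad <- rbind(effect_row(1.2, 1e-4), effect_row(1.4, 1, source = "s2"))
  expect_warning(pooled <- meta_dedupe(with_bad), "undefined SE")
  expect_equal(pooled$or, 1.2)
  all_bad <- rbind(effect_row(1.0, 1e-4), effect_row(1.3, 1, source = "s2"))
  expect_warning(expect_error(meta_dedupe(all_bad), "undefined SE"))
})

test_that("harmonise_alleles: identity, dosage flip, palindromic exclusion", {
  ef <- effect_row(2.0, 1e-5, risk = "A", other = "G")
  same <- harmonise_alleles(ef, "A", "G")
  expect_equal(same$or, 2.0)
  expect_false(same$flip_dosage)

  # risk allele is the non-counted allele: risk OR kept, dosage flipped
  flip <- harmonise_alleles(ef, "G", "A")
  expect_equal(flip$or, 2.0)
  expect_true(flip$flip_dosage)

  expect_warning(
    out <- harmonise_alleles(effect_row(1.5, 1e-5, risk = "A", other = "T"),
                             "A", "T"),
    "palindromic")
  expect_null(out)
  expect_warning(
    out2 <- harmonise_alleles(ef, "C", "T"), "do not match")
  expect_null(out2)
})

test_that("ld_clump: trivial retention, duplicate removal, window respect", {
  # three SNPs on different chromosomes: everything retained
  pan <- tiny_panel(or = c(1.2, 1.3, 1.4), p = c(1e-8, 1e-5, 1e-4))
  set.seed(1)
  d <- tiny_dosages(matrix(rbinom(60, 2, 0.5), nrow = 20), pan)
  out <- ld_clump(pan, d)
  expect_equal(out$snps$rsid, pan$snps$rsid)

  # identical columns 50 kb apart: the better p survives
  pan2 <- tiny_panel(or = c(1.2, 1.3), p = c(1e-8, 1e-5),
                     chrom = c("2", "2"), pos = c(1e6, 1e6 + 5e4))
  x <- rbinom(30, 2, 0.4)
  d2 <- tiny_dosages(cbind(x, x), pan2)
  out2 <- ld_clump(pan2, d2)
  expect_equal(out2$snps$rsid, "rs001")
  rep2 <- attr(out2, "clump_report")
  expect_equal(rep2$dropped_rsid, "rs002")
  expect_equal(rep2$r2, 1, tolerance = 1e-12)

  # same correlation but outside the 200-kb window: both retained
  pan3 <- tiny_panel(or = c(1.2, 1.3), p = c(1e-8, 1e-5),
                     chrom = c("2", "2"), pos = c(1e6, 1e6 + 2.5e5))
  out3 <- ld_clump(pan3, tiny_dosages(cbind(x, x), pan3))
  expect_equal(nrow(out3$snps), 2)
})

test_that("ld_clump matches a brute-force oracle on 5-SNP instances and is idempotent", {
  for (seed in 1:8) {
    set.seed(seed)
    pan <- tiny_panel(or = runif(5, 1.05, 2), p = 10^-runif(5, 2, 8),
                      chrom = sample(c("1", "1", "1", "2", "2")),
                      pos = sample(seq(1e6, 1.3e6, by = 5e4), 5))
    base <- matrix(rbinom(40 * 5, 2, 0.5), nrow = 40)
    # induce correlation between random column pairs
    base[, 2] <- ifelse(runif(40) < 0.8, base[, 1], base[, 2])
    base[, 4] <- ifelse(runif(40) < 0.6, base[, 3], base[, 4])
    d <- tiny_dosages(base, pan)
    out <- ld_clump(pan, d)
    expect_equal(sort(out$snps$rsid),
                 clump_oracle(pan$snps, base), info = paste("seed", seed))
    # idempotence
    again <- ld_clump(out, d)
    expect_equal(again$snps$rsid, out$snps$rsid)
    # the globally most significant SNP always survives
    expect_true(pan$snps$rsid[which.min(pan$snps$p)] %in% out$snps$rsid)
    # survivors preserve input order
    expect_equal(out$snps$rsid,
                 pan$snps$rsid[pan$snps$rsid %in% out$snps$rsid])
  }
})

test_that("ld_clump errors on missing SNPs and tolerates zero variance", {
  pan <- tiny_panel(or = c(1.2, 1.3), p = c(1e-8, 1e-5))
  d_missing <- dosage_matrix(matrix(1, 5, 1),
                             pan$snps[1, c("rsid", "chrom", "pos",
                                           "risk_allele", "other_allele")],
                             "test")
  expect_error(ld_clump(pan, d_missing), "rs002")

  pan2 <- tiny_panel(or = c(1.2, 1.3), p = c(1e-8, 1e-5),
                     chrom = c("1", "1"), pos = c(1e6, 1.05e6))
  d0 <- tiny_dosages(cbind(rep(1, 10), rbinom(10, 2, 0.5)), pan2)
  expect_message(out <- ld_clump(pan2, d0), "zero-variance")
  expect_equal(nrow(out$snps), 2)
})

test_that("build_panel applies p-filter, harmonisation, dedupe and clumping", {
  effects <- rbind(
    effect_row(1.3, 1e-5, rsid = "rsA", chrom = "1", pos = 1e6),
    effect_row(1.4, 1e-6, rsid = "rsA", chrom = "1", pos = 1e6, source = "s2"),
    effect_row(1.2, 5e-3, rsid = "rsB", chrom = "2", pos = 1e6),   # p too big
    effect_row(1.5, 1e-7, rsid = "rsC", chrom = "3", pos = 1e6,
               risk = "A", other = "T"),                            # palindromic
    effect_row(1.1, 1e-4, rsid = "rsD", chrom = "4", pos = 1e6))
  si <- data.frame(rsid = c("rsA", "rsB", "rsC", "rsD"),
                   chrom = c("1", "2", "3", "4"), pos = rep(1e6L, 4),
                   risk_allele = "A", other_allele = c("G", "G", "T", "G"))
  set.seed(2)
  dm <- dosage_matrix(matrix(rbinom(30 * 4, 2, 0.5), 30), si, "test")
  expect_warning(pan <- build_panel(effects, dosages = dm), "palindromic")
  expect_equal(pan$snps$rsid, c("rsA", "rsD"))
  # rsA pooled from two sources
  expect_match(pan$snps$source[1], "s2")
})
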