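# Synthetic cohort generator: distributional checks against simple sampling
# oracles, determinism, calibration properties.

test_that("null-effect model reduces to Bernoulli(prevalence)", {
  pan <- tiny_panel(or = rep(1, 3))  # OR 1 -> log_or 0
  spec <- population_spec("null", n_cases = 1, n_controls = 1,
                          raf = rep(0.5, 3), prevalence_per_1e5 = 145)
  mdl <- effect_model(pan, intercept = qlogis(0.00145), ref_raf = rep(0.5, 3))
  set.seed(101)
  pop <- simulate_population(spec, mdl, 2e5)
  se <- sqrt(0.00145 * (1 - 0.00145) / 2e5)
  expect_lt(abs(mean(pop$status) - 0.00145), 3 * se)
})

test_that("control RAF estimates recover the generating frequencies", {
  pan <- tiny_panel(or = 1.0)
  for (raf in c(0.23, 0.17)) {
    spec <- population_spec(paste0("p", raf), n_cases = 0, n_controls = 10000,
                            raf = raf, prevalence_per_1e5 = 145)
    mdl <- effect_model(pan, intercept = qlogis(0.00145), ref_raf = raf)
    co <- generate_cohort(spec, mdl, seed = 7)
    est <- control_raf(co$dosages, co$table, "rs001")
    se <- sqrt(raf * (1 - raf) / (2 * 10000))
    expect_lt(abs(est - raf), 3 * se)
  }
})

test_that("sib pairs have empirical kinship 0.25 and unrelateds ~0", {
  pan <- tiny_panel(or = 1.0)
  set.seed(5)
  spec <- population_spec("fam", n_cases = 0, n_controls = 60,
                          raf = 0.5, prevalence_per_1e5 = 145,
                          n_families = 2,
                          marker_raf = runif(10000, 0.1, 0.9))
  mdl <- effect_model(pan, intercept = qlogis(0.00145), ref_raf = 0.5)
  co <- generate_cohort(spec, mdl, seed = 11)
  k <- kinship_estimate(co$markers)
  fam <- co$table$family
  sib_idx <- which(!is.na(fam))
  # two families, members adjacent in the table
  for (f in unique(fam[sib_idx])) {
    pair <- which(fam == f & !is.na(fam))
    expect_lt(abs(k$kinship[pair[1], pair[2]] - 0.25), 0.02)
  }
  # unrelated pair and self-kinship
  un <- which(is.na(fam))[1:2]
  expect_lt(abs(k$kinship[un[1], un[2]]), 0.02)
  expect_lt(abs(k$kinship[un[1], un[1]] - 0.5), 0.05)
  expect_identical(k$kinship, t(k$kinship))
})

test_that("generation is deterministic and fails cleanly at the cap", {
  s1 <- default_scenario(3, scale = 0.02)
  s2 <- default_scenario(3, scale = 0.02)
  expect_identical(s1$cohorts$orkney$dosages$dosages,
                   s2$cohorts$orkney$dosages$dosages)
  expect_identical(s1$cohorts$mainland$table, s2$cohorts$mainland$table)
  expect_identical(s1$panel$snps, s2$panel$snps)

  pan <- tiny_panel(or = 1.0)
  hopeless <- population_spec("rare", n_cases = 50, n_controls = 10,
                              raf = 0.5, prevalence_per_1e5 = 1)
  mdl <- effect_model(pan, intercept = qlogis(1e-5), ref_raf = 0.5)
  expect_error(generate_cohort(hopeless, mdl, seed = 1),
               "iteration cap")
})

test_that("default scenario shapes: sizes, HLA frequency gap, flat background", {
  sc <- shared_scenario()  # scale 0.5
  sizes <- vapply(sc$cohorts, function(co) nrow(co$dosages$dosages), numeric(1))
  expect_equal(unname(sizes[c("mainland", "orkney", "shetland")]),
               round(0.5 * c(30, 97, 15)) + round(0.5 * c(8708, 2118, 2090)))
  expect_equal(nrow(sc$panel$snps), 127)
  expect_equal(lengths(sc$panel$subsets)[c("full", "no_hla", "hla_only")],
               c(full = 127, no_hla = 126, hla_only = 1))

  co <- sc$cohorts
  gap <- control_raf(co$orkney$dosages, co$orkney$table, "rs9271069") -
    control_raf(co$mainland$dosages, co$mainland$table, "rs9271069")
  se <- sqrt(0.23 * 0.77 / (2 * 1059) + 0.17 * 0.83 / (2 * 4354))
  expect_lt(abs(gap - 0.06), 3 * se)

  # background SNPs share frequencies across populations: chi2 p-values flat
  bg <- setdiff(sc$panel$snps$rsid, "rs9271069")
  ps <- vapply(bg, function(rs) {
    raf_chi2(co$orkney$dosages, co$orkney$table,
             co$mainland$dosages, co$mainland$table, rs)$p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("dosages are hard calls in {0,1,2} and frequencies strictly inside (0,1)", {
  sc <- shared_scenario()
  d <- sc$cohorts$shetland$dosages$dosages
  expect_true(all(d %in% c(0, 1, 2)))
  expect_error(population_spec("bad", 1, 1, raf = c(0.5, 0),
                               prevalence_per_1e5 = 145),
               "strictly in")
})

test_that("LD blocks induce the requested dosage correlation", {
  pan <- tiny_panel(or = rep(1, 4))
  spec <- population_spec("ld", n_cases = 0, n_controls = 4000,
                          raf = rep(0.4, 4), prevalence_per_1e5 = 145)
  mdl <- effect_model(pan, intercept = qlogis(0.00145), ref_raf = rep(0.4, 4),
                      ld_blocks = list(list(idx = 1:2, rho = 0.9)))
  co <- generate_cohort(spec, mdl, seed = 21)
  d <- co$dosages$dosages
  expect_gt(cor(d[, 1], d[, 2])^2, 0.4)   # strongly correlated within block
  expect_lt(cor(d[, 3], d[, 4])^2, 0.01)  # independent across blocks
  expect_error(effect_model(pan, 0, rep(0.4, 4),
                            ld_blocks = list(list(idx = 1:2, rho = 1))),
               "rho")
})

test_that("type-I calibration: null-effect PRS coefficient CI covers 0", {
  set.seed(303)
  pan <- tiny_panel(or = runif(10, 1.05, 1.2))
  spec <- population_spec("null", n_cases = 50, n_controls = 350,
                          raf = runif(10, 0.2, 0.8),
                          prevalence_per_1e5 = 12500)
  mdl <- effect_model(pan, intercept = qlogis(0.125), ref_raf = spec$raf,
                      log_or = rep(0, 10))  # no true effect
  cover <- logical(100)
  for (r in 1:100) {
    co <- generate_cohort(spec, mdl, seed = 5000 + r)
    s <- pooled_zscore(prs_score(co$dosages, pan))
    f <- logistic_fit(s, co$table)
    cover[r] <- abs(f$coefficient) <= 1.96 * f$se
  }
  expect_gte(mean(cover), 0.93)
})
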