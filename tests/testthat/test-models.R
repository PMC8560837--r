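# Association models and evaluation statistics.

test_that("gaussian_group_model matches the normal-equations oracle on 8 rows", {
  z <- c(0.3, -0.2, 1.1, 0.8, -0.5, 0.0, 0.9, -1.2)
  tab <- tiny_table(c(1, 0, 1, 1, 0, 0, 1, 0),
                    age = c(50, 60, 45, 52, 58, 61, 47, 55),
                    sex = c("F", "M", "F", "M", "F", "M", "F", "M"),
                    pc1 = c(0.1, -0.2, 0.3, 0.0, 0.2, -0.1, 0.4, -0.3),
                    pc2 = c(-0.1, 0.2, 0.1, -0.2, 0.0, 0.3, -0.3, 0.1))
  scores <- data.frame(id = tab$id, cohort = "t", subset = "full",
                       raw = z, z = z)
  fit <- gaussian_group_model(scores, tab)

  X <- cbind(1, tab$status, tab$age, tab$sex == "M", tab$pc1, tab$pc2)
  beta <- solve(t(X) %*% X, t(X) %*% z)
  resid <- z - X %*% beta
  sigma2 <- sum(resid^2) / (8 - 6)
  se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
  expect_equal(fit$coefficient, beta[2], tolerance = 1e-10)
  expect_equal(fit$se, se[2], tolerance = 1e-10)
  expect_equal(fit$p, 2 * pt(-abs(beta[2] / se[2]), df = 2), tolerance = 1e-10)
})

test_that("gaussian_group_model error paths and large-n consistency", {
  z <- rnorm(10)
  tab <- tiny_table(rep(1, 10))
  scores <- data.frame(id = tab$id, cohort = "t", subset = "full",
                       raw = z, z = z)
  expect_error(gaussian_group_model(scores, tab), "no contrast")

  set.seed(17)
  n <- 20000
  status <- rbinom(n, 1, 0.3)
  zz <- 0.8 * status + rnorm(n)
  tab2 <- tiny_table(status, ids = sprintf("i%05d", 1:n),
                     age = rnorm(n, 50, 10),
                     sex = sample(c("F", "M"), n, TRUE),
                     pc1 = rnorm(n), pc2 = rnorm(n))
  sc2 <- data.frame(id = tab2$id, cohort = "t", subset = "full",
                    raw = zz, z = zz)
  fit <- gaussian_group_model(sc2, tab2)
  expect_lt(abs(fit$coefficient - 0.8), 3 * fit$se)
})

test_that("logistic_fit: intercept-only closed form and Newton oracle", {
  set.seed(23)
  n <- 200
  status <- rbinom(n, 1, 0.3)
  z <- rnorm(n)
  tab <- tiny_table(status, ids = sprintf("i%04d", 1:n))
  scores <- data.frame(id = tab$id, cohort = "t", subset = "full",
                       raw = z, z = z)
  fit <- logistic_fit(scores, tab, covariates = FALSE)
  # the null model (covariates = FALSE) is intercept-only: ln(q/(1-q))
  expect_equal(unname(fit$null_coef["(Intercept)"]),
               qlogis(mean(status)), tolerance = 1e-8)

  # 6-row hand data against an independent Newton-Raphson oracle
  z6 <- c(-1.2, -0.4, 0.1, 0.6, 1.3, 2.0)
  s6 <- c(0, 0, 1, 0, 1, 1)
  tab6 <- tiny_table(s6)
  sc6 <- data.frame(id = tab6$id, cohort = "t", subset = "full",
                    raw = z6, z = z6)
  fit6 <- logistic_fit(sc6, tab6, covariates = FALSE)
  X <- cbind(1, z6)
  b <- c(0, 0)
  for (it in 1:50) {
    p <- 1 / (1 + exp(-X %*% b))
    W <- as.numeric(p * (1 - p))
    b <- b + solve(t(X) %*% (X * W), t(X) %*% (s6 - p))
  }
  expect_equal(fit6$coefficient, b[2], tolerance = 1e-8)
  p <- 1 / (1 + exp(-X %*% b))  # probabilities at convergence
  info <- solve(t(X) %*% (X * as.numeric(p * (1 - p))))
  # SE is information-based; glm stops on a deviance criterion so its
  # observed information differs from the fully converged Newton value in
  # the 5th decimal on this tiny flat likelihood
  expect_equal(fit6$se, sqrt(info[2, 2]), tolerance = 1e-4)
  ll <- sum(s6 * log(p) + (1 - s6) * log(1 - p))
  expect_equal(fit6$aic, 2 * 2 - 2 * ll, tolerance = 1e-6)
})

test_that("logistic_fit flags separation distinctly", {
  z <- c(-3, -2, -1, 1, 2, 3, -2.5, 2.5)
  s <- as.integer(z > 0)
  tab <- tiny_table(s)
  sc <- data.frame(id = tab$id, cohort = "t", subset = "full", raw = z, z = z)
  err <- tryCatch(logistic_fit(sc, tab, covariates = FALSE),
                  error = function(e) e)
  expect_s3_class(err, "prs_separation_error")
})

test_that("nagelkerke_r2: endpoints, direct-likelihood oracle, nesting guard", {
  expect_equal(nagelkerke_r2(-10, -10, n = 50), 0)
  expect_equal(nagelkerke_r2(0, -30, n = 50), 1)

  set.seed(31)
  n <- 80
  z <- rnorm(n)
  status <- rbinom(n, 1, plogis(-1 + z))
  tab <- tiny_table(status, ids = sprintf("i%03d", 1:n))
  sc <- data.frame(id = tab$id, cohort = "t", subset = "full", raw = z, z = z)
  fit <- logistic_fit(sc, tab, covariates = FALSE)
  # oracle: likelihoods evaluated directly from refit probabilities
  g1 <- glm(status ~ z, family = binomial())
  g0 <- glm(status ~ 1, family = binomial())
  l1 <- sum(dbinom(status, 1, fitted(g1), log = TRUE))
  l0 <- sum(dbinom(status, 1, fitted(g0), log = TRUE))
  r2_oracle <- (1 - exp((2 / n) * (l0 - l1))) / (1 - exp((2 / n) * l0))
  expect_equal(nagelkerke_r2(fit), r2_oracle, tolerance = 1e-10)
  expect_error(nagelkerke_r2(l0 - 1, l0, n = n), "not nested")

  # nesting always holds on fitted models
  for (seed in 1:10) {
    set.seed(seed)
    st <- rbinom(60, 1, 0.4)
    zz <- rnorm(60)
    tt <- tiny_table(st, ids = sprintf("x%03d", 1:60))
    ss <- data.frame(id = tt$id, cohort = "t", subset = "full",
                     raw = zz, z = zz)
    f <- logistic_fit(ss, tt)
    expect_gte(f$loglik, f$null_loglik - 1e-10)
  }
})

test_that("roc_auc: perfect separation, exhaustive pair-count oracle, null", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)

  # 4 cases / 6 controls with a tie: brute force over all 24 pairs
  pred <- c(0.9, 0.8, 0.7, 0.4, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1)
  status <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  wins <- 0
  for (i in which(status == 1)) {
    for (j in which(status == 0)) {
      wins <- wins + (pred[i] > pred[j]) + 0.5 * (pred[i] == pred[j])
    }
  }
  out <- roc_auc(pred, status)
  expect_identical(out$auc, wins / 24)
  expect_gt(out$auc_se, 0)

  set.seed(41)
  st <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(rnorm(2000), st)$auc - 0.5), 0.05)
  expect_error(roc_auc(rnorm(5), rep(1, 5)), "at least one")
})

test_that("fixed_effect_meta: identity, equal weights, closed-form oracle", {
  one <- fixed_effect_meta(0.6, se = 0.11)
  expect_equal(one$beta, 0.6)
  expect_equal(one$se, 0.11)

  eq <- fixed_effect_meta(c(0.2, 0.4, 0.9), se = rep(0.3, 3))
  expect_equal(eq$beta, 0.5, tolerance = 1e-12)

  # published-style full-SNP-set estimates from the three cohorts
  b <- c(0.59, 0.60, 0.63); s <- c(0.26, 0.11, 0.19)
  pooled <- fixed_effect_meta(b, se = s)
  w <- 1 / s^2
  beta_oracle <- optimize(function(x) sum(w * (b - x)^2),
                          interval = c(0, 1), tol = 1e-12)$minimum
  expect_equal(pooled$beta, beta_oracle, tolerance = 1e-8)
  expect_equal(pooled$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("gaussian and logistic PRS effects agree in sign under a true effect", {
  set.seed(53)
  pan <- tiny_panel(or = runif(8, 1.3, 2))
  spec <- population_spec("eff", n_cases = 60, n_controls = 300,
                          raf = runif(8, 0.3, 0.7),
                          prevalence_per_1e5 = 10000)
  mdl <- effect_model(pan, intercept = qlogis(0.1), ref_raf = spec$raf)
  agree <- logical(30)
  for (r in 1:30) {
    co <- generate_cohort(spec, mdl, seed = 900 + r)
    s <- pooled_zscore(prs_score(co$dosages, pan))
    lf <- logistic_fit(s, co$table)
    gf <- gaussian_group_model(s, co$table)
    agree[r] <- sign(lf$coefficient) == sign(gf$coefficient)
  }
  expect_gte(mean(agree), 29 / 30)
})

test_that("genotype_pca separates populations and returns orthonormal loadings", {
  set.seed(61)
  m <- 60
  raf_a <- runif(m, 0.2, 0.8)
  raf_b <- plogis(qlogis(raf_a) + rnorm(m, 0, 0.8))  # drifted frequencies
  pan <- tiny_panel(or = rep(1.1, m), rsid = sprintf("s%03d", 1:m),
                    chrom = rep("1", m), pos = seq_len(m) * 1e6)
  da <- tiny_dosages(sapply(raf_a, function(p) rbinom(300, 2, p)), pan, "a")
  db <- tiny_dosages(sapply(raf_b, function(p) rbinom(300, 2, p)), pan, "b")
  pca <- genotype_pca(list(da, db), k = 2)
  pop <- rep(c(0, 1), each = 300)
  a <- roc_auc(pca$scores[, 1], pop)$auc
  expect_gt(max(a, 1 - a), 0.9)  # separation regardless of sign convention
  expect_equal(crossprod(pca$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)

  # identical individuals: zero variance after centring, rank failure
  ident <- tiny_dosages(matrix(1, 10, m), pan)
  expect_error(genotype_pca(ident), "rank")
  expect_error(genotype_pca(da, k = 400), "exceeds")
})
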