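test_that("fixed effects pooling matches hand-worked cases", {
  # single study: identity, normal-tail p
  fe <- fixed_effects(5, 2)
  expect_equal(fe$beta, 5)
  expect_equal(fe$se, 2)
  expect_equal(fe$z, 2.5)
  expect_equal(fe$p, 2 * pnorm(-2.5))
  # symmetric equal-se studies: mean and se/sqrt(k)
  fe <- fixed_effects(c(1, 3, 5), c(2, 2, 2))
  expect_equal(fe$beta, 3)
  expect_equal(fe$se, 2 / sqrt(3))
  # hand-computed weighted mean: betas (1,2,4), ses (1,0.5,2)
  w <- c(1, 4, 0.25)
  fe <- fixed_effects(c(1, 2, 4), c(1, 0.5, 2))
  expect_equal(fe$beta, sum(w * c(1, 2, 4)) / sum(w), tolerance = 1e-12)
  expect_equal(fe$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_error(fixed_effects(numeric(0), numeric(0)), "no study")
  expect_error(fixed_effects(1, 0), "positive")
})

test_that("Cochran Q matches hand-worked cases and conventions", {
  expect_equal(cochran_q(c(2, 2, 2), c(1, 2, 3))$Q, 0)
  expect_equal(cochran_q(c(2, 2, 2), c(1, 2, 3))$p, 1)
  q <- cochran_q(c(0, 0, 3), c(1, 1, 1))
  expect_equal(q$Q, 6, tolerance = 1e-12)
  expect_equal(q$df, 2L)
  expect_equal(q$p, exp(-3), tolerance = 1e-12)
  one <- cochran_q(4, 1.5)
  expect_equal(one$Q, 0)
  expect_equal(one$df, 0L)
  expect_true(is.na(one$p))
})

test_that("DerSimonian-Laird matches the hand-worked case and truncates", {
  dl <- dersimonian_laird(c(0, 0, 3), c(1, 1, 1))
  expect_equal(dl$tau2, 2, tolerance = 1e-12)
  expect_equal(dl$beta, 1, tolerance = 1e-12)
  expect_equal(dl$se, 1, tolerance = 1e-12)
  # Q <= k - 1 -> tau2 = 0 and random == fixed
  dl0 <- dersimonian_laird(c(1, 1.1, 0.9), c(1, 1, 1))
  fe0 <- fixed_effects(c(1, 1.1, 0.9), c(1, 1, 1))
  expect_equal(dl0$tau2, 0)
  expect_equal(dl0$beta, fe0$beta)
  expect_equal(dl0$se, fe0$se)
  # single study: degenerate random == input study
  dl1 <- dersimonian_laird(5, 2)
  expect_equal(dl1$tau2, 0)
  expect_equal(dl1$beta, 5)
  expect_equal(dl1$se, 2)
})

test_that("H and I2 follow the Q-based definitions", {
  hi <- h_and_i2(6, 2)
  expect_equal(hi$H, sqrt(3))
  expect_equal(hi$I2, 2 / 3)
  expect_equal(h_and_i2(2, 2)$H, 1)
  expect_equal(h_and_i2(2, 2)$I2, 0)
  expect_equal(h_and_i2(0, 3)$I2, 0)
})

test_that("meta statistics match an independent formula oracle", {
  set.seed(14)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    beta <- rnorm(k, 0, 5)
    se <- runif(k, 0.2, 3)
    fe <- fixed_effects(beta, se)
    qq <- cochran_q(beta, se)
    re <- dersimonian_laird(beta, se)
    hi <- h_and_i2(qq$Q, qq$df)
    orc <- oracle_meta(beta, se)
    expect_equal(fe$beta, orc$beta_fixed, tolerance = 1e-12)
    expect_equal(fe$se, orc$se_fixed, tolerance = 1e-12)
    expect_equal(qq$Q, orc$Q, tolerance = 1e-12)
    expect_equal(re$tau2, orc$tau2, tolerance = 1e-12)
    expect_equal(re$beta, orc$beta_random, tolerance = 1e-12)
    expect_equal(re$se, orc$se_random, tolerance = 1e-12)
    expect_equal(hi$H, orc$H, tolerance = 1e-12)
    expect_equal(hi$I2, orc$I2, tolerance = 1e-12)
    # random-effects CI contains the fixed-effects CI
    expect_gte(re$se, fe$se)
    # pooled fixed estimate lies within the study estimates
    expect_gte(fe$beta, min(beta) - 1e-12)
    expect_lte(fe$beta, max(beta) + 1e-12)
  }
})

test_that("meta statistics agree with the metafor reference implementation", {
  library(metafor)
  set.seed(8)
  for (i in 1:40) {
    k <- sample(2:4, 1)
    beta <- rnorm(k, 1, 4)
    se <- runif(k, 0.3, 2)
    ref <- rma(yi = beta, sei = se, method = "DL")
    re <- dersimonian_laird(beta, se)
    qq <- cochran_q(beta, se)
    expect_equal(re$beta, as.numeric(ref$b), tolerance = 1e-8)
    expect_equal(re$se, ref$se, tolerance = 1e-8)
    expect_equal(re$tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(qq$Q, ref$QE, tolerance = 1e-8)
    expect_equal(qq$p, ref$QEp, tolerance = 1e-8)
  }
})

test_that("BH adjustment is a step-up with NA passthrough", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))  # all-equal fixed point
  expect_equal(bh_fdr(0.37), 0.37)
  p <- c(0.01, NA, 0.04, 0.03)
  adj <- bh_fdr(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[1], 0.03)  # m = 3, not 4
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("missingness filter applies the strict 25% rule and drops unnamed", {
  make_co <- function(name, n, mets, na_cols = character(0)) {
    X <- matrix(rnorm(n * length(mets), 12, 1), n, length(mets),
                dimnames = list(sprintf("%s%03d", name, 1:n), mets))
    for (m in na_cols) X[, m] <- NA_real_
    ph <- data.frame(subject_id = rownames(X),
                     pct_change_homa_ir = rnorm(n, -16, 40),
                     weight_baseline = 95, pct_change_weight = -8, age = 55,
                     sex = "F", race = "AA", triglycerides = 120)
    cohort_dataset(name, ph, X, scale = "log")
  }
  mets <- c("m1", "m2", "m3", "unk1")
  set.seed(2)
  # pooled samples: 443 + 163 + 125 = 731; m2 missing in the whole
  # 125-sample cohort only -> 125/731 = 17.1% missing -> kept
  cohorts <- list(make_co("a", 443, mets), make_co("b", 163, mets),
                  make_co("c", 125, mets, na_cols = "m2"))
  ann <- data.frame(metabolite = mets,
                    known = c(TRUE, TRUE, TRUE, FALSE))
  res <- missingness_filter(cohorts, ann)
  expect_equal(unname(res$missingness["m2"]), 125 / 731, tolerance = 1e-12)
  expect_true("m2" %in% res$retained)
  expect_false("unk1" %in% res$retained)  # unnamed removed regardless
  # missingness exactly 0.25 is removed (strict <)
  co4 <- make_co("d", 4, mets)
  co4$abundance[1, "m3"] <- NA
  res2 <- missingness_filter(list(co4), ann)
  expect_equal(unname(res2$missingness["m3"]), 0.25)
  expect_false("m3" %in% res2$retained)
  expect_true("m1" %in% res2$retained)
})

test_that("run_meta assembles the schema, directions and FDR columns", {
  r <- function(cohort, mets, beta, se, n) {
    data.frame(metabolite = mets, cohort = cohort,
               model_form = "univariate", beta = beta, se = se, n = n,
               p = 2 * pnorm(-abs(beta / se)))
  }
  tabs <- list(
    r("a", c("m1", "m2", "m3"), c(-2, 1, 0.5), c(0.5, 1, 1), 100),
    r("b", c("m1", "m2"), c(-1, -0.5), c(0.4, 0.8), 60),
    r("c", "m1", -3, 1.1, 40))
  meta <- run_meta(tabs)
  expect_setequal(meta$Metabolite, c("m1", "m2", "m3"))
  m1 <- meta[meta$Metabolite == "m1", ]
  expect_equal(m1$N_Studies, 3)
  expect_equal(m1$N_Samples, 200)
  expect_equal(m1$Direction, "---")
  orc <- oracle_meta(c(-2, -1, -3), c(0.5, 0.4, 1.1))
  expect_equal(m1$Beta_Random, orc$beta_random, tolerance = 1e-12)
  expect_equal(m1$Q, orc$Q, tolerance = 1e-12)
  # metabolite in 2 of 3 cohorts: direction carries "?"
  m2 <- meta[meta$Metabolite == "m2", ]
  expect_equal(m2$N_Studies, 2)
  expect_equal(m2$Direction, "+-?")
  # single-cohort metabolite equals its study estimate with tau2 = 0
  m3 <- meta[meta$Metabolite == "m3", ]
  expect_equal(m3$Beta_Random, 0.5)
  expect_equal(m3$SE_Random, 1)
  expect_equal(m3$Tau2, 0)
  expect_true(is.na(m3$Q_Pvalue))
  expect_true(all(meta$Pvalue_Adj_Random >= meta$Pvalue_Random))
  # permuting study order leaves every field unchanged
  meta2 <- run_meta(tabs[c(3, 1, 2)])
  cols <- c("Metabolite", "N_Samples", "N_Studies", "Beta_Fixed",
            "Beta_Random", "SE_Random", "Q", "Tau2", "Pvalue_Adj_Random")
  expect_equal(meta[order(meta$Metabolite), cols],
               meta2[order(meta2$Metabolite), cols], ignore_attr = TRUE)
})

test_that("random-effects p-values are near-uniform under the global null", {
  set.seed(31)
  k <- 3
  p <- replicate(400, {
    se <- runif(k, 0.5, 1.5)
    beta <- rnorm(k, 0, se)
    dersimonian_laird(beta, se)$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})
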