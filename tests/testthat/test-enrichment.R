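mini_meta <- function(z, ids = sprintf("m%d", seq_along(z)), n_studies = 3) {
  data.frame(Metabolite = ids, Zvalue_Random = z, Q = abs(z),
             N_Studies = n_studies)
}

test_that("ranking sorts by statistic with deterministic tie-break", {
  tab <- mini_meta(c(3, -1, 2), ids = c("m1", "m2", "m3"))
  rk <- rank_metabolites(tab, "signed_z")
  expect_equal(rk$metabolite, c("m1", "m3", "m2"))
  # ties break lexicographically on id, stable across input order
  tab2 <- mini_meta(c(1, 1, 1), ids = c("b", "c", "a"))
  expect_equal(rank_metabolites(tab2, "signed_z")$metabolite,
               c("a", "b", "c"))
  expect_equal(rank_metabolites(tab2[c(3, 1, 2), ], "signed_z")$metabolite,
               c("a", "b", "c"))
  # q mode drops single-cohort metabolites
  tab3 <- mini_meta(c(2, 1), ids = c("m1", "m2"), n_studies = c(3, 1))
  expect_equal(rank_metabolites(tab3, "q_stat")$metabolite, "m1")
  expect_error(rank_metabolites(tab[0, ], "signed_z"), "empty")
})

test_that("enrichment score matches the stated tiny cases", {
  rk <- data.frame(metabolite = c("a", "b"), stat = c(2, -2))
  es <- enrichment_score(rk, "a")
  expect_equal(es$running_sum, c(1, 0))
  expect_equal(es$ES, 1)
  # complement of the top item walks negative
  expect_equal(enrichment_score(rk, "b")$ES, -1)
  expect_error(enrichment_score(rk, "zzz"), "no members")
  rk0 <- data.frame(metabolite = c("a", "b", "c"), stat = c(0, 0, 0))
  expect_error(enrichment_score(rk0, "a"), "zero")
})

test_that("enrichment score equals the brute-force walk oracle", {
  set.seed(4)
  for (i in 1:50) {
    N <- sample(6:12, 1)
    rk <- data.frame(metabolite = sprintf("m%02d", 1:N),
                     stat = round(rnorm(N), 2))
    rk <- rk[order(-rk$stat, rk$metabolite), ]
    n <- sample(2:4, 1)
    members <- sample(rk$metabolite, n)
    for (w in c(0, 1)) {
      got <- enrichment_score(rk, members, weight_exponent = w)
      expect_equal(got$ES,
                   oracle_es(rk$stat, rk$metabolite %in% members, w = w),
                   tolerance = 1e-12)
      # hit mass and miss mass each total one: walk ends at zero
      expect_lt(abs(got$running_sum[N]), 1e-12)
    }
  }
})

test_that("reversing the list and negating statistics negates the ES", {
  set.seed(12)
  rk <- data.frame(metabolite = sprintf("m%02d", 1:10),
                   stat = sort(rnorm(10, 0, 2), decreasing = TRUE))
  members <- c("m02", "m03", "m07")
  rev_rk <- data.frame(metabolite = rev(rk$metabolite),
                       stat = rev(-rk$stat))
  expect_equal(enrichment_score(rev_rk, members)$ES,
               -enrichment_score(rk, members)$ES, tolerance = 1e-12)
  expect_true(abs(enrichment_score(rk, members)$ES) <= 1)
})

test_that("enrichment score agrees with the fgsea reference walk", {
  library(fgsea)
  set.seed(6)
  stats <- sort(rnorm(40, 0, 2), decreasing = TRUE)
  rk <- data.frame(metabolite = sprintf("m%02d", 1:40), stat = stats)
  for (i in 1:10) {
    idx <- sort(sample(40, 6))
    got <- enrichment_score(rk, rk$metabolite[idx])$ES
    ref <- fgsea::calcGseaStat(stats, selectedStats = idx, gseaParam = 1)
    expect_equal(abs(got), abs(ref), tolerance = 1e-10)
    # sign must agree except at an exact |max| == |min| tie, where the two
    # implementations use opposite conventions
    if (abs(got + ref) > 1e-8 * max(abs(got), 1))
      expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("permutation null is seeded, shared-size and exhaustive when small", {
  # antisymmetric statistic vector: the null ES distribution is symmetric
  rk <- data.frame(metabolite = sprintf("m%02d", 1:30),
                   stat = seq(3, -3, length.out = 30))
  n1 <- permutation_null(rk, 5, n_perm = 500, seed = 10)
  n2 <- permutation_null(rk, 5, n_perm = 500, seed = 10)
  expect_identical(n1, n2)
  expect_false(attr(n1, "exhaustive"))
  expect_lt(abs(mean(n1)), 3 * sd(n1) / sqrt(length(n1)))
  # exhaustive mode: C(6,2) = 15 memberships enumerated
  rk6 <- data.frame(metabolite = sprintf("m%d", 1:6),
                    stat = c(2.5, 1.2, 0.4, -0.3, -1.1, -2.2))
  ex <- permutation_null(rk6, 2, n_perm = 100, seed = 1)
  expect_true(attr(ex, "exhaustive"))
  expect_length(ex, 15)
  # degenerate boundary: set size N - 1 still valid (6 memberships)
  expect_length(permutation_null(rk6, 5, n_perm = 10, seed = 1), 6)
  expect_length(permutation_null(rk6, 5, n_perm = 3, seed = 1), 3)
})

test_that("permutation p-value applies the same-sign plus-one rule", {
  # es above every null value, 999 same-sign nulls -> p = 1/1000
  null_es <- runif(999, 0.01, 0.5)
  pv <- permutation_pvalue(0.9, null_es)
  expect_equal(pv$pval, 1 / 1000)
  expect_equal(pv$nMoreExtreme, 0)
  # es at the median of same-sign nulls -> p near 0.5
  pv2 <- permutation_pvalue(median(null_es), null_es)
  expect_equal(pv2$pval, 0.5, tolerance = 0.01)
  # opposite-sign nulls are ignored
  pv3 <- permutation_pvalue(-0.2, c(null_es, -0.1, -0.3))
  expect_equal(pv3$n_same_sign, 2)
  expect_equal(pv3$pval, (1 + 1) / (2 + 1))
})

test_that("tiny-case p-values match exhaustive enumeration exactly", {
  set.seed(9)
  for (i in 1:20) {
    N <- sample(5:8, 1)
    stats <- round(rnorm(N, 0, 1.5), 2)
    rk <- data.frame(metabolite = sprintf("m%d", 1:N), stat = stats)
    rk <- rk[order(-rk$stat, rk$metabolite), ]
    n <- sample(2:3, 1)
    member_idx <- sort(sample(N, n))
    members <- rk$metabolite[member_idx]
    orc <- oracle_enrichment_exact(rk$stat, member_idx)
    got_es <- enrichment_score(rk, members)$ES
    null_es <- permutation_null(rk, n, n_perm = choose(N, n), seed = 1)
    got_p <- permutation_pvalue(got_es, null_es)
    expect_equal(got_es, orc$ES, tolerance = 1e-12)
    expect_equal(got_p$pval, orc$pval, tolerance = 1e-12)
    expect_equal(got_p$nMoreExtreme, orc$nMoreExtreme)
  }
})

test_that("NES normalizes by same-sign null mean magnitude", {
  null_es <- c(0.2, 0.4, -0.1, -0.5)
  expect_equal(normalized_es(0.3, null_es), 1)  # mean(|0.2, 0.4|) = 0.3
  expect_equal(normalized_es(-0.6, null_es), -2)
  expect_warning(nes <- normalized_es(0.5, c(-0.1, -0.2)), "same-sign")
  expect_true(is.na(nes))
  # with w = 0 the walk ignores magnitudes: doubling stats leaves NES fixed
  rk <- data.frame(metabolite = sprintf("m%d", 1:12),
                   stat = sort(rnorm(12), decreasing = TRUE))
  rk2 <- transform(rk, stat = stat * 2)
  members <- c("m2", "m5", "m9")
  es1 <- enrichment_score(rk, members, weight_exponent = 0)$ES
  es2 <- enrichment_score(rk2, members, weight_exponent = 0)$ES
  expect_equal(es1, es2, tolerance = 1e-12)
})

test_that("run_enrichment tests qualifying sets and is order-invariant", {
  set.seed(20)
  z <- c(sort(rnorm(8, 4, 0.5), decreasing = TRUE), rnorm(30))
  tab <- mini_meta(z, ids = sprintf("m%02d", 1:38))
  sets <- list(top = sprintf("m%02d", 1:8),
               rand = sprintf("m%02d", 9:20),
               tiny = sprintf("m%02d", 21:24),     # 4 members: excluded
               ghost = c("x1", "x2"))              # absent: excluded
  res <- run_enrichment(tab, sets, mode = "signed_z", n_perm = 400,
                        seed = 5)
  expect_setequal(res$pathway, c("top", "rand"))
  expect_equal(res$pathway[1], "top")
  expect_gt(res$ES[res$pathway == "top"], 0)
  expect_true(all(res$padj >= res$pval))
  expect_true(all(res$pval >= 1 / 401))
  # reordering the set db leaves results identical
  res2 <- run_enrichment(tab, sets[c(4, 3, 2, 1)], mode = "signed_z",
                         n_perm = 400, seed = 5)
  expect_equal(res[order(res$pathway), ], res2[order(res2$pathway), ],
               ignore_attr = TRUE)
  # no qualifying set warns and returns an empty frame
  expect_warning(empty <- run_enrichment(tab, sets["tiny"], n_perm = 50),
                 "no set qualifies")
  expect_equal(nrow(empty), 0)
})

test_that("plot data exposes the running-sum curve and stat-scaled ticks", {
  rk <- data.frame(metabolite = sprintf("m%d", 1:10),
                   stat = sort(rnorm(10), decreasing = TRUE))
  pd <- enrichment_plot_data(rk, c("m2", "m6"))
  expect_equal(nrow(pd$curve), 10)
  expect_equal(pd$ticks$position, c(2, 6))
  expect_equal(pd$ticks$stat, rk$stat[c(2, 6)])
  expect_lt(abs(pd$curve$running_sum[10]), 1e-12)
})
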