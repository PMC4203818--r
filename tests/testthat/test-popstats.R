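test_that("gene counting yields per-stratum closures", {
  d <- calls_from_labels("*1", "*2")
  ft <- allele_frequencies(d)
  expect_equal(sort(ft$pct), c(50, 50))

  sim <- small_sim(n = 30, seed = 41, rq_sd = 0, missing_rate = 0)
  calls <- sim$truth[, 1:7]
  ft2 <- allele_frequencies(calls, sim$cohort, by = "region")
  sums <- tapply(ft2$pct, ft2$region, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  totals <- tapply(ft2$count, ft2$region, sum)
  expect_true(all(totals == 60L))
  expect_error(allele_frequencies(calls_from_labels(character(0), character(0))),
               "empty")
})

test_that("activity aggregation removes undetermined slots from both sides", {
  only1 <- calls_from_labels(rep("*1", 5), rep("*1", 5))
  at <- activity_class_table(only1, DEFS)
  expect_equal(at$pct[at$activity == "normal"], 100)

  withND <- calls_from_labels(c("*1", "Others", "*34"), c("*4", "*1", "*17"))
  at2 <- activity_class_table(withND, DEFS)
  expect_equal(at2$n_evaluable[1], 4L) # 6 slots minus Others and *34
  expect_equal(sum(at2$count), 4L)
})

test_that("published-style count tables aggregate to the evaluable denominator", {
  sv <- published_survey_tables()$allele_counts
  agg <- aggregate_counts_by_activity(sv$allele, sv$total, DEFS)
  expect_equal(agg$n_evaluable[1], 2011L)
  expect_equal(agg$count[agg$activity == "none"], 303L)
  expect_equal(round(agg$pct[agg$activity == "none"], 1), 15.1)
})

test_that("Pearson chi-squared matches hand computation", {
  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  res <- chi2_independence(tab)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1L)

  prop <- matrix(c(10, 20, 20, 40), 2)
  r0 <- chi2_independence(prop)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(chi2_independence(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
})

test_that("the G test equals the likelihood-ratio formula", {
  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  g_hand <- 2 * sum(tab * log(tab / e))
  res <- g_test_independence(tab)
  expect_equal(res$statistic, g_hand, tolerance = 1e-12)

  expect_equal(g_test_independence(matrix(c(10, 20, 20, 40), 2))$statistic, 0)

  # asymptotic agreement with Pearson on well-filled tables
  set.seed(6)
  for (i in 1:5) {
    t2 <- matrix(rpois(12, 40) + 10, 3, 4)
    g <- g_test_independence(t2)$statistic
    x <- chi2_independence(t2)$statistic
    if (x > 0.5) expect_lt(abs(g - x) / x, 0.15)
  }
})

test_that("AMOVA components equal the distance-matrix computation", {
  set.seed(91)
  labels <- c("*1", "*2", "*4", "*17")
  grp_ind <- rep(c("a", "b", "c"), each = 10)
  a1 <- sample(labels, 30, TRUE, c(0.5, 0.3, 0.1, 0.1))
  a2 <- sample(labels, 30, TRUE, c(0.2, 0.2, 0.3, 0.3))
  res <- amova(c(a1, a2), grp_ind, n_permutations = 50, seed = 1)
  orc <- amova_oracle(c(a1, a2), c(grp_ind, grp_ind))
  expect_equal(res$sigma_among, orc$sigma_among, tolerance = 1e-10)
  expect_equal(res$sigma_within, orc$sigma_within, tolerance = 1e-10)
  expect_equal(res$phi_st, orc$phi, tolerance = 1e-10)
  expect_equal(res$pct_among + res$pct_within, 100, tolerance = 1e-9)
})

test_that("AMOVA spans the null and maximal-differentiation extremes", {
  set.seed(17)
  labels <- c("*1", "*2", "*4")
  al <- sample(labels, 160, TRUE)
  grp <- rep(c("x", "y"), each = 40)
  null_res <- amova(al, grp, n_permutations = 200, seed = 2)
  expect_gt(null_res$pct_within, 95)

  slot <- rep(c("*1", "*4"), each = 20)
  fx <- amova(c(slot, slot), rep(c("x", "y"), each = 20),
              n_permutations = 100, seed = 3)
  expect_equal(fx$phi_st, 1)
  expect_equal(fx$pct_among, 100)
  expect_lt(fx$p_value, 0.05)
})

test_that("Weir-Cockerham theta equals the nested-ANOVA formulation", {
  set.seed(55)
  labels <- c("*1", "*2", "*4")
  a1 <- sample(labels, 40, TRUE, c(0.6, 0.3, 0.1))
  a2 <- sample(labels, 40, TRUE, c(0.3, 0.3, 0.4))
  grp <- rep(c("p1", "p2"), each = 20)
  est <- pairwise_fst(a1, a2, grp, n_bootstrap = 0)
  orc <- wc_oracle(a1, a2, grp)
  expect_equal(est$theta, orc, tolerance = 1e-12)
})

test_that("theta hits its boundary cases", {
  # identical frequencies, large n: near zero with CI lower bound 0
  set.seed(10)
  labels <- c("*1", "*2", "*4")
  n <- 400
  a1 <- sample(labels, n, TRUE)
  a2 <- sample(labels, n, TRUE)
  grp <- rep(c("p1", "p2"), each = n / 2)
  est <- pairwise_fst(a1, a2, grp, n_bootstrap = 200, seed = 4)
  expect_lt(abs(est$theta), 0.02)
  expect_equal(est$ci_low, 0)
  expect_lte(est$ci_low, est$ci_high)

  # fixed difference: theta = 1
  fx <- pairwise_fst(rep(c("*1", "*4"), each = 20),
                     rep(c("*1", "*4"), each = 20),
                     rep(c("p1", "p2"), each = 20), n_bootstrap = 0)
  expect_equal(fx$theta, 1)

  expect_warning(
    mono <- pairwise_fst(rep("*1", 20), rep("*1", 20),
                         rep(c("p1", "p2"), each = 10), n_bootstrap = 0),
    "monomorphic")
  expect_equal(mono$theta, 0)
})

test_that("AMOVA and theta agree on two-group synthetic data", {
  set.seed(28)
  n <- 250
  labels <- c("*1", "*2", "*4", "*17")
  p1 <- c(0.45, 0.3, 0.15, 0.1)
  p2 <- c(0.35, 0.3, 0.15, 0.2)
  a1 <- c(sample(labels, n, TRUE, p1), sample(labels, n, TRUE, p2))
  a2 <- c(sample(labels, n, TRUE, p1), sample(labels, n, TRUE, p2))
  grp <- rep(c("x", "y"), each = n)
  th <- pairwise_fst(a1, a2, grp, n_bootstrap = 0)$theta
  ph <- amova(c(a1, a2), grp, n_permutations = 50, seed = 5)$phi_st
  expect_lt(abs(th - ph), 0.02)
  expect_equal(sign(th), sign(ph))
})

test_that("rank tests match hand computations", {
  kw <- kruskal_wallis(c(1:3, 4:6, 7:9), rep(letters[1:3], each = 3))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2L)

  same <- kruskal_wallis(rep(c(1, 2, 3), 3), rep(letters[1:3], each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)

  # rank-based: invariant under monotone transforms
  x <- c(0.1, 0.5, 0.9, 0.2, 0.6, 1.4, 0.3, 0.8, 2.2)
  g <- rep(letters[1:3], each = 3)
  expect_equal(kruskal_wallis(x, g)$statistic,
               kruskal_wallis(exp(x), g)$statistic, tolerance = 1e-12)

  mw <- mann_whitney(1:3, 4:6)
  expect_equal(mw$statistic, 0)
  # U_a + U_b = n_a n_b
  u_ab <- mann_whitney(c(1, 5, 3, 8), c(2, 6, 4))$statistic
  u_ba <- mann_whitney(c(2, 6, 4), c(1, 5, 3, 8))$statistic
  expect_equal(u_ab + u_ba, 12)
  ident <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p_value, 1, tolerance = 1e-9)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(3)
  p <- runif(20)
  adj <- bh_fdr(p)
  expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
  expect_true(all(adj <= 1 & adj >= p))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("rare-allele pooling respects the count threshold", {
  al <- c(rep("*1", 10), rep("*2", 6), rep("*39", 2), "*34")
  pooled <- pool_rare_alleles(al, min_count = 5)
  expect_setequal(unique(pooled), c("*1", "*2", "rare"))
  expect_equal(sum(pooled == "rare"), 3L)
})
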