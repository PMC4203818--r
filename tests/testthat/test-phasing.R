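panel_n <- length(cyp2d6_panel_labels())

test_that("fully homozygous cohorts reduce to gene counting with certain phase", {
  g <- geno_matrix(list(c("*1", "*1"), c("*1", "*1"), c("*4", "*4"),
                        c("*2", "*2")))
  ph <- em_phase(g, DEFS, n_restarts = 2, seed = 5)
  fr <- ph$frequencies
  expect_equal(sort(fr$freq[fr$freq > 1e-9], decreasing = TRUE),
               c(4, 2, 2) / 8, tolerance = 1e-9)
  expect_equal(fr$freq[fr$star == "*1"], 0.5, tolerance = 1e-9)
  expect_true(all(ph$best_pairs$posterior > 1 - 1e-9))
})

test_that("a single heterozygous site phases uniquely", {
  # *1/*39 differ only at 4180
  g <- geno_matrix(list(c("*1", "*39")))
  ph <- em_phase(g, DEFS, n_restarts = 2, seed = 5)
  fr <- ph$frequencies[ph$frequencies$freq > 1e-9, ]
  expect_setequal(fr$star, c("*1", "*39"))
  expect_equal(fr$freq, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(ph$best_pairs$posterior, 1, tolerance = 1e-9)
})

test_that("EM matches an independent likelihood maximizer on two-site cohorts", {
  # 20 individuals over *1 (ref at -1584 and 100), *35 (var at -1584 via G),
  # *10 (var at 100): construct genotypes varying only sites 1 and 3
  set.seed(42)
  true_f <- c(0.45, 0.25, 0.2, 0.1) # 00, 01, 10, 11 on sites (1, 3)
  draw <- function() sample(0:3, 1, prob = true_f)
  n <- 20
  h1 <- replicate(n, draw())
  h2 <- replicate(n, draw())
  bits <- function(h) c(h %/% 2, h %% 2)
  g <- matrix(0L, n, panel_n)
  g2 <- matrix(0L, n, 2)
  for (i in 1:n) {
    b <- bits(h1[i]) + bits(h2[i])
    g2[i, ] <- b
    g[i, 1] <- b[1]
    g[i, 3] <- b[2]
  }
  expect_true(any(g2[, 1] == 1 & g2[, 2] == 1)) # double heterozygotes present
  ph <- em_phase(g, DEFS, n_restarts = 5, seed = 9)
  f_oracle <- oracle_two_site(g2)
  # map package haplotype codes onto the 4 two-site haplotypes
  code_of <- function(b1, b3) b1 * 2^(panel_n - 1) + b3 * 2^(panel_n - 3)
  f_pkg <- vapply(list(c(0,0), c(0,1), c(1,0), c(1,1)), function(b) {
    i <- match(code_of(b[1], b[2]), ph$frequencies$code)
    if (is.na(i)) 0 else ph$frequencies$freq[i]
  }, 0)
  expect_equal(f_pkg, f_oracle, tolerance = 1e-4)
})

test_that("the EM log-likelihood never decreases", {
  sim <- small_sim(n = 25, seed = 3)
  ph <- em_phase(sim$cohort, DEFS, n_restarts = 3, seed = 3)
  expect_true(all(diff(ph$log_likelihood_trace) > -1e-10))
  expect_true(ph$converged)
})

test_that("EM recovers known haplotype frequencies at n = 500", {
  labels <- c("*1", "*2", "*4", "*17", "*41", "*10")
  true_f <- c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04)
  set.seed(77)
  n <- 500
  a <- sample(labels, n, TRUE, true_f)
  b <- sample(labels, n, TRUE, true_f)
  g <- geno_matrix(Map(c, a, b))
  ph <- em_phase(g, DEFS, n_restarts = 3, seed = 1)
  emp <- table(factor(c(a, b), levels = labels)) / (2 * n)
  for (k in seq_along(labels)) {
    est <- ph$frequencies$freq[match(labels[k], ph$frequencies$star)]
    se <- sqrt(true_f[k] * (1 - true_f[k]) / (2 * n))
    expect_lt(abs(est - true_f[k]), 3 * se + 1e-12)
  }
})

test_that("restarts agree on cohorts drawn from few haplotypes", {
  labels <- c("*1", "*2", "*4", "*41")
  set.seed(8)
  n <- 60
  g <- geno_matrix(Map(c, sample(labels, n, TRUE), sample(labels, n, TRUE)))
  ll_final <- function(seed) {
    ph <- em_phase(g, DEFS, n_restarts = 5, seed = seed)
    ph$log_likelihood_trace[length(ph$log_likelihood_trace)]
  }
  expect_lt(abs(ll_final(1) - ll_final(99)), 1e-6)
})

test_that("one-copy individuals contribute a single chromosome", {
  g <- geno_matrix(list(c("*1", "*2"), c("*1", "*1"), c("*4", "*4")))
  ph <- em_phase(g, DEFS, cn = c(2L, 2L, 1L), n_restarts = 2, seed = 5)
  expect_equal(ph$n_chromosomes, 5L)
  fr <- ph$frequencies
  expect_equal(fr$freq[fr$star == "*4"], 1 / 5, tolerance = 1e-9)
  expect_equal(ph$best_pairs$n_copies_phased, c(2L, 2L, 1L))
  expect_true(is.na(ph$best_pairs$hap_b[3]))
})

test_that("zero-copy and all-missing individuals are excluded with a warning", {
  g <- geno_matrix(list(c("*1", "*2"), c("*1", "*1")))
  g <- rbind(g, NA_integer_)
  expect_warning(ph <- em_phase(g, DEFS, n_restarts = 2, seed = 5),
                 "all site calls missing")
  expect_equal(ph$n_chromosomes, 4L)
  expect_equal(ph$best_pairs$n_copies_phased[3], 0L)
})

test_that("phasing is deterministic given the seed", {
  sim <- small_sim(n = 15, seed = 21)
  p1 <- em_phase(sim$cohort, DEFS, seed = 4)
  p2 <- em_phase(sim$cohort, DEFS, seed = 4)
  expect_identical(p1$frequencies, p2$frequencies)
  expect_identical(p1$best_pairs, p2$best_pairs)
})

test_that("diplotype posteriors follow Hardy-Weinberg weighting", {
  # homozygous record: one resolution, probability 1
  g_hom <- geno_from_labels("*1", "*1")
  f <- c(`0` = 0.6, `1` = 0.4) # *1 and *39 codes
  names(f) <- c(cyp2d6star:::states_to_code(hap_states("*1"), DEFS),
                cyp2d6star:::states_to_code(hap_states("*39"), DEFS))
  pp <- phase_posterior(g_hom, f)
  expect_equal(nrow(pp), 1L)
  expect_equal(pp$prob, 1)

  # double heterozygote, cis haplotypes hold all frequency: cis certain
  c1 <- cyp2d6star:::states_to_code(hap_states("*1"), DEFS)
  c35 <- cyp2d6star:::states_to_code(hap_states("*35"), DEFS)
  g_dh <- geno_from_labels("*1", "*35") # het at sites 1, 2, 8, 11
  f2 <- stats::setNames(c(0.5, 0.5), c(c1, c35))
  pp2 <- phase_posterior(g_dh, f2)
  expect_equal(pp2$prob[1], 1)
  expect_setequal(c(pp2$hap_a[1], pp2$hap_b[1]), c(c1, c35))

  # uniform frequencies over all compatible haplotypes: double het at two
  # sites splits 0.5 / 0.5 by the symmetry of 2 f_i f_j
  g2 <- integer(panel_n)
  g2[c(1, 3)] <- 1L
  codes <- unique(as.vector(cyp2d6star:::enumerate_pairs(g2)))
  f3 <- stats::setNames(rep(1 / length(codes), length(codes)), codes)
  pp3 <- phase_posterior(g2, f3)
  expect_equal(nrow(pp3), 2L)
  expect_equal(pp3$prob, c(0.5, 0.5))

  # incompatible record falls back to uniform ranking via the floor
  f4 <- stats::setNames(1, c1 + 1) # all mass on an incompatible haplotype
  pp4 <- phase_posterior(g_dh, f4)
  expect_equal(sum(pp4$prob), 1)
  expect_equal(pp4$prob, rep(1 / nrow(pp4), nrow(pp4)))
})
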