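# Independent oracles used by both the unit and the acceptance tests.
# Each recomputes a quantity through a route that shares no code with the
# package implementation it checks.

# Maximum-likelihood haplotype frequencies for a two-site system by
# multi-start Nelder-Mead on softmax-parameterized frequencies over the
# 4-haplotype simplex (haplotypes 00, 01, 10, 11).
oracle_two_site <- function(g2) {
  pair_sets <- apply(g2, 1, function(r) {
    a <- list(`0` = list(c(0, 0)), `1` = list(c(0, 1), c(1, 0)),
              `2` = list(c(1, 1)))
    s1 <- a[[as.character(r[1])]]
    s2 <- a[[as.character(r[2])]]
    out <- list()
    for (x in s1) for (y in s2) {
      out[[length(out) + 1L]] <- c(2 * x[1] + y[1] + 1L, 2 * x[2] + y[2] + 1L)
    }
    out
  })
  negll <- function(theta) {
    f <- exp(c(theta, 0))
    f <- f / sum(f)
    -sum(vapply(pair_sets, function(ps) {
      log(sum(vapply(ps, function(p) f[p[1]] * f[p[2]], 0)))
    }, 0))
  }
  best <- NULL
  for (s in 1:10) {
    set.seed(s)
    fit <- stats::optim(stats::rnorm(3), negll, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  f <- exp(c(best$par, 0))
  f / sum(f)
}

# AMOVA sums of squares from the full pairwise identity-distance matrix,
# components from the standard unequal-size one-way partition.
amova_oracle <- function(alleles, grp) {
  N <- length(alleles)
  d <- outer(alleles, alleles, FUN = "!=") * 1
  ss_total <- sum(d[lower.tri(d)]) / N
  groups <- unique(grp)
  ss_within <- 0
  for (g in groups) {
    sel <- grp == g
    dg <- d[sel, sel, drop = FALSE]
    ss_within <- ss_within + sum(dg[lower.tri(dg)]) / sum(sel)
  }
  ng <- table(grp)
  G <- length(groups)
  ms_a <- (ss_total - ss_within) / (G - 1)
  ms_w <- ss_within / (N - G)
  n_c <- (N - sum(ng^2) / N) / (G - 1)
  s_a <- (ms_a - ms_w) / n_c
  list(sigma_among = s_a, sigma_within = ms_w, phi = s_a / (s_a + ms_w))
}

# Weir-Cockerham multi-allelic theta through the nested-ANOVA route:
# per-allele indicator variables over gene copies, individuals nested in
# populations; a = (MSP - MSI) / (2 n_c), b = (MSI - MSG) / 2, c = MSG.
wc_oracle <- function(a1, a2, grp) {
  lev <- unique(c(a1, a2))
  grp <- factor(grp)
  r <- nlevels(grp)
  ni <- as.vector(table(grp))
  nbar <- mean(ni)
  n_c <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  A <- 0; B <- 0; C <- 0
  n <- length(a1)
  for (k in lev) {
    y <- rbind(as.numeric(a1 == k), as.numeric(a2 == k))
    ybar_ind <- colMeans(y)
    ybar_pop <- tapply(ybar_ind, grp, mean)
    ybar_all <- mean(ybar_ind)
    msg <- sum((y[1, ] - ybar_ind)^2 + (y[2, ] - ybar_ind)^2) / n
    msi <- 2 * sum((ybar_ind - ybar_pop[as.integer(grp)])^2) / (n - r)
    msp <- 2 * sum(ni * (ybar_pop - ybar_all)^2) / (r - 1)
    A <- A + (msp - msi) / (2 * n_c)
    B <- B + (msi - msg) / 2
    C <- C + msg
  }
  A / (A + B + C)
}
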