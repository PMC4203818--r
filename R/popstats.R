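# Population statistics over star-allele calls: gene-counting frequency
# tables, activity-class aggregation, contingency tests, two-level
# haplotypic AMOVA with permutation p, Weir-Cockerham multi-allelic theta
# with bootstrap CIs, and rank-based ancestry association tests.

# Expand diplotype calls into one row per allele slot (2 per individual;
# an xN label occupies a single slot, so a cohort of N individuals always
# yields 2N slots).
diplotype_slots <- function(calls, data = NULL, by = NULL) {
  out <- tibble(
    individual_id = rep(calls$individual_id, 2L),
    allele = c(calls$allele_a, calls$allele_b)
  )
  if (!is.null(by)) {
    if (is.null(data)) stop("`data` is required when `by` is given")
    for (v in by) out[[v]] <- rep(data[[v]], 2L)
  }
  out
}

#' Allele frequencies by gene counting
#'
#' Tallies the two allele slots of every diplotype call per stratum and
#' reports counts and percent frequencies. An xN duplication label
#' occupies one slot, so per-stratum counts always sum to twice the number
#' of individuals; duplications that could not be attributed to an allele
#' are counted under their base labels.
#'
#' @param calls Diplotype-call tibble.
#' @param data Optional tibble aligned with \code{calls} carrying stratum
#'   columns.
#' @param by Stratum column name(s) in \code{data}; \code{NULL} for the
#'   total sample.
#' @return Tibble with the stratum columns, \code{allele}, \code{count},
#'   \code{pct}, \code{n_chromosomes}; class \code{cyp_freq_table}.
#' @export
allele_frequencies <- function(calls, data = NULL, by = NULL) {
  if (nrow(calls) == 0L) stop("empty cohort")
  slots <- diplotype_slots(calls, data, by)
  slots <- slots[!is.na(slots$allele), , drop = FALSE]
  counts <- dplyr::count(slots, dplyr::across(dplyr::all_of(c(by, "allele"))),
                         name = "count")
  if (!is.null(by)) {
    totals <- dplyr::count(slots, dplyr::across(dplyr::all_of(by)),
                           name = "n_chromosomes")
    counts <- dplyr::inner_join(counts, totals, by = by)
  } else {
    counts$n_chromosomes <- nrow(slots)
  }
  counts$pct <- 100 * counts$count / counts$n_chromosomes
  structure(as_tibble(counts), class = c("cyp_freq_table", class(counts)))
}

#' Aggregate allele counts into activity classes
#'
#' Groups allele slots into predicted-activity classes (none, reduced,
#' normal, increased) over the evaluable-chromosome denominator:
#' undetermined-activity slots (unassignable "Others" haplotypes and
#' ND-activity alleles) are removed from both numerator and denominator,
#' as are any duplication copies that could not be attributed to an allele
#' (those never occupy a slot).
#'
#' @inheritParams allele_frequencies
#' @param defs Allele definitions.
#' @return Tibble with stratum columns, \code{activity}, \code{count},
#'   \code{pct}, \code{n_evaluable}.
#' @export
activity_class_table <- function(calls, defs, data = NULL, by = NULL) {
  slots <- diplotype_slots(calls, data, by)
  slots <- slots[!is.na(slots$allele), , drop = FALSE]
  slots$activity <- classify_activity(slots$allele, defs)
  slots <- slots[slots$activity != "ND", , drop = FALSE]
  slots$activity <- factor(slots$activity,
                           levels = setdiff(ACTIVITY_LEVELS, "ND"))
  counts <- dplyr::count(slots, dplyr::across(dplyr::all_of(c(by, "activity"))),
                         .drop = FALSE, name = "count")
  if (!is.null(by)) {
    totals <- dplyr::count(slots, dplyr::across(dplyr::all_of(by)),
                           name = "n_evaluable")
    counts <- dplyr::inner_join(counts, totals, by = by)
  } else {
    counts$n_evaluable <- nrow(slots)
  }
  counts$pct <- 100 * counts$count / counts$n_evaluable
  as_tibble(counts)
}

#' Aggregate a published allele-count table into activity classes
#'
#' Same aggregation as \code{\link{activity_class_table}} but starting from
#' a table of allele labels and chromosome counts (e.g. a published survey
#' table) instead of per-individual calls.
#'
#' @param alleles Character vector of allele labels (may include
#'   \code{"Others"}).
#' @param counts Integer vector of chromosome counts.
#' @param defs Allele definitions.
#' @return Tibble \code{activity}, \code{count}, \code{pct},
#'   \code{n_evaluable}.
#' @export
aggregate_counts_by_activity <- function(alleles, counts, defs) {
  act <- classify_activity(alleles, defs)
  keep <- act != "ND"
  total <- sum(counts[keep])
  agg <- tapply(counts[keep],
                factor(act[keep], levels = setdiff(ACTIVITY_LEVELS, "ND")),
                sum, default = 0L)
  tibble(
    activity = names(agg),
    count = as.integer(agg),
    pct = 100 * as.integer(agg) / total,
    n_evaluable = total
  )
}

test_result <- function(method, statistic, df, p_value, ...) {
  structure(
    tibble(method = method, statistic = statistic, df = df,
           p_value = p_value, ...),
    class = c("cyp_test", "tbl_df", "tbl", "data.frame")
  )
}

check_margins <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("contingency table must be at least 2 x 2")
  if (any(tab < 0)) stop("contingency table must be non-negative")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0)) stop("zero row margin: ",
                         paste(which(rs == 0), collapse = ", "))
  if (any(cs == 0)) stop("zero column margin: ",
                         paste(which(cs == 0), collapse = ", "))
  tab
}

#' Pearson chi-squared test of independence
#'
#' @param tab An r x c matrix of counts.
#' @return A \code{cyp_test} tibble: method, statistic, df, p_value.
#' @export
chi2_independence <- function(tab) {
  tab <- check_margins(tab)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result("Pearson chi-squared", unname(ct$statistic),
              unname(ct$parameter), ct$p.value)
}

#' Likelihood-ratio (G) test of independence
#'
#' The likelihood-ratio test of the saturated against the independence
#' log-linear model for an r x c table: \eqn{G^2 = 2 \sum O \log(O/E)}
#' over cells with positive observed counts, on (r-1)(c-1) degrees of
#' freedom. For a single categorical predictor this is the multinomial
#' log-linear association test.
#'
#' @inheritParams chi2_independence
#' @export
g_test_independence <- function(tab) {
  tab <- check_margins(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pos <- tab > 0
  g2 <- 2 * sum(tab[pos] * log(tab[pos] / e[pos]))
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  test_result("G-test (likelihood-ratio)", g2, df,
              stats::pchisq(g2, df, lower.tail = FALSE))
}

# --- AMOVA ----------------------------------------------------------------

# Identity-distance sums of squares from label counts. For 0/1 distance the
# pairwise-distance sums reduce to allele-count arithmetic, which is what
# makes the permutation test cheap; tests verify the identity against the
# full distance-matrix computation.
amova_components <- function(allele_int, group_int, n_groups, n_levels) {
  N <- length(allele_int)
  cnt_tot <- tabulate(allele_int, n_levels)
  ss_total <- (N^2 - sum(cnt_tot^2)) / (2 * N)
  ss_within <- 0
  ng <- tabulate(group_int, n_groups)
  for (g in seq_len(n_groups)) {
    sel <- group_int == g
    cg <- tabulate(allele_int[sel], n_levels)
    ss_within <- ss_within + (ng[g]^2 - sum(cg^2)) / (2 * ng[g])
  }
  ss_among <- ss_total - ss_within
  df_among <- n_groups - 1L
  df_within <- N - n_groups
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  n_c <- (N - sum(ng^2) / N) / df_among
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n_c
  denom <- sigma_among + sigma_within
  list(ss_total = ss_total, ss_among = ss_among, ss_within = ss_within,
       df_among = df_among, df_within = df_within,
       sigma_among = sigma_among, sigma_within = sigma_within,
       phi_st = if (denom > 0) sigma_among / denom else 0)
}

#' Two-level haplotypic AMOVA with permutation test
#'
#' Analysis of molecular variance partitioning allele-frequency variation
#' among and within populations, using label-identity distance (0 for
#' identical star-allele labels, 1 otherwise), which makes the fixation
#' index a pure frequency statistic. The permutation p-value shuffles
#' individuals among groups with both chromosomes moving together and is
#' the proportion of permutations (plus one, including the observed
#' arrangement) whose fixation index is at least the observed one.
#'
#' @param alleles Character vector of allele labels, two consecutive
#'   entries per individual, or a 2-column matrix (one row per
#'   individual).
#' @param group Group label per individual.
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed for the permutations.
#' @return Object of class \code{cyp_amova}: list with variance
#'   components, percentages, \code{phi_st}, \code{p_value},
#'   \code{n_permutations}.
#' @export
amova <- function(alleles, group, n_permutations = 10000L, seed = 1L) {
  if (is.matrix(alleles)) {
    alleles <- c(alleles[, 1L], alleles[, 2L])
  }
  al <- as.character(alleles)
  n_ind <- length(group)
  if (length(al) != 2L * n_ind) {
    stop("`alleles` must supply two chromosomes per individual ",
         "(a 2-column matrix, or a vector with slot-a labels followed by slot-b labels)")
  }
  if (anyNA(al)) stop("allele labels must be non-missing")
  grp <- factor(group)
  if (nlevels(grp) < 2L) stop("at least two groups are required")
  if (any(table(grp) < 1L)) stop("every group needs at least one individual")
  lev <- unique(al)
  allele_int <- match(al, lev)
  # chromosome i and i + n_ind belong to individual i
  gi <- as.integer(grp)
  group_chrom <- c(gi, gi)
  obs <- amova_components(allele_int, group_chrom, nlevels(grp), length(lev))

  old_seed <- local_rng_seed(seed)
  on.exit(restore_rng_seed(old_seed), add = TRUE)
  phi_perm <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    pg <- gi[sample.int(n_ind)]
    phi_perm[b] <- amova_components(allele_int, c(pg, pg),
                                    nlevels(grp), length(lev))$phi_st
  }
  p <- (sum(phi_perm >= obs$phi_st) + 1) / (n_permutations + 1)

  denom <- obs$sigma_among + obs$sigma_within
  structure(list(
    sigma_among = obs$sigma_among,
    sigma_within = obs$sigma_within,
    pct_among = 100 * obs$sigma_among / denom,
    pct_within = 100 * obs$sigma_within / denom,
    phi_st = obs$phi_st,
    p_value = p,
    n_permutations = n_permutations,
    ss = c(among = obs$ss_among, within = obs$ss_within,
           total = obs$ss_total),
    df = c(among = obs$df_among, within = obs$df_within)
  ), class = "cyp_amova")
}

#' @export
print.cyp_amova <- function(x, ...) {
  cat("AMOVA (label-identity distance)\n")
  cat(sprintf("  among populations:  %6.2f%% (sigma^2 = %.6g)\n",
              x$pct_among, x$sigma_among))
  cat(sprintf("  within populations: %6.2f%% (sigma^2 = %.6g)\n",
              x$pct_within, x$sigma_within))
  cat(sprintf("  Phi_ST = %.5g, permutation p = %.4g (%d permutations)\n",
              x$phi_st, x$p_value, x$n_permutations))
  invisible(x)
}

# --- Weir-Cockerham multi-allelic theta -----------------------------------

# Per-allele variance components a, b, c summed over alleles of one
# multi-allelic locus scored on diploid individuals in r populations.
# `a1`, `a2`: integer allele indices per individual; `gi`: population index.
wc_theta_components <- function(a1, a2, gi, r, n_levels) {
  ni <- tabulate(gi, r)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  a_sum <- 0
  b_sum <- 0
  c_sum <- 0
  for (k in seq_len(n_levels)) {
    # allele dosage and heterozygote indicator per individual
    dos <- (a1 == k) + (a2 == k)
    het <- as.numeric(dos == 1L)
    p_i <- vapply(seq_len(r), function(g) sum(dos[gi == g]) / (2 * ni[g]),
                  numeric(1))
    h_i <- vapply(seq_len(r), function(g) mean(het[gi == g]), numeric(1))
    pbar <- sum(ni * p_i) / (r * nbar)
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    a_k <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b_k <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    c_k <- hbar / 2
    a_sum <- a_sum + a_k
    b_sum <- b_sum + b_k
    c_sum <- c_sum + c_k
  }
  c(a = a_sum, b = b_sum, c = c_sum)
}

wc_theta <- function(a1, a2, gi, r, n_levels) {
  comp <- wc_theta_components(a1, a2, gi, r, n_levels)
  denom <- comp[["a"]] + comp[["b"]] + comp[["c"]]
  if (denom == 0) return(NA_real_)
  comp[["a"]] / denom
}

#' Pairwise Weir-Cockerham F_ST with bootstrap confidence interval
#'
#' The multi-allelic Weir-Cockerham estimator theta for one locus scored
#' on diploid individuals in two (or more) populations: per-allele
#' variance components a, b, c are summed over alleles and
#' \eqn{\theta = \sum a / \sum (a + b + c)}. The star-allele locus is
#' treated as a single multi-allelic locus. The percentile confidence
#' interval resamples individuals with replacement within each population;
#' the lower bound is truncated at 0, and negative point estimates are
#' reported as computed.
#'
#' @param allele_a,allele_b The two allele labels per individual.
#' @param group Population label per individual (2 or more levels).
#' @param n_bootstrap Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param conf_level Confidence level of the percentile interval.
#' @return Object of class \code{cyp_fst}: list \code{theta},
#'   \code{ci_low}, \code{ci_high}, \code{n_bootstrap}.
#' @export
pairwise_fst <- function(allele_a, allele_b, group, n_bootstrap = 3000L,
                         seed = 1L, conf_level = 0.95) {
  grp <- factor(group)
  r <- nlevels(grp)
  if (r < 2L) stop("at least two populations are required")
  if (any(table(grp) < 2L)) stop("every population needs at least two individuals")
  lev <- unique(c(allele_a, allele_b))
  a1 <- match(allele_a, lev)
  a2 <- match(allele_b, lev)
  gi <- as.integer(grp)
  theta <- wc_theta(a1, a2, gi, r, length(lev))
  if (is.na(theta)) {
    warning("monomorphic populations: theta defined as 0")
    theta <- 0
  }
  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0L) {
    old_seed <- local_rng_seed(seed)
    on.exit(restore_rng_seed(old_seed), add = TRUE)
    idx_by_group <- split(seq_along(gi), gi)
    boot <- numeric(n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      idx <- unlist(lapply(idx_by_group, function(ix) {
        ix[sample.int(length(ix), replace = TRUE)]
      }), use.names = FALSE)
      th <- wc_theta(a1[idx], a2[idx], gi[idx], r, length(lev))
      boot[b] <- if (is.na(th)) 0 else th
    }
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
    ci[1L] <- max(0, ci[1L])
  }
  structure(list(theta = theta, ci_low = ci[1L], ci_high = ci[2L],
                 n_bootstrap = n_bootstrap),
            class = "cyp_fst")
}

#' @export
print.cyp_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham theta = %.5g (95%% CI %.4g-%.4g, %d bootstraps)\n",
              x$theta, x$ci_low, x$ci_high, x$n_bootstrap))
  invisible(x)
}

#' All pairwise F_ST estimates between strata
#'
#' @param calls Diplotype-call tibble.
#' @param data Tibble aligned with \code{calls} carrying the stratum
#'   column.
#' @param by Name of the stratum column.
#' @inheritParams pairwise_fst
#' @return Tibble \code{group_1}, \code{group_2}, \code{theta},
#'   \code{ci_low}, \code{ci_high}.
#' @export
fst_matrix <- function(calls, data, by, n_bootstrap = 3000L, seed = 1L) {
  g <- as.character(data[[by]])
  levs <- sort(unique(g))
  pairs <- utils::combn(levs, 2L)
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    sel <- g %in% pairs[, j]
    est <- pairwise_fst(calls$allele_a[sel], calls$allele_b[sel], g[sel],
                        n_bootstrap = n_bootstrap, seed = seed + j)
    out[[j]] <- tibble(group_1 = pairs[1L, j], group_2 = pairs[2L, j],
                       theta = est$theta, ci_low = est$ci_low,
                       ci_high = est$ci_high)
  }
  dplyr::bind_rows(out)
}

# --- rank-based ancestry association --------------------------------------

#' Kruskal-Wallis test
#'
#' Rank-based one-way comparison of a continuous value (e.g. an ancestry
#' proportion) across groups, with tie correction; p from the chi-squared
#' approximation on k - 1 degrees of freedom.
#'
#' @param values Numeric vector.
#' @param group Group label per value.
#' @return A \code{cyp_test} tibble (statistic H).
#' @export
kruskal_wallis <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("at least two groups are required")
  if (length(unique(values)) == 1L) {
    return(test_result("Kruskal-Wallis", 0, nlevels(group) - 1L, 1))
  }
  kt <- stats::kruskal.test(values, group)
  test_result("Kruskal-Wallis", unname(kt$statistic),
              unname(kt$parameter), kt$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test with the normal approximation and tie correction;
#' two-sided. The reported statistic is U for the first sample.
#'
#' @param a,b Numeric vectors.
#' @return A \code{cyp_test} tibble (statistic U; \code{df} is NA).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
  test_result("Mann-Whitney U", unname(wt$statistic), NA_integer_,
              wt$p.value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Ancestry-phenotype association battery
#'
#' For each genomic-ancestry component, a Kruskal-Wallis test across the
#' metabolizer phenotype classes (ND excluded), followed by pairwise
#' Mann-Whitney comparisons with Benjamini-Hochberg adjustment.
#'
#' @param cohort Cohort tibble with \code{anc_amerindian},
#'   \code{anc_african}, \code{anc_european}.
#' @param phenotypes Tibble from \code{\link{predict_phenotype}} aligned
#'   with \code{cohort}.
#' @return List with \code{kruskal} (one row per ancestry component) and
#'   \code{pairwise} (per component and phenotype pair, raw and adjusted
#'   p).
#' @export
ancestry_association <- function(cohort, phenotypes) {
  comp <- c(Amerindian = "anc_amerindian", African = "anc_african",
            European = "anc_european")
  ph <- as.character(phenotypes$phenotype)
  keep <- ph != "ND" & !is.na(ph)
  kw <- vector("list", length(comp))
  pw <- vector("list", length(comp))
  classes <- intersect(c("PM", "IM", "EM", "UM"), unique(ph[keep]))
  for (i in seq_along(comp)) {
    v <- cohort[[comp[i]]][keep]
    g <- ph[keep]
    kt <- kruskal_wallis(v, g)
    kw[[i]] <- tibble(ancestry = names(comp)[i],
                      H = kt$statistic, df = kt$df, p_value = kt$p_value)
    if (length(classes) >= 2L) {
      prs <- utils::combn(classes, 2L)
      rows <- vector("list", ncol(prs))
      for (j in seq_len(ncol(prs))) {
        mt <- mann_whitney(v[g == prs[1L, j]], v[g == prs[2L, j]])
        rows[[j]] <- tibble(ancestry = names(comp)[i],
                            class_1 = prs[1L, j], class_2 = prs[2L, j],
                            U = mt$statistic, p_value = mt$p_value)
      }
      tab <- dplyr::bind_rows(rows)
      tab$p_adjusted <- bh_fdr(tab$p_value)
      pw[[i]] <- tab
    }
  }
  list(kruskal = dplyr::bind_rows(kw), pairwise = dplyr::bind_rows(pw))
}

#' Pool rare allele labels
#'
#' Replaces labels whose total count is below a threshold with
#' \code{"rare"}; used before region-by-allele contingency tests so that
#' expected cell counts are not dominated by singleton alleles.
#'
#' @param alleles Character vector of allele labels.
#' @param min_count Pooling threshold on the total count of a label.
#' @return Character vector with rare labels replaced.
#' @export
pool_rare_alleles <- function(alleles, min_count = 5L) {
  tab <- table(alleles)
  rare <- names(tab)[tab < min_count]
  ifelse(alleles %in% rare, "rare", alleles)
}
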