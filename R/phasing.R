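# EM haplotype-frequency estimation for the 11-site biallelic panel.
#
# Haplotypes are integer bit codes (site 1 = most significant bit, 1 =
# variant state) so that numeric order equals lexicographic order of state
# vectors, which is what the deterministic tie-break uses.

# Per-site diploid genotype codes: 0 hom-ref, 1 het, 2 hom-var, NA missing.
# `cohort` is a cohort tibble (see read_cohort); returns an n x 11 matrix.
cohort_genotype_codes <- function(cohort, defs) {
  s <- defs$sites
  n <- nrow(cohort)
  g <- matrix(NA_integer_, n, PANEL_SIZE)
  for (j in seq_len(PANEL_SIZE)) {
    tok <- site_column_token(s$label[j])
    a <- cohort[[paste0("g_", tok, "_1")]]
    b <- cohort[[paste0("g_", tok, "_2")]]
    av <- site_state_code(a, s$reference_state[j], s$variant_state[j], s$label[j])
    bv <- site_state_code(b, s$reference_state[j], s$variant_state[j], s$label[j])
    g[, j] <- av + bv
  }
  g
}

site_state_code <- function(x, ref, var, label) {
  out <- rep(NA_integer_, length(x))
  out[!is.na(x) & x == ref] <- 0L
  out[!is.na(x) & x == var] <- 1L
  bad <- !is.na(x) & x != "." & is.na(out)
  if (any(bad)) {
    stop(sprintf("site %s: state '%s' is neither reference (%s) nor variant (%s)",
                 label, x[which(bad)[1L]], ref, var))
  }
  out
}

# All ordered haplotype-pair resolutions compatible with one genotype row.
# Missing sites are marginalized (all four ordered state pairs). Returns a
# two-column integer matrix of bit codes.
enumerate_pairs <- function(grow) {
  a <- 0L
  b <- 0L
  for (j in seq_len(PANEL_SIZE)) {
    bit <- 2L^(PANEL_SIZE - j)
    gj <- grow[j]
    if (is.na(gj)) {
      site <- cbind(c(0L, 0L, bit, bit), c(0L, bit, 0L, bit))
    } else if (gj == 0L) {
      site <- cbind(0L, 0L)
    } else if (gj == 2L) {
      site <- cbind(bit, bit)
    } else {
      site <- cbind(c(0L, bit), c(bit, 0L))
    }
    k <- nrow(site)
    m <- length(a)
    if (m * k > 65536L) {
      stop("too many haplotype-pair resolutions for one individual (too many missing/heterozygous sites)")
    }
    a <- rep(a, each = k) + rep(site[, 1L], m)
    b <- rep(b, each = k) + rep(site[, 2L], m)
  }
  cbind(a, b)
}

# Compatible single haplotypes for a hemizygous (one-copy) individual.
enumerate_hemi <- function(grow) {
  h <- 0L
  for (j in seq_len(PANEL_SIZE)) {
    bit <- 2L^(PANEL_SIZE - j)
    gj <- grow[j]
    states <- if (is.na(gj)) c(0L, bit) else if (gj == 2L) bit else 0L
    h <- rep(h, each = length(states)) + rep(states, length(h))
  }
  h
}

#' Estimate haplotype frequencies by expectation-maximization
#'
#' Maximum-likelihood haplotype-frequency estimation under Hardy-Weinberg
#' random pairing (multinomial EM in the Excoffier-Slatkin style), over all
#' diplotype resolutions consistent with each unphased genotype. Missing
#' site calls are marginalized, not imputed. Individuals with a single gene
#' copy (copy number 1) contribute one chromosome, read directly from their
#' homozygous-appearing calls; individuals with copy number 0 (homozygous
#' whole-gene deletion) contribute none. Individuals with three or more
#' copies are phased as diploid; the extra copy is resolved downstream
#' during diplotype assembly.
#'
#' The EM is run from \code{n_restarts} random initializations plus one
#' allele-frequency-product initialization, and the restart with the highest
#' final log-likelihood is kept. Results are deterministic given
#' \code{seed}.
#'
#' @param cohort A cohort tibble (\code{\link{read_cohort}} or
#'   \code{\link{simulate_cohort}}), or an n x 11 integer genotype matrix
#'   (0 hom-ref, 1 het, 2 hom-var, NA missing).
#' @param defs Allele definitions.
#' @param cn Optional integer copy-number vector (recycled from the cohort's
#'   \code{cn} column when present); NA is treated as two copies for phasing.
#' @param tol Convergence threshold on the log-likelihood change.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of random restarts (in addition to the
#'   allele-frequency-product initialization).
#' @param seed Integer seed controlling the random restarts.
#' @return An object of class \code{cyp_phasing}: list with
#'   \code{frequencies} (tibble \code{code}, \code{states}, \code{star},
#'   \code{freq}), \code{best_pairs} (tibble \code{row}, \code{id},
#'   \code{hap_a}, \code{hap_b}, \code{star_a}, \code{star_b},
#'   \code{posterior}, \code{phase_ambiguous}, \code{n_copies_phased}),
#'   \code{log_likelihood_trace}, \code{n_iterations}, \code{converged}.
#' @export
em_phase <- function(cohort, defs, cn = NULL, tol = 1e-8, max_iter = 1000L,
                     n_restarts = 5L, seed = 1L) {
  if (is.matrix(cohort)) {
    g <- cohort
    ids <- rownames(g)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(g)))
  } else {
    g <- cohort_genotype_codes(cohort, defs)
    ids <- cohort$id
    if (is.null(cn) && "cn" %in% names(cohort)) cn <- cohort$cn
  }
  n <- nrow(g)
  if (n == 0L) stop("empty cohort")
  if (is.null(cn)) cn <- rep(NA_integer_, n)
  cn <- rep_len(as.integer(cn), n)

  all_missing <- apply(g, 1L, function(r) all(is.na(r)))
  zero_cn <- !is.na(cn) & cn == 0L
  hemi <- !is.na(cn) & cn == 1L & !all_missing
  excluded <- all_missing | zero_cn
  if (any(all_missing & !zero_cn)) {
    warning(sum(all_missing & !zero_cn),
            " individual(s) with all site calls missing excluded from phasing")
  }
  # hemizygous rows must not show heterozygous calls
  het_hemi <- hemi & apply(g, 1L, function(r) any(!is.na(r) & r == 1L))
  if (any(het_hemi)) {
    warning(sum(het_hemi),
            " one-copy individual(s) with heterozygous calls excluded from phasing")
    excluded <- excluded | het_hemi
    hemi <- hemi & !het_hemi
  }
  dip <- !excluded & !hemi
  if (!any(dip | hemi)) stop("no phasable individuals in cohort")

  # long vectors of ordered pair resolutions for diploid rows
  pair_list <- lapply(which(dip), function(i) enumerate_pairs(g[i, ]))
  pair_n <- vapply(pair_list, nrow, 0L)
  pair_ind <- rep(seq_along(pair_list), pair_n)  # 1..n_dip
  pa_code <- unlist(lapply(pair_list, function(m) m[, 1L]), use.names = FALSE)
  pb_code <- unlist(lapply(pair_list, function(m) m[, 2L]), use.names = FALSE)

  hemi_list <- lapply(which(hemi), function(i) enumerate_hemi(g[i, ]))
  hemi_n <- vapply(hemi_list, length, 0L)
  hemi_ind <- rep(seq_along(hemi_list), hemi_n)
  hh_code <- unlist(hemi_list, use.names = FALSE)

  hap_codes <- sort(unique(c(pa_code, pb_code, hh_code)))
  K <- length(hap_codes)
  pa <- match(pa_code, hap_codes)
  pb <- match(pb_code, hap_codes)
  hh <- match(hh_code, hap_codes)
  n_dip <- sum(dip)
  n_hemi <- sum(hemi)
  n_chrom <- 2L * n_dip + n_hemi

  group_sum <- function(w, idx, ngrp) {
    out <- numeric(ngrp)
    s <- rowsum(w, idx)
    out[as.integer(rownames(s))] <- s
    out
  }

  run_em <- function(f0) {
    f <- f0 / sum(f0)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- f[pa] * f[pb]
      tot <- group_sum(w, pair_ind, n_dip)
      ll <- sum(log(tot))
      if (n_hemi > 0L) {
        hw <- f[hh]
        htot <- group_sum(hw, hemi_ind, n_hemi)
        ll <- ll + sum(log(htot))
      }
      ll_trace <- c(ll_trace, ll)
      cnt <- numeric(K)
      wn <- w / tot[pair_ind]
      cnt <- group_sum(c(wn, wn), c(pa, pb), K)
      if (n_hemi > 0L) {
        hwn <- hw / htot[hemi_ind]
        cnt <- cnt + group_sum(hwn, hh, K)
      }
      f_new <- cnt / n_chrom
      if (is.finite(ll) && ll - ll_old < tol && it > 1L) {
        converged <- TRUE
        f <- f_new
        break
      }
      ll_old <- ll
      f <- f_new
    }
    list(f = f, ll = ll_trace[length(ll_trace)], trace = ll_trace,
         converged = converged, n_iter = length(ll_trace))
  }

  # allele-frequency-product initialization
  p_site <- colMeans(g[dip | hemi, , drop = FALSE], na.rm = TRUE) / 2
  p_site[is.nan(p_site)] <- 0.5
  bits <- t(vapply(hap_codes, function(cd) {
    as.integer(intToBits(cd))[PANEL_SIZE:1]
  }, integer(PANEL_SIZE)))
  f_prod <- apply(bits, 1L, function(b) prod(ifelse(b == 1L, p_site, 1 - p_site)))
  f_prod <- pmax(f_prod, 1e-10)

  inits <- list(f_prod)
  if (n_restarts > 0L) {
    old_seed <- local_rng_seed(seed)
    on.exit(restore_rng_seed(old_seed), add = TRUE)
    for (r in seq_len(n_restarts)) {
      inits[[r + 1L]] <- stats::rexp(K)
    }
  }
  fits <- lapply(inits, run_em)
  best <- fits[[which.max(vapply(fits, `[[`, 0, "ll"))]]
  f <- best$f

  # per-individual best unordered resolution under the final frequencies
  best_rows <- which(dip | hemi)
  hap_a <- rep(NA_integer_, n)
  hap_b <- rep(NA_integer_, n)
  post <- rep(NA_real_, n)
  ambig <- rep(NA, n)
  w <- f[pa] * f[pb]
  tot <- group_sum(w, pair_ind, n_dip)
  dip_rows <- which(dip)
  for (k in seq_len(n_dip)) {
    sel <- which(pair_ind == k)
    lo <- pmin(pa_code[sel], pb_code[sel])
    hi <- pmax(pa_code[sel], pb_code[sel])
    key <- paste(lo, hi)
    pk <- group_sum_by_key(w[sel], key)
    pk$w <- pk$w / tot[k]
    ord <- order(-pk$w, pk$lo, pk$hi)
    pk <- pk[ord, , drop = FALSE]
    i <- dip_rows[k]
    hap_a[i] <- pk$lo[1L]
    hap_b[i] <- pk$hi[1L]
    post[i] <- pk$w[1L]
    ambig[i] <- nrow(pk) > 1L && (pk$w[1L] - pk$w[2L]) < 1e-9
  }
  hemi_rows <- which(hemi)
  if (n_hemi > 0L) {
    hw <- f[hh]
    htot <- group_sum(hw, hemi_ind, n_hemi)
    for (k in seq_len(n_hemi)) {
      sel <- which(hemi_ind == k)
      ord <- order(-hw[sel], hh_code[sel])
      i <- hemi_rows[k]
      hap_a[i] <- hh_code[sel][ord[1L]]
      post[i] <- hw[sel][ord[1L]] / htot[k]
      ambig[i] <- length(sel) > 1L &&
        (hw[sel][ord[1L]] - hw[sel][ord[2L]]) < 1e-9
    }
  }

  freqs <- tibble(
    code = hap_codes,
    states = code_to_string(hap_codes, defs),
    star = match_codes(hap_codes, defs),
    freq = f
  )
  freqs <- freqs[order(-freqs$freq, freqs$code), ]

  best_pairs <- tibble(
    row = seq_len(n),
    id = ids,
    hap_a = hap_a,
    hap_b = hap_b,
    star_a = match_codes(hap_a, defs),
    star_b = match_codes(hap_b, defs),
    posterior = post,
    phase_ambiguous = ambig,
    n_copies_phased = ifelse(excluded, 0L, ifelse(hemi, 1L, 2L))
  )

  structure(list(
    frequencies = freqs,
    best_pairs = best_pairs,
    log_likelihood_trace = best$trace,
    n_iterations = best$n_iter,
    converged = best$converged,
    n_chromosomes = n_chrom
  ), class = "cyp_phasing")
}

group_sum_by_key <- function(w, key) {
  s <- rowsum(w, key)
  parts <- strsplit(rownames(s), " ", fixed = TRUE)
  data.frame(
    lo = as.integer(vapply(parts, `[[`, "", 1L)),
    hi = as.integer(vapply(parts, `[[`, "", 2L)),
    w = as.numeric(s)
  )
}

#' @export
print.cyp_phasing <- function(x, ...) {
  cat("EM phasing:", nrow(x$frequencies), "haplotypes,",
      x$n_chromosomes, "chromosomes\n")
  cat("  iterations:", x$n_iterations,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  log-likelihood:",
      format(x$log_likelihood_trace[length(x$log_likelihood_trace)]), "\n")
  print(utils::head(x$frequencies, 10L))
  invisible(x)
}

#' Posterior over diplotype resolutions for one genotype
#'
#' Ranks every unordered haplotype pair compatible with an unphased genotype
#' by its Hardy-Weinberg posterior probability under a fixed
#' haplotype-frequency vector: \eqn{2 f_i f_j} for heterozygous pairs and
#' \eqn{f_i^2} for homozygous ones, renormalized over the compatible set. A
#' genotype incompatible with every positive-frequency haplotype falls back
#' to a floor pseudo-frequency so that ranking degrades to uniform over the
#' compatible pairs instead of dividing by zero.
#'
#' @param genotype Integer vector of 11 per-site codes (0/1/2/NA).
#' @param freqs Either a \code{cyp_phasing} object or a numeric vector of
#'   frequencies named by haplotype bit code.
#' @param floor Pseudo-frequency applied during ranking only.
#' @return Tibble \code{hap_a}, \code{hap_b}, \code{prob}, sorted by
#'   decreasing probability (ties broken lexicographically).
#' @export
phase_posterior <- function(genotype, freqs, floor = 1e-12) {
  if (inherits(freqs, "cyp_phasing")) {
    fr <- freqs$frequencies
    fv <- stats::setNames(fr$freq, fr$code)
  } else {
    fv <- freqs
  }
  if (abs(sum(fv) - 1) > 1e-6) stop("frequencies must be normalized")
  pairs <- enumerate_pairs(genotype)
  lo <- pmin(pairs[, 1L], pairs[, 2L])
  hi <- pmax(pairs[, 1L], pairs[, 2L])
  key <- !duplicated(paste(lo, hi))
  lo <- lo[key]
  hi <- hi[key]
  f_of <- function(code) {
    x <- fv[as.character(code)]
    x[is.na(x)] <- 0
    unname(x)
  }
  fa <- f_of(lo)
  fb <- f_of(hi)
  p <- ifelse(lo == hi, fa * fb, 2 * fa * fb)
  if (sum(p) <= 0) {
    # the record is incompatible with every positive-frequency haplotype:
    # every resolution's floored weight is the same order, i.e. uniform
    p <- rep(max(floor, .Machine$double.xmin), length(p))
  }
  p <- unname(p / sum(p))
  out <- tibble(hap_a = unname(lo), hap_b = unname(hi), prob = p)
  out[order(-out$prob, out$hap_a, out$hap_b), ]
}

# seed handling: set the RNG reproducibly and restore the caller's state
local_rng_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
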