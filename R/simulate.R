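# Synthetic admixed-cohort generator. Individuals draw a per-region
# Dirichlet ancestry vector over three ancestral components; each of their
# two gene-copy slots draws an ancestral origin and then a star allele from
# that component's haplotype-frequency profile. Linkage within a haplotype
# is perfect: haplotypes are drawn as whole star alleles, never recombined.

REGIONS <- c("North", "Northeast", "Southeast", "South")
ANCESTRIES <- c("Amerindian", "African", "European")

#' Default ancestral haplotype-frequency profiles
#'
#' Star-allele frequency profiles for the three ancestral components of an
#' admixed American population. The numbers are package defaults chosen to
#' reproduce the qualitative contrasts seen in continental surveys — the
#' no-function *4 enriched in Europeans, the reduced-function *17 and *29
#' essentially African, *10 mildly East-Asian/African, high *1 in
#' Amerindians — and make no claim of literature accuracy; edit the
#' returned list to change the scenario.
#'
#' @return Named list (\code{European}, \code{African}, \code{Amerindian})
#'   of named frequency vectors over base star-allele labels (including
#'   the whole-gene deletion *5), each summing to 1.
#' @export
default_ancestral_profiles <- function() {
  list(
    European = c("*1" = 0.34, "*2" = 0.26, "*4" = 0.17, "*41" = 0.07,
                 "*35" = 0.05, "*5" = 0.03, "*9" = 0.02, "*10" = 0.02,
                 "*39" = 0.02, "*17" = 0.01, "*29" = 0.01),
    African = c("*1" = 0.33, "*2" = 0.19, "*17" = 0.17, "*29" = 0.10,
                "*5" = 0.06, "*10" = 0.04, "*41" = 0.03, "*4" = 0.03,
                "*39" = 0.02, "*35" = 0.02, "*34" = 0.01),
    Amerindian = c("*1" = 0.58, "*2" = 0.24, "*4" = 0.05, "*41" = 0.05,
                   "*10" = 0.03, "*35" = 0.03, "*5" = 0.02)
  )
}

#' Build a simulation configuration
#'
#' @param n_per_region Named integer vector of sample sizes per region.
#' @param dirichlet Matrix of Dirichlet concentration parameters, one row
#'   per region, columns Amerindian/African/European. Row means (after
#'   normalization) set the expected regional ancestry; the total
#'   concentration sets the spread.
#' @param dup_prob Probability that a non-deleted haplotype carries a
#'   duplication event.
#' @param dup_mult_probs Named probability vector over duplication
#'   multipliers (total copies carried by the duplicated slot).
#' @param missing_rate Per-site, per-individual probability that both
#'   genotype calls are missing.
#' @param rq_sd Standard deviation of the noise on the emitted
#'   relative-quantification value (true copy number / 2).
#' @param seed Integer seed.
#' @return List of class \code{cyp_sim_config}.
#' @export
sim_config <- function(n_per_region = c(North = 255, Northeast = 255,
                                        Southeast = 255, South = 255),
                       dirichlet = NULL,
                       dup_prob = 0.044,
                       dup_mult_probs = c("2" = 0.80, "3" = 0.15,
                                          "4" = 0.04, "5" = 0.01),
                       missing_rate = 0.005,
                       rq_sd = 0.04,
                       seed = 1L) {
  if (is.null(dirichlet)) {
    dirichlet <- 7 * rbind(
      North = c(0.20, 0.22, 0.58),
      Northeast = c(0.09, 0.33, 0.58),
      Southeast = c(0.10, 0.28, 0.62),
      South = c(0.07, 0.17, 0.76)
    )
    colnames(dirichlet) <- ANCESTRIES
    dirichlet <- dirichlet[names(n_per_region)[names(n_per_region) %in%
                                                 rownames(dirichlet)], ,
                           drop = FALSE]
    if (nrow(dirichlet) != length(n_per_region)) {
      stop("provide a `dirichlet` matrix when using non-default region names")
    }
  }
  stopifnot(all(n_per_region >= 0), all(dirichlet > 0),
            dup_prob >= 0, dup_prob <= 1,
            abs(sum(dup_mult_probs) - 1) < 1e-9,
            missing_rate >= 0, missing_rate <= 1, rq_sd >= 0)
  structure(list(
    n_per_region = n_per_region,
    dirichlet = dirichlet,
    dup_prob = dup_prob,
    dup_mult_probs = dup_mult_probs,
    missing_rate = missing_rate,
    rq_sd = rq_sd,
    seed = as.integer(seed)
  ), class = "cyp_sim_config")
}

#' The default Brazilian-like scenario
#'
#' A four-region, 1020-individual scenario with the regional admixture
#' gradients of an admixed tri-ancestral population (European majority,
#' African contribution highest in the Northeast, Amerindian highest in
#' the North), a duplication-carrier rate near 8 percent, low genotype
#' missingness and mild copy-number assay noise.
#'
#' @param seed Integer seed.
#' @return List with \code{config} (a \code{cyp_sim_config}) and
#'   \code{profiles} (ancestral haplotype-frequency profiles).
#' @export
brazil_like_preset <- function(seed = 1L) {
  list(config = sim_config(seed = seed),
       profiles = default_ancestral_profiles())
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

# crude self-reported color from the ancestry vector, for stratified tables
color_from_ancestry <- function(afr) {
  score <- afr + stats::rnorm(length(afr), sd = 0.1)
  ifelse(score > 0.45, "Black", ifelse(score > 0.22, "Brown", "White"))
}

#' Simulate an admixed cohort with ground truth
#'
#' Generates a cohort in the package's cohort-file layout together with
#' the hidden truth for every pipeline stage. Per individual: ancestry is
#' drawn from the region's Dirichlet; each of two gene-copy slots draws an
#' ancestral origin from the ancestry vector and then a star allele from
#' that component's profile; non-deleted slots acquire a duplication
#' multiplier with probability \code{dup_prob}; the true copy number is
#' the sum of slot copies (*5 contributes none, capped at 6); the emitted
#' relative quantification is true CN / 2 plus normal noise; unphased
#' diploid site calls are the union of the slot haplotypes' states, with
#' per-site missingness.
#'
#' @param config A \code{cyp_sim_config}.
#' @param profiles Ancestral profiles
#'   (\code{\link{default_ancestral_profiles}}).
#' @param defs Allele definitions.
#' @return List of class \code{cyp_simulation}: \code{cohort} (cohort
#'   tibble), \code{truth} (tibble with true slot labels, copy number and
#'   phenotype), \code{config}.
#' @export
simulate_cohort <- function(config = sim_config(),
                            profiles = default_ancestral_profiles(),
                            defs = load_allele_definitions()) {
  for (p in profiles) {
    if (abs(sum(p) - 1) > 1e-9) stop("profile frequencies must sum to 1")
    unknown <- setdiff(names(p), defs$alleles$name)
    if (length(unknown)) stop("profile uses unknown allele label(s): ",
                              paste(unknown, collapse = ", "))
  }
  if (!all(ANCESTRIES %in% names(profiles))) {
    stop("profiles must be named ", paste(ANCESTRIES, collapse = ", "))
  }
  old_seed <- local_rng_seed(config$seed)
  on.exit(restore_rng_seed(old_seed), add = TRUE)

  n_total <- sum(config$n_per_region)
  region <- rep(names(config$n_per_region), config$n_per_region)
  id <- sprintf("ind%04d", seq_len(n_total))

  anc <- t(vapply(region, function(rg) {
    rdirichlet1(config$dirichlet[rg, ])
  }, numeric(3)))
  colnames(anc) <- ANCESTRIES

  mults <- as.integer(names(config$dup_mult_probs))
  slot_allele <- matrix("", n_total, 2L)
  slot_mult <- matrix(1L, n_total, 2L)
  for (i in seq_len(n_total)) {
    for (s in 1:2) {
      origin <- sample(ANCESTRIES, 1L, prob = anc[i, ])
      prof <- profiles[[origin]]
      al <- sample(names(prof), 1L, prob = prof)
      slot_allele[i, s] <- al
      if (al != "*5" && stats::runif(1) < config$dup_prob) {
        slot_mult[i, s] <- if (length(mults) == 1L) mults else
          sample(mults, 1L, prob = config$dup_mult_probs)
      }
    }
    # cap total copies at the assembler's supported maximum
    repeat {
      copies <- ifelse(slot_allele[i, ] == "*5", 0L, slot_mult[i, ])
      if (sum(copies) <= CN_MAX) break
      s_big <- which.max(slot_mult[i, ])
      slot_mult[i, s_big] <- slot_mult[i, s_big] - 1L
    }
  }
  copies <- ifelse(slot_allele == "*5", 0L, slot_mult)
  true_cn <- as.integer(rowSums(copies))

  rq <- true_cn / 2 + stats::rnorm(n_total, sd = config$rq_sd)
  rq <- pmax(rq, 0.01)

  # unphased diploid site calls from the (up to two) present haplotypes
  al <- defs$alleles
  state_of <- function(label) {
    i <- match(label, al$name)
    al$states[[i]]
  }
  calls_1 <- matrix(".", n_total, PANEL_SIZE)
  calls_2 <- matrix(".", n_total, PANEL_SIZE)
  for (i in seq_len(n_total)) {
    present <- slot_allele[i, slot_allele[i, ] != "*5"]
    if (length(present) == 0L) next  # homozygous deletion: nothing amplifies
    s1 <- state_of(present[1L])
    s2 <- if (length(present) >= 2L) state_of(present[2L]) else s1
    calls_1[i, ] <- s1
    calls_2[i, ] <- s2
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n_total * PANEL_SIZE) < config$missing_rate,
                   n_total, PANEL_SIZE)
    calls_1[miss] <- "."
    calls_2[miss] <- "."
  }

  color <- color_from_ancestry(anc[, "African"])

  cohort <- tibble(id = id, region = unname(region),
                   color = unname(color),
                   anc_amerindian = unname(anc[, "Amerindian"]),
                   anc_african = unname(anc[, "African"]),
                   anc_european = unname(anc[, "European"]))
  for (j in seq_len(PANEL_SIZE)) {
    tok <- site_column_token(PANEL_LABELS[j])
    cohort[[paste0("g_", tok, "_1")]] <- ifelse(calls_1[, j] == ".",
                                                NA_character_, calls_1[, j])
    cohort[[paste0("g_", tok, "_2")]] <- ifelse(calls_2[, j] == ".",
                                                NA_character_, calls_2[, j])
  }
  cohort$rq <- rq
  class(cohort) <- c("cyp_cohort", class(cohort))

  # truth: the generating diplotype (duplications attributed, so never
  # ambiguous) and its phenotype
  true_label <- matrix("", n_total, 2L)
  for (s in 1:2) {
    true_label[, s] <- ifelse(
      slot_mult[, s] > 1L & slot_allele[, s] != "*5",
      paste0(slot_allele[, s], "x", slot_mult[, s]),
      slot_allele[, s])
  }
  truth_calls <- tibble(
    individual_id = id,
    allele_a = true_label[, 1L],
    allele_b = true_label[, 2L],
    total_copy_number = true_cn,
    duplication_ambiguous = FALSE,
    unassigned_copies = 0L,
    blocked = FALSE
  )
  truth_pheno <- predict_phenotype(truth_calls, defs)
  truth <- truth_calls
  truth$true_phenotype <- as.character(truth_pheno$phenotype)
  truth$active_copies <- truth_pheno$active_copies

  structure(list(cohort = cohort, truth = truth, config = config),
            class = "cyp_simulation")
}
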