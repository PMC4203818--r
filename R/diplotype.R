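# Copy-number calling from relative quantification, and assembly of
# star-allele diplotypes from phased haplotypes plus copy number.

CN_MAX <- 6L  # largest copy number the assembler accepts

#' Call integer gene copy number from relative quantification
#'
#' Converts a relative-quantification value (target vs a two-copy
#' calibrator) into an integer copy-number call with a confidence and a
#' Z score, emulating the acceptance thresholds used with TaqMan
#' copy-number assays: a call passes when confidence exceeds 0.95 and the
#' Z score is below 1.75.
#'
#' The estimated dosage is \code{2 * rq}. The integer call is the nearest
#' integer (ties to even); the Z score is the distance of the dosage from
#' that integer in units of \code{replicate_sd}; the confidence is the
#' posterior probability of the called integer under a normal error model
#' with standard deviation \code{replicate_sd} and a flat prior over
#' integer copy numbers.
#'
#' @param rq Positive numeric vector of relative-quantification values.
#' @param replicate_sd Replicate standard deviation of the dosage estimate.
#' @return Tibble with \code{rq}, \code{cn_integer}, \code{confidence},
#'   \code{z_score}, \code{pass_flag}.
#' @export
call_copy_number <- function(rq, replicate_sd = 0.1) {
  if (any(is.na(rq)) || any(rq <= 0)) {
    stop("relative quantification values must be positive and non-missing")
  }
  if (replicate_sd <= 0) stop("replicate_sd must be positive")
  x <- 2 * rq
  cn <- as.integer(round(x))
  z <- abs(x - cn) / replicate_sd
  dens <- vapply(0:(CN_MAX + 4L), function(k) {
    stats::dnorm(x - k, sd = replicate_sd)
  }, numeric(length(x)))
  if (length(x) == 1L) dens <- matrix(dens, nrow = 1L)
  conf <- dens[cbind(seq_along(x), cn + 1L)] / rowSums(dens)
  tibble(
    rq = rq,
    cn_integer = cn,
    confidence = conf,
    z_score = z,
    pass_flag = conf > 0.95 & z < 1.75
  )
}

#' Assemble a star-allele diplotype from phased labels and copy number
#'
#' Combines the two phased star-allele labels of an individual with the
#' integer gene copy number into a diplotype call, introducing the
#' whole-gene deletion (*5) and xN duplication labels:
#' \itemize{
#'   \item \code{cn = 2}: labels unchanged.
#'   \item \code{cn = 1}: the single observed haplotype fills slot one and
#'     the second slot is *5.
#'   \item \code{cn = 0}: *5/*5.
#'   \item \code{cn = k >= 3} with both slots sharing one base allele: one
#'     slot becomes base x(k-1); unambiguous.
#'   \item \code{cn = k >= 3} with differing (or unassignable) base
#'     alleles: the duplication cannot be attributed to either haplotype;
#'     the slots keep their base labels, \code{duplication_ambiguous} is
#'     set, and the k-2 extra copies are carried as
#'     \code{unassigned_copies}.
#' }
#' A missing copy number (e.g. a failed copy-number call) produces a
#' phenotype-blocking call (\code{blocked = TRUE}).
#'
#' @param allele_a,allele_b Star labels from \code{\link{match_haplotype}}
#'   (\code{allele_b} may be NA for one-copy individuals).
#' @param cn Integer copy number in [0, 6], or NA.
#' @param individual_id Optional identifier carried through.
#' @return One-row tibble: \code{individual_id}, \code{allele_a},
#'   \code{allele_b}, \code{total_copy_number},
#'   \code{duplication_ambiguous}, \code{unassigned_copies},
#'   \code{blocked}.
#' @export
assemble_diplotype <- function(allele_a, allele_b = NA_character_, cn,
                               individual_id = NA_character_) {
  row <- function(a, b, tot, amb = FALSE, unassigned = 0L, blocked = FALSE) {
    tibble(individual_id = individual_id, allele_a = a, allele_b = b,
           total_copy_number = tot, duplication_ambiguous = amb,
           unassigned_copies = as.integer(unassigned), blocked = blocked)
  }
  if (is.na(cn)) {
    return(row(allele_a, allele_b, NA_integer_, blocked = TRUE))
  }
  cn <- as.integer(cn)
  if (cn < 0L || cn > CN_MAX) {
    stop("copy number ", cn, " outside the supported range [0, ", CN_MAX, "]")
  }
  if (cn == 0L) return(row("*5", "*5", 0L))
  if (cn == 1L) {
    if (is.na(allele_a)) stop("one-copy individual needs one phased allele label")
    return(row(allele_a, "*5", 1L))
  }
  if (is.na(allele_a) || is.na(allele_b)) {
    stop("two phased allele labels are required for copy number >= 2")
  }
  if (allele_a == "*5" || allele_b == "*5") {
    stop("*5 is assigned from copy number, not from phased labels")
  }
  if (cn == 2L) return(row(allele_a, allele_b, 2L))
  # cn >= 3: a duplication must be attributed
  if (allele_a == allele_b && allele_a != "Others") {
    return(row(paste0(allele_a, "x", cn - 1L), allele_b, cn))
  }
  row(allele_a, allele_b, cn, amb = TRUE, unassigned = cn - 2L)
}

#' Assemble diplotypes for a phased cohort
#'
#' Vectorized wrapper joining a phasing result with copy-number calls.
#' One-copy individuals use their single phased haplotype; zero-copy
#' individuals are *5/*5; failed or missing copy-number calls yield
#' phenotype-blocking diplotypes.
#'
#' @param phasing A \code{cyp_phasing} object.
#' @param cn Integer copy-number vector (NA where the call failed), in
#'   cohort row order.
#' @param defs Allele definitions.
#' @return Tibble of diplotype calls, one row per individual.
#' @export
diplotype_cohort <- function(phasing, cn, defs) {
  bp <- phasing$best_pairs
  n <- nrow(bp)
  cn <- rep_len(as.integer(cn), n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- bp$star_a[i]
    b <- bp$star_b[i]
    ci <- cn[i]
    if (!is.na(ci) && ci == 0L) {
      out[[i]] <- assemble_diplotype(NA, NA, 0L, bp$id[i])
    } else if (!is.na(ci) && ci == 1L) {
      out[[i]] <- assemble_diplotype(a, NA, 1L, bp$id[i])
    } else if (is.na(a) || (is.na(b) && (is.na(ci) || ci >= 2L))) {
      # unphasable individual: blocked
      out[[i]] <- assemble_diplotype(NA_character_, NA_character_, NA,
                                     bp$id[i])
    } else {
      out[[i]] <- assemble_diplotype(a, b, ci, bp$id[i])
    }
  }
  dplyr::bind_rows(out)
}

# copies contributed by one slot label (*5 = 0, xN = N)
slot_copies <- function(label) {
  ifelse(is.na(label), 0L,
         ifelse(label == "*5", 0L, label_multiplier(label)))
}
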