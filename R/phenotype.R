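# Predicted metabolizer phenotype from the diplotype, under dominance
# rules: the phenotype is set by the most efficient haplotype carried.

#' Predict metabolizer phenotypes from diplotype calls
#'
#' Classifies each individual as poor (PM), intermediate (IM), extensive
#' (EM) or ultrarapid (UM) metabolizer, or as not determined (ND):
#' \enumerate{
#'   \item any unassignable ("Others") or undetermined-activity allele, an
#'     unattributable duplication, or a blocked call gives ND;
#'   \item \code{active_copies} is the number of gene copies carried on
#'     normal-function alleles (an xN slot contributes N); three or more
#'     active copies give UM;
#'   \item otherwise at least one normal-function allele gives EM;
#'   \item otherwise two inactive alleles give PM;
#'   \item otherwise (two reduced-activity alleles, or one reduced and one
#'     inactive) IM.
#' }
#'
#' @param calls Diplotype-call tibble from \code{\link{diplotype_cohort}}
#'   or \code{\link{assemble_diplotype}}.
#' @param defs Allele definitions.
#' @return Tibble \code{individual_id}, \code{phenotype},
#'   \code{active_copies} (NA for ND calls).
#' @export
predict_phenotype <- function(calls, defs) {
  n <- nrow(calls)
  pheno <- character(n)
  active <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (isTRUE(calls$blocked[i]) || isTRUE(calls$duplication_ambiguous[i])) {
      pheno[i] <- "ND"
      next
    }
    slots <- c(calls$allele_a[i], calls$allele_b[i])
    if (anyNA(slots)) stop("unresolved diplotype slots for individual ",
                           calls$individual_id[i])
    act <- classify_activity(slots, defs)
    base_act <- classify_activity(label_base(slots), defs)
    if (any(act == "ND") || any(slots == "Others")) {
      pheno[i] <- "ND"
      next
    }
    copies <- slot_copies(slots)
    a <- sum(copies[base_act == "normal"])
    active[i] <- as.integer(a)
    pheno[i] <- if (a >= 3L) "UM"
      else if (any(base_act == "normal")) "EM"
      else if (all(base_act == "none")) "PM"
      else "IM"
  }
  tibble(individual_id = calls$individual_id,
         phenotype = factor(pheno, levels = PHENOTYPE_LEVELS),
         active_copies = active)
}

#' Phenotype frequency table by stratum
#'
#' Per-stratum percentages of the five phenotype classes, with the number
#' of individuals per stratum. Strata are any columns of \code{data}
#' (e.g. region, skin-color label, or both).
#'
#' @param phenotypes Tibble from \code{\link{predict_phenotype}}.
#' @param data Optional tibble aligned with \code{phenotypes} carrying the
#'   stratum columns.
#' @param by Character vector of stratum column names in \code{data};
#'   \code{NULL} for a single overall stratum.
#' @return Tibble with the stratum columns, \code{phenotype}, \code{n},
#'   \code{pct}, and per-stratum totals in column \code{n_stratum}.
#' @export
phenotype_table <- function(phenotypes, data = NULL, by = NULL) {
  df <- tibble(phenotype = phenotypes$phenotype)
  if (!is.null(by)) {
    if (is.null(data)) stop("`data` is required when `by` is given")
    for (v in by) df[[v]] <- data[[v]]
  }
  grouped <- dplyr::count(df, dplyr::across(dplyr::all_of(c(by, "phenotype"))),
                          .drop = FALSE, name = "n")
  if (!is.null(by)) {
    totals <- dplyr::count(df, dplyr::across(dplyr::all_of(by)), name = "n_stratum")
    grouped <- dplyr::inner_join(grouped, totals, by = by)
  } else {
    grouped$n_stratum <- nrow(df)
  }
  empty <- grouped$n_stratum == 0L
  if (any(empty)) {
    warning("omitting empty stratum/strata from phenotype table")
    grouped <- grouped[!empty, , drop = FALSE]
  }
  grouped$pct <- 100 * grouped$n / grouped$n_stratum
  as_tibble(grouped)
}
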