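# End-to-end pipeline: phasing -> copy-number calling -> diplotype
# assembly -> phenotype prediction -> population statistics.

#' Run the full analysis pipeline on a cohort
#'
#' Executes every stage in order and returns a report bundle: haplotype
#' frequencies, per-individual diplotypes and phenotypes, gene-counting
#' allele-frequency tables (total and per region), activity-class and
#' phenotype tables, region-by-allele and phenotype association tests,
#' AMOVA by region and by color, pairwise F_ST matrices, and the
#' rank-based ancestry-phenotype battery. Deterministic given
#' \code{seed}. When \code{out_dir} is given, each table is also written
#' as a TSV carrying provenance metadata (package version, seed,
#' configuration hash) in '#'-prefixed header lines.
#'
#' @param cohort Cohort tibble (\code{\link{read_cohort}} or the
#'   \code{cohort} element of \code{\link{simulate_cohort}}).
#' @param defs Allele definitions.
#' @param replicate_sd Replicate standard deviation used by the
#'   copy-number caller when only raw \code{rq} values are present.
#' @param n_permutations AMOVA permutation count.
#' @param n_bootstrap F_ST bootstrap count.
#' @param pool_rare_below Pooling threshold for rare alleles in the
#'   region-by-allele contingency test.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Optional output directory for the TSV bundle.
#' @return List of class \code{cyp_bundle}.
#' @export
run_pipeline <- function(cohort, defs = load_allele_definitions(),
                         replicate_sd = 0.1,
                         n_permutations = 10000L,
                         n_bootstrap = 3000L,
                         pool_rare_below = 5L,
                         seed = 1L,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # copy number first (phasing needs to know one-copy individuals)
  cn <- stage("copy-number", {
    if ("cn" %in% names(cohort) && any(!is.na(cohort$cn))) {
      as.integer(cohort$cn)
    } else if ("rq" %in% names(cohort)) {
      cc <- call_copy_number(cohort$rq, replicate_sd = replicate_sd)
      ifelse(cc$pass_flag, cc$cn_integer, NA_integer_)
    } else {
      rep(NA_integer_, nrow(cohort))
    }
  })

  phasing <- stage("phasing", em_phase(cohort, defs, cn = cn, seed = seed))
  diplotypes <- stage("diplotyping", diplotype_cohort(phasing, cn, defs))
  phenotypes <- stage("phenotyping", predict_phenotype(diplotypes, defs))

  freq_total <- stage("frequencies", allele_frequencies(diplotypes))
  freq_region <- stage("frequencies",
                       allele_frequencies(diplotypes, cohort, by = "region"))
  activity_region <- stage("activity",
                           activity_class_table(diplotypes, defs, cohort,
                                                by = "region"))
  pheno_region_color <- stage("phenotype-table",
                              phenotype_table(phenotypes, cohort,
                                              by = c("region", "color")))

  # region-by-allele contingency test with rare labels pooled
  chi2_region <- stage("chi-squared", {
    slots <- diplotype_slots(diplotypes, cohort, by = "region")
    slots <- slots[!is.na(slots$allele), ]
    slots$allele <- pool_rare_alleles(slots$allele, pool_rare_below)
    chi2_independence(table(slots$allele, slots$region))
  })
  gtest_pheno_region <- stage("association", {
    keep <- !is.na(phenotypes$phenotype)
    g_test_independence(table(as.character(phenotypes$phenotype)[keep],
                              cohort$region[keep]))
  })
  gtest_pheno_color <- stage("association", {
    keep <- !is.na(phenotypes$phenotype)
    g_test_independence(table(as.character(phenotypes$phenotype)[keep],
                              cohort$color[keep]))
  })

  amova_region <- stage("amova", amova(
    cbind(diplotypes$allele_a, diplotypes$allele_b), cohort$region,
    n_permutations = n_permutations, seed = seed))
  amova_color <- stage("amova", amova(
    cbind(diplotypes$allele_a, diplotypes$allele_b), cohort$color,
    n_permutations = n_permutations, seed = seed + 1L))

  fst_region <- stage("fst", fst_matrix(diplotypes, cohort, "region",
                                        n_bootstrap = n_bootstrap,
                                        seed = seed + 2L))
  fst_color <- stage("fst", fst_matrix(diplotypes, cohort, "color",
                                       n_bootstrap = n_bootstrap,
                                       seed = seed + 100L))

  ancestry <- if (all(c("anc_amerindian", "anc_african", "anc_european")
                      %in% names(cohort)) &&
                  any(!is.na(cohort$anc_african))) {
    stage("ancestry-association", ancestry_association(cohort, phenotypes))
  } else NULL

  provenance <- list(
    package_version = as.character(utils::packageVersion("cyp2d6star")),
    cohort_format_version = COHORT_FORMAT_VERSION,
    seed = seed,
    n_individuals = nrow(cohort),
    config_hash = rlang::hash(list(replicate_sd, n_permutations,
                                   n_bootstrap, pool_rare_below, seed))
  )

  bundle <- structure(list(
    phasing = phasing,
    copy_number = cn,
    diplotypes = diplotypes,
    phenotypes = phenotypes,
    allele_freq_total = freq_total,
    allele_freq_by_region = freq_region,
    activity_by_region = activity_region,
    phenotype_by_region_color = pheno_region_color,
    chi2_allele_region = chi2_region,
    gtest_phenotype_region = gtest_pheno_region,
    gtest_phenotype_color = gtest_pheno_color,
    amova_region = amova_region,
    amova_color = amova_color,
    fst_region = fst_region,
    fst_color = fst_color,
    ancestry_tests = ancestry,
    provenance = provenance
  ), class = "cyp_bundle")

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a report bundle to TSV files
#'
#' @param bundle A \code{cyp_bundle}.
#' @param out_dir Output directory (created if absent).
#' @return \code{out_dir}, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pv <- bundle$provenance
  header <- c(
    paste0("# cyp2d6star version=", pv$package_version),
    paste0("# seed=", pv$seed, " config_hash=", pv$config_hash,
           " n_individuals=", pv$n_individuals)
  )
  emit <- function(tbl, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    writeLines(header, path)
    suppressWarnings(
      utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
    invisible(path)
  }
  emit(bundle$phasing$frequencies, "haplotype_frequencies")
  emit(bundle$diplotypes, "diplotypes")
  emit(bundle$phenotypes, "phenotypes")
  emit(bundle$allele_freq_total, "allele_frequencies_total")
  emit(bundle$allele_freq_by_region, "allele_frequencies_by_region")
  emit(bundle$activity_by_region, "activity_classes_by_region")
  emit(bundle$phenotype_by_region_color, "phenotypes_by_region_color")
  amova_tbl <- function(a) tibble(
    sigma_among = a$sigma_among, sigma_within = a$sigma_within,
    pct_among = a$pct_among, pct_within = a$pct_within,
    phi_st = a$phi_st, p_value = a$p_value,
    n_permutations = a$n_permutations)
  emit(amova_tbl(bundle$amova_region), "amova_region")
  emit(amova_tbl(bundle$amova_color), "amova_color")
  emit(bundle$fst_region, "fst_region")
  emit(bundle$fst_color, "fst_color")
  emit(dplyr::bind_rows(bundle$chi2_allele_region,
                        bundle$gtest_phenotype_region,
                        bundle$gtest_phenotype_color), "contingency_tests")
  if (!is.null(bundle$ancestry_tests)) {
    emit(bundle$ancestry_tests$kruskal, "ancestry_kruskal")
    emit(bundle$ancestry_tests$pairwise, "ancestry_pairwise")
  }
  invisible(out_dir)
}

#' @export
print.cyp_bundle <- function(x, ...) {
  cat("CYP2D6 pipeline bundle:", x$provenance$n_individuals,
      "individuals (seed", x$provenance$seed, ")\n")
  ph <- table(x$phenotypes$phenotype)
  cat("  phenotypes:",
      paste(names(ph), ph, sep = "=", collapse = " "), "\n")
  cat(sprintf("  AMOVA by region: Phi_ST = %.5g (p = %.3g)\n",
              x$amova_region$phi_st, x$amova_region$p_value))
  invisible(x)
}
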