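# Cohort-file reading and writing. One row per individual: identifier,
# region, skin-color label, three genomic-ancestry proportions, two state
# columns per panel site (panel order), and a relative-quantification
# and/or integer copy-number column. Missing values are ".".

COHORT_FORMAT_VERSION <- "1"

site_column_token <- function(label) sub("^-", "m", label)

cohort_genotype_columns <- function() {
  toks <- site_column_token(PANEL_LABELS)
  as.vector(rbind(paste0("g_", toks, "_1"), paste0("g_", toks, "_2")))
}

cohort_columns <- function() {
  c("id", "region", "color",
    "anc_amerindian", "anc_african", "anc_european",
    cohort_genotype_columns(), "rq", "cn")
}

#' Write a cohort file
#'
#' Serializes a cohort tibble to the package's tab-delimited cohort
#' dialect (missing values as \code{"."}). Columns absent from the tibble
#' (e.g. \code{cn} when only raw relative quantification is available) are
#' written as missing.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- tibble::as_tibble(cohort)
  for (col in cohort_columns()) {
    if (!col %in% names(out)) out[[col]] <- NA
  }
  out <- out[, cohort_columns()]
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' Read a cohort file
#'
#' Parses and validates a cohort file. Row-level problems (ancestry
#' proportions off the simplex, unknown state characters, non-numeric
#' quantification values) are aggregated and reported together with their
#' line numbers.
#'
#' @param path Path to a cohort TSV.
#' @param ancestry_tol Tolerance on the ancestry-proportion sum.
#' @return A validated cohort tibble of class \code{cyp_cohort}.
#' @export
read_cohort <- function(path, ancestry_tol = 1e-6) {
  raw <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  expected <- cohort_columns()
  if (!identical(names(raw), expected)) {
    stop("malformed cohort header: expected columns ",
         paste(expected, collapse = ", "))
  }
  n <- nrow(raw)
  line <- seq_len(n) + 1L  # file line numbers (header is line 1)
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows)) {
      problems <<- c(problems, paste0("line ", paste(line[rows], collapse = ","),
                                      ": ", msg))
    }
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    note(which(!is.na(raw[[col]]) & is.na(x)), paste0(col, " is not numeric"))
    x
  }
  anc <- cbind(num("anc_amerindian"), num("anc_african"), num("anc_european"))
  has_anc <- rowSums(!is.na(anc)) > 0L
  full_anc <- rowSums(!is.na(anc)) == 3L
  note(which(has_anc & !full_anc), "ancestry proportions must be all present or all missing")
  bad_range <- which(full_anc & (apply(anc, 1L, function(a) any(a < 0 | a > 1))))
  note(bad_range, "ancestry proportion outside [0, 1]")
  bad_sum <- which(full_anc &
                     abs(rowSums(anc) - 1) > ancestry_tol)
  note(setdiff(bad_sum, bad_range), "ancestry proportions do not sum to 1")
  for (col in cohort_genotype_columns()) {
    x <- raw[[col]]
    note(which(!is.na(x) & !(x %in% VALID_STATES)),
         paste0(col, " has a state outside {A,C,G,T,del}"))
  }
  rq <- num("rq")
  note(which(!is.na(rq) & rq <= 0), "rq must be positive")
  cn <- suppressWarnings(as.integer(raw$cn))
  note(which(!is.na(raw$cn) & is.na(cn)), "cn is not an integer")
  if (length(problems)) {
    stop("cohort file validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  }
  out <- raw
  out$anc_amerindian <- anc[, 1L]
  out$anc_african <- anc[, 2L]
  out$anc_european <- anc[, 3L]
  out$rq <- rq
  out$cn <- cn
  class(out) <- c("cyp_cohort", class(out))
  out
}

#' Published survey reference tables
#'
#' Loads the packaged reference tables transcribed from a published
#' 1020-individual Brazilian CYP2D6 survey: per-region allele chromosome
#' counts, per-region copy-number-variation counts (individuals with 3-6
#' gene copies), and the per-region activity-class percentage table with
#' its evaluable chromosome totals. These support worked-example
#' arithmetic (gene-counting frequencies, duplication-carrier rates,
#' activity aggregation, contingency reconstruction) without any
#' individual-level data.
#'
#' @return List of tibbles: \code{allele_counts}, \code{cnv_counts},
#'   \code{activity_pct}.
#' @export
published_survey_tables <- function() {
  rd <- function(f) {
    readr::read_tsv(system.file("extdata", f, package = "cyp2d6star"),
                    show_col_types = FALSE)
  }
  list(
    allele_counts = rd("brazil_survey_allele_counts.tsv"),
    cnv_counts = rd("brazil_survey_cnv_counts.tsv"),
    activity_pct = rd("brazil_survey_activity_pct.tsv")
  )
}
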