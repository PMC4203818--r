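#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Fixed gene-relative positions of the genotyping panel, in panel order.
PANEL_LABELS <- c("-1584", "31", "100", "1023", "1846",
                  "2549", "2615", "2850", "2988", "3183", "4180")
PANEL_SIZE <- length(PANEL_LABELS)

VALID_STATES <- c("A", "C", "G", "T", "del")
ACTIVITY_LEVELS <- c("none", "reduced", "normal", "increased", "ND")
PHENOTYPE_LEVELS <- c("PM", "IM", "EM", "UM", "ND")

#' Panel site labels
#'
#' The eleven gene-relative positions of the CYP2D6 genotyping panel, in the
#' fixed panel order used throughout the package. Position labels are
#' relative to the gene (upstream positions are negative).
#'
#' @return Character vector of length 11.
#' @export
cyp2d6_panel_labels <- function() PANEL_LABELS

#' Load the star-allele definition table
#'
#' Reads an allele-definition TSV describing, for each named star allele, its
#' state at the eleven panel positions, its gene copy multiplier (xN
#' duplication labels) and its enzyme-activity class. The packaged default
#' table covers the thirteen base alleles of the assay panel (including the
#' whole-gene deletion *5, which has no sequence and is called from copy
#' number) plus the duplication alleles observed in the Brazilian survey the
#' panel was designed for.
#'
#' The dialect is: header
#' \code{allele<TAB>-1584<TAB>...<TAB>4180<TAB>multiplier<TAB>activity};
#' states are \code{A}, \code{C}, \code{G}, \code{T} or \code{del}; a row
#' whose states are all \code{-} denotes the whole-gene deletion.
#'
#' @param path Path to a definition TSV; \code{NULL} loads the packaged table.
#' @return An object of class \code{cyp_allele_defs}: a list with elements
#'   \code{sites} (tibble: \code{label}, \code{reference_state},
#'   \code{variant_state}, \code{panel_index}) and \code{alleles} (tibble:
#'   \code{name}, \code{base}, \code{multiplier}, \code{activity},
#'   \code{whole_gene_deletion}, \code{states} list-column, \code{code}).
#' @export
load_allele_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cyp2d6_allele_definitions.tsv",
                        package = "cyp2d6star")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  expected_header <- c("allele", PANEL_LABELS, "multiplier", "activity")
  if (!identical(header, expected_header)) {
    stop("allele-definition table: malformed header at line 1; expected ",
         paste(expected_header, collapse = " | "))
  }
  n_col <- length(expected_header)
  rows <- fields[-1]
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != n_col) {
      stop(sprintf(
        "allele-definition table: line %d has %d columns, expected %d",
        i + 1L, length(rows[[i]]), n_col))
    }
  }
  name <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(name)) {
    stop("allele-definition table: duplicate allele name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  states_mat <- t(vapply(rows, function(r) r[2:(PANEL_SIZE + 1L)],
                         character(PANEL_SIZE)))
  multiplier <- as.integer(vapply(rows, `[[`, "", PANEL_SIZE + 2L))
  activity <- vapply(rows, `[[`, "", PANEL_SIZE + 3L)

  deletion <- apply(states_mat, 1L, function(s) all(s == "-"))
  for (i in which(!deletion)) {
    bad <- !(states_mat[i, ] %in% VALID_STATES)
    if (any(bad)) {
      stop(sprintf(
        "allele-definition table: line %d (%s): invalid state '%s' (must be one of %s)",
        i + 1L, name[i], states_mat[i, which(bad)[1L]],
        paste(VALID_STATES, collapse = ", ")))
    }
  }
  if (any(is.na(multiplier)) || any(multiplier < 1L)) {
    stop("allele-definition table: multiplier must be an integer >= 1")
  }
  if (!all(activity %in% ACTIVITY_LEVELS)) {
    stop("allele-definition table: activity must be one of ",
         paste(ACTIVITY_LEVELS, collapse = ", "))
  }

  base <- sub("x[0-9]+$", "", name)
  if (any(deletion & multiplier != 1L)) {
    stop("allele-definition table: the whole-gene deletion cannot carry a duplication multiplier")
  }

  # Derive per-site reference/variant states: reference is the state of the
  # all-reference allele (*1 by convention, the first multiplier-1 row whose
  # states are shared most widely); every site must be biallelic.
  seq_rows <- which(!deletion & multiplier == 1L)
  ref_row <- seq_rows[match("*1", name[seq_rows])]
  if (is.na(ref_row)) {
    stop("allele-definition table: no *1 (all-reference) definition present")
  }
  reference_state <- states_mat[ref_row, ]
  variant_state <- character(PANEL_SIZE)
  for (j in seq_len(PANEL_SIZE)) {
    obs <- unique(states_mat[!deletion, j])
    alt <- setdiff(obs, reference_state[j])
    if (length(alt) > 1L) {
      stop(sprintf("allele-definition table: site %s is not biallelic (states %s)",
                   PANEL_LABELS[j], paste(obs, collapse = "/")))
    }
    variant_state[j] <- if (length(alt) == 1L) alt else NA_character_
  }
  sites <- tibble(
    label = PANEL_LABELS,
    reference_state = reference_state,
    variant_state = variant_state,
    panel_index = seq_len(PANEL_SIZE) - 1L
  )

  # Bit code per sequence-defined haplotype: site 1 is the most significant
  # bit so that numeric order equals lexicographic order of state vectors.
  code <- rep(NA_integer_, length(name))
  for (i in which(!deletion)) {
    bits <- as.integer(states_mat[i, ] == variant_state)
    code[i] <- sum(bits * 2L^((PANEL_SIZE - 1L):0L))
  }

  base_seq <- which(!deletion & multiplier == 1L)
  if (anyDuplicated(code[base_seq])) {
    dup <- code[base_seq][duplicated(code[base_seq])][1L]
    clash <- name[base_seq][code[base_seq] == dup]
    stop("allele-definition table: base definitions are not pairwise distinct: ",
         paste(clash, collapse = " and "), " share one state vector")
  }

  alleles <- tibble(
    name = name,
    base = base,
    multiplier = multiplier,
    activity = activity,
    whole_gene_deletion = deletion,
    states = lapply(seq_along(name), function(i) {
      if (deletion[i]) NULL else unname(states_mat[i, ])
    }),
    code = code
  )

  structure(list(sites = sites, alleles = alleles),
            class = "cyp_allele_defs")
}

#' @export
print.cyp_allele_defs <- function(x, ...) {
  cat("CYP2D6 allele definitions:", nrow(x$alleles), "alleles over",
      nrow(x$sites), "panel sites\n")
  cat("  base alleles:",
      paste(x$alleles$name[x$alleles$multiplier == 1L], collapse = " "), "\n")
  cat("  duplications:",
      paste(x$alleles$name[x$alleles$multiplier > 1L], collapse = " "), "\n")
  invisible(x)
}

# states (chr vector, panel order) -> integer bit code, or NA if any missing
states_to_code <- function(states, defs) {
  if (length(states) != PANEL_SIZE) {
    stop("haplotype must have exactly ", PANEL_SIZE, " states")
  }
  if (anyNA(states) || any(states == ".")) return(NA_integer_)
  s <- defs$sites
  is_var <- states == s$variant_state
  is_ref <- states == s$reference_state
  if (any(!is_var & !is_ref)) {
    j <- which(!is_var & !is_ref)[1L]
    stop(sprintf("state '%s' at site %s is neither the reference (%s) nor the variant (%s) state",
                 states[j], s$label[j], s$reference_state[j], s$variant_state[j]))
  }
  sum(as.integer(is_var) * 2L^((PANEL_SIZE - 1L):0L))
}

# integer bit code -> chr vector of states
code_to_states <- function(code, defs) {
  bits <- as.integer(intToBits(code))[PANEL_SIZE:1]
  ifelse(bits == 1L, defs$sites$variant_state, defs$sites$reference_state)
}

# compact display string for a haplotype code, e.g. "CGCCGAAC G G G" -> "CGCCGAACGGG"
code_to_string <- function(code, defs) {
  vapply(code, function(cd) paste(code_to_states(cd, defs), collapse = ""),
         character(1))
}

#' Assign a star allele to a fully observed haplotype
#'
#' Implements perfect-match calling: a haplotype is assigned the unique base
#' allele whose defining states equal its own at all eleven panel positions,
#' and is pooled as \code{"Others"} when no definition matches. The
#' whole-gene deletion (*5) has no sequence and is never returned here; it is
#' called from the copy-number assay during diplotype assembly.
#'
#' @param h A character vector of 11 states (panel order), or an integer bit
#'   code as used internally by the phaser.
#' @param defs Allele definitions from \code{\link{load_allele_definitions}}.
#' @return A star-allele label (e.g. \code{"*4"}) or \code{"Others"}.
#' @export
match_haplotype <- function(h, defs) {
  if (is.character(h)) {
    if (anyNA(h) || any(h == ".")) {
      stop("haplotype has missing states; phase or marginalize missing sites before matching")
    }
    h <- states_to_code(h, defs)
  }
  if (is.na(h)) {
    stop("haplotype has missing states; phase or marginalize missing sites before matching")
  }
  al <- defs$alleles
  base <- al$multiplier == 1L & !al$whole_gene_deletion
  hit <- which(base & al$code == h)
  if (length(hit) == 1L) al$name[hit] else "Others"
}

# vectorized over integer codes
match_codes <- function(codes, defs) {
  al <- defs$alleles
  base <- al[al$multiplier == 1L & !al$whole_gene_deletion, ]
  out <- base$name[match(codes, base$code)]
  out[is.na(out) & !is.na(codes)] <- "Others"
  out
}

label_base <- function(label) sub("x[0-9]+$", "", label)

label_multiplier <- function(label) {
  m <- regexpr("x[0-9]+$", label)
  out <- rep(1L, length(label))
  hit <- !is.na(m) & m > 0L
  out[hit] <- as.integer(substring(label[hit], m[hit] + 1L))
  out
}

# Activity of a duplication given its base allele's activity. Matches every
# explicitly listed duplication: normal-function bases gain activity,
# no-function bases stay inactive, reduced-function or undetermined bases
# cannot be extrapolated.
duplication_activity <- function(base_activity) {
  vapply(base_activity, function(a) {
    switch(a,
           normal = "increased",
           none = "none",
           reduced = "ND",
           ND = "ND",
           increased = "increased")
  }, character(1))
}

#' Classify the enzyme activity of a star-allele label
#'
#' Maps an allele label (base, xN duplication, or \code{"Others"}) to its
#' predicted enzyme-activity class. Explicitly defined duplications use their
#' tabulated class; other duplications follow the duplication rule: a
#' duplicated normal-function allele has increased activity, a duplicated
#' no-function allele remains inactive, and duplications of reduced-function
#' or undetermined alleles are not determined (\code{"ND"}).
#' \code{"Others"} (unassignable haplotypes) are \code{"ND"}.
#'
#' @param star Character vector of allele labels.
#' @param defs Allele definitions.
#' @return Character vector over
#'   \code{c("none","reduced","normal","increased","ND")}.
#' @export
classify_activity <- function(star, defs) {
  al <- defs$alleles
  vapply(star, function(s) {
    if (is.na(s)) return(NA_character_)
    if (s == "Others") return("ND")
    i <- match(s, al$name)
    if (!is.na(i)) return(al$activity[i])
    b <- label_base(s)
    m <- label_multiplier(s)
    j <- match(b, al$name)
    if (is.na(j)) stop("unknown allele label: ", s)
    if (m > 1L) duplication_activity(al$activity[j]) else al$activity[j]
  }, character(1), USE.NAMES = FALSE)
}
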