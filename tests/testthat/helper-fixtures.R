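# Shared fixtures: allele definitions loaded once, and builders that turn
# star-allele labels into genotype matrices / diplotype-call tibbles.

DEFS <- load_allele_definitions()

hap_states <- function(label) {
  DEFS$alleles$states[[match(label, DEFS$alleles$name)]]
}

# unphased diploid genotype codes (0/1/2) for an individual carrying two
# star alleles
geno_from_labels <- function(a, b) {
  sa <- hap_states(a)
  sb <- hap_states(b)
  var <- DEFS$sites$variant_state
  as.integer((sa == var) + (sb == var))
}

geno_matrix <- function(pairs) {
  t(vapply(pairs, function(p) geno_from_labels(p[1], p[2]),
           integer(length(cyp2d6_panel_labels()))))
}

# diplotype-call tibble straight from labels (cn = 2 unless stated)
calls_from_labels <- function(a, b, cn = 2L, amb = FALSE, blocked = FALSE,
                              id = NULL) {
  n <- length(a)
  if (is.null(id)) id <- sprintf("t%03d", seq_len(n))
  tibble::tibble(
    individual_id = id, allele_a = a, allele_b = b,
    total_copy_number = rep_len(as.integer(cn), n),
    duplication_ambiguous = rep_len(amb, n),
    unassigned_copies = 0L,
    blocked = rep_len(blocked, n)
  )
}

# small simulated cohort shared by several files
small_sim <- function(n = 40L, seed = 11L, ...) {
  simulate_cohort(sim_config(
    n_per_region = c(North = n, Northeast = n, Southeast = n, South = n),
    seed = seed, ...), defs = DEFS)
}
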