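# cyp2d6star

An R package for CYP2D6 pharmacogenetic analysis of admixed cohorts
genotyped on an eleven-variant panel plus a whole-gene copy-number assay.
It is written for population-pharmacogenetics studies that need to go from
unphased genotypes all the way to cohort statistics: haplotype phasing,
star-allele assignment, copy-number-aware diplotypes (whole-gene deletion
\*5, xN duplications), predicted metabolizer phenotypes (PM/IM/EM/UM), and
the standard population-genetics battery.

## What it computes

* **EM haplotype phasing** — maximum-likelihood haplotype frequencies
  under Hardy–Weinberg random pairing (multinomial EM,
  Excoffier–Slatkin style), marginalizing missing calls; one-copy
  individuals contribute a single chromosome, zero-copy individuals none.
  Per-individual diplotypes are maximum-posterior resolutions weighted
  2·f\_i·f\_j (i≠j) or f\_i².
* **Star-allele calling** — strict perfect matching of phased haplotypes
  against the packaged definition table (13 base alleles, of which \*5 is
  copy-number-called; 7 duplication alleles); unmatched haplotypes pool
  as "Others".
* **Copy number** — integer dosage from relative quantification
  (`cn = round(2·rq)`, ties to even), accepted when confidence > 0.95 and
  Z score < 1.75; deletions and duplications folded into the diplotype,
  with duplications in heterozygous carriers flagged as unattributable.
* **Phenotype** — dominance rules: ≥3 active gene copies → UM; ≥1
  normal-function allele → EM; two no-function alleles → PM; reduced
  combinations → IM; undetermined alleles or unattributable duplications
  → ND.
* **Population statistics** — gene-counting frequency tables; two-level
  haplotypic AMOVA on label-identity distance,
  Φ\_ST = σ²\_among / (σ²\_among + σ²\_within), with a seeded permutation
  p; Weir–Cockerham multi-allelic θ = Σa / Σ(a+b+c) with
  individual-level bootstrap percentile CIs; Pearson χ² and
  likelihood-ratio (G²) independence tests; Kruskal–Wallis +
  Mann–Whitney + Benjamini–Hochberg for ancestry–phenotype association.
* **Synthetic cohorts** — a generator producing admixed four-region
  cohorts (per-individual Dirichlet ancestry over
  European/African/Amerindian haplotype-frequency profiles, deletion and
  duplication events, assay noise) together with the hidden truth for
  every stage.

## Worked example

```r
library(cyp2d6star)

preset <- brazil_like_preset(seed = 1)          # 4 regions x 255 individuals
sim    <- simulate_cohort(preset$config, preset$profiles)
bundle <- run_pipeline(sim$cohort, n_permutations = 2000,
                       n_bootstrap = 1000, seed = 1)
bundle
#> CYP2D6 pipeline bundle: 1020 individuals (seed 1 )
#>   phenotypes: PM=29 IM=75 EM=809 UM=13 ND=94
#>   AMOVA by region: Phi_ST = -0.00057917 (p = 0.778)

head(bundle$allele_freq_total[order(-bundle$allele_freq_total$count), ], 5)
#>   allele count n_chromosomes   pct
#> 1 *1       719          2040 35.2
#> 2 *2       486          2040 23.8
#> 3 *4       254          2040 12.5
#> 4 *17      109          2040  5.34
#> 5 *41      103          2040  5.05

bundle$amova_region
#> AMOVA (label-identity distance)
#>   among populations:   -0.06% (sigma^2 = -0.00022961)
#>   within populations: 100.06% (sigma^2 = 0.396676)
#>   Phi_ST = -0.00057917, permutation p = 0.7776 (2000 permutations)
```

Reading the output: each of the 1020 individuals contributes two allele
slots (2040 chromosomes); extensive metabolizers dominate (809/1020);
the four regions share ancestral profiles, so essentially all allelic
variance is within populations (Φ\_ST ≈ 0, permutation p ≫ 0.05), and
every pairwise θ between regions is small with a confidence interval
starting at 0. The 94 ND calls are individuals carrying an unassignable
haplotype or a duplication that cannot be attributed to one chromosome —
the same structural ambiguity real assay-based surveys report.

A thin command-line wrapper lives in `inst/cli/cyp2d6star-cli.R`
(`simulate` and `run-all` subcommands) for shell use.

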