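---
title: "CYP2D6 star-allele calling and population pharmacogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CYP2D6 star-allele calling and population pharmacogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyp2d6star)
```

## The problem

CYP2D6 metabolizes roughly a quarter of prescribed drugs, and its gene is
exceptionally polymorphic: point variants, whole-gene deletions and
whole-gene duplications combine into named haplotypes ("star alleles") with
normal, reduced, absent or increased enzyme activity. In admixed
populations, allele frequencies blend European, African and Amerindian
ancestral patterns, so a cohort survey has to travel the whole distance
from raw genotypes to population statistics:

1. phase unordered diploid genotypes into haplotypes,
2. assign each haplotype a star allele by perfect matching,
3. call integer gene copy number from a relative-quantification assay and
   fold deletions (*5) and duplications (xN) into the diplotype,
4. predict the metabolizer phenotype (PM / IM / EM / UM) from the
   diplotype, and
5. quantify population structure and ancestry association.

`cyp2d6star` implements each stage as a testable module and adds a
synthetic admixed-cohort generator so that the entire pipeline can be
exercised, with known ground truth, without access to any individual-level
study data.

## The variant panel and allele model

The genotyping panel covers eleven gene-relative positions (−1584, 31,
100, 1023, 1846, 2549, 2615, 2850, 2988, 3183, 4180). Every site is
biallelic on this panel; the two indels (2549, 2615) are modeled as
single-site reference/`del` calls, which is what a biallelic TaqMan assay
reports — indel length is not represented. The packaged definition table
lists 13 base alleles. Twelve are sequence-defined; the whole-gene
deletion *5 has no sequence and is called from copy number alone.
Duplication alleles (*1x2, *1x3, *2x2, *2x5, *4x2, *17x2, *35x2) share
their base allele's states and carry a copy multiplier.

Matching is strict: a haplotype is assigned a star allele only when all
eleven states agree with a definition; everything else is pooled as
`"Others"`, whose activity is undetermined. Over the full 2^11 haplotype
space, exactly the 12 sequence-defined base alleles are reachable — a
property the test suite checks by enumeration.

Activity classes follow the definition table (normal, reduced, none,
increased, ND). Duplications not listed explicitly follow a rule that
reproduces every listed case: duplicating a normal-function allele
increases activity, duplicating a no-function allele changes nothing, and
duplications of reduced-function or undetermined alleles are left ND
(doubling a reduced allele is not evidence of any particular activity
level). One nomenclature note: the source nomenclature lists the *2
duplication with a degenerate −1584 state (G or C); the packaged table
records the canonical G pattern, and a non-duplicated C-variant of that
haplotype pools as "Others".

## Phasing by expectation-maximization

Haplotype frequencies are estimated by a multinomial EM under
Hardy–Weinberg random pairing (the classical gene-counting EM of the
Excoffier–Slatkin family): the E step distributes each individual over all
ordered haplotype-pair resolutions consistent with its genotype in
proportion to the current frequency product, and the M step re-estimates
frequencies from expected counts. Missing site calls are marginalized —
summed over both states — rather than imputed or dropped, which preserves
the chromosome bookkeeping. Individuals with one gene copy contribute a
single chromosome read directly from their homozygous-appearing calls;
zero-copy individuals contribute nothing; individuals with three or more
copies are phased as ordinary diploids and their extra copy is resolved
downstream, mirroring the phase-then-assign-duplication order of
assay-based surveys.

Numerical choices: convergence at a log-likelihood change below 1e-8 with
a 1000-iteration cap; five random restarts plus one deterministic
allele-frequency-product initialization, keeping the best final
likelihood; results are reproducible for a given seed, and the caller's
RNG state is restored afterwards. The log-likelihood is asserted
non-decreasing at every iteration. Per-individual best diplotypes are the
maximum-posterior unordered resolutions under the final frequencies
(heterozygous pairs weighted 2·f·f, homozygous f²); exact posterior ties
are broken lexicographically on the state vectors and flagged. A genotype
incompatible with every positive-frequency haplotype is ranked uniformly
over its compatible resolutions via a 1e-12 floor frequency applied during
ranking only.

The test suite checks the EM against an independent maximizer of the same
likelihood (multi-start Nelder–Mead over softmax-parameterized
frequencies) on two-site cohorts, to 1e-4. A literal grid search at that
resolution over the frequency simplex would need ~10^12 evaluations, so
direct numerical maximization serves as the independent route; it shares
no code with the EM.

## Copy number and diplotype assembly

The copy-number caller converts a relative-quantification value (target
vs a two-copy calibrator) to dosage `2*rq`, rounds to the nearest integer
(ties to even), and reports a Z score (distance from the integer in
replicate-standard-deviation units) and a confidence (posterior
probability of the called integer under a normal error model with a flat
prior over integers). A call passes when confidence exceeds 0.95 and the
Z score is below 1.75 — the acceptance thresholds commonly applied to
TaqMan copy-number analysis. Failed calls propagate as missing copy
number and block phenotyping for that individual. Copy numbers above 6
(the largest value a survey of this design has observed) are rejected as
likely quantification outliers.

Assembly rules: two copies leave the phased labels unchanged; one copy
pairs the observed haplotype with *5; zero copies give *5/*5. With k ≥ 3
copies and both haplotypes sharing one base allele, the duplication is
attributable and one slot becomes base×(k−1). With differing base
alleles the duplication cannot be attributed to either haplotype: the
slots keep their base labels, the call is flagged ambiguous, and the k−2
extra copies are carried separately. Ambiguous duplications therefore
never inflate allele-level xN counts (they are deliberately
under-counted, as in assay-based surveys), but they do count as
duplication carriers, and they force the phenotype to ND.

One genuine identifiability limit is worth stating: a duplication on one
chromosome masked by a deletion on the other (e.g. *41x2/*5) has total
copy number 2 and is indistinguishable from *41/*41 by any whole-gene
copy-number assay. The generator can produce such individuals (they are
biologically real); the truth-recovery tests exclude them, documenting
rather than hiding the limit. Similarly, the exon-9-targeted assay design
this models cannot see exon-9-converted hybrid alleles; that caveat is
documented, not modeled.

## Phenotype prediction

Phenotypes follow the dominance convention widely used in population
surveys (deliberately not the CPIC activity-score convention, which is
drug-specific): the most efficient haplotype determines the class.

* any undetermined-activity allele ("Others", *34, an ND duplication), an
  unattributable duplication, or a blocked copy-number call → **ND**;
* three or more gene copies on normal-function alleles → **UM**;
* otherwise at least one normal-function allele → **EM**;
* otherwise two no-function alleles → **PM**;
* otherwise (two reduced, or reduced plus none) → **IM**.

The ND-propagation choice — an undetermined allele forces ND even when
the partner allele is normal — is configurable in principle and
intentionally conservative; it reproduces the few-percent-per-stratum ND
prevalence a strict-matching survey reports. A monotonicity property is
tested: replacing either allele with a more active one never moves the
phenotype toward PM.

## Population statistics

Frequencies are gene counting: every individual contributes two allele
slots (an xN label occupies one slot), so per-stratum counts always sum
to twice the stratum size. Activity-class tables drop ND slots from
numerator and denominator, giving the "evaluable chromosome" denominator.

AMOVA is the two-level haplotypic partition with label-identity distance
(0 for same star allele, 1 otherwise), which makes Φ_ST a pure
frequency statistic; with 0/1 distance the sums of squares reduce to
allele-count arithmetic, and the tests verify that identity against the
full distance-matrix computation to 1e-10. The permutation p shuffles
individuals among groups with both chromosomes moving together (default
10,000 permutations, seeded) and includes the observed arrangement in the
numerator and denominator.

Pairwise differentiation is the Weir–Cockerham multi-allelic θ: the
per-allele variance components a, b, c are summed over alleles and
θ = Σa / Σ(a+b+c). Confidence intervals are percentile bootstrap over
individuals resampled within groups (default 3,000 replicates), the lower
bound truncated at zero while negative point estimates are reported as
computed — the reporting convention of the R differentiation packages
this mirrors. The tests recompute θ through the nested-ANOVA route
(per-allele indicator variables; mean squares among populations, among
individuals within populations, and within individuals) and require
agreement to 1e-12.

Association tests are deliberately bought, not built: Pearson χ²
(`chisq.test`, no continuity correction), Kruskal–Wallis
(`kruskal.test`), Mann–Whitney (`wilcox.test`, normal approximation with
tie correction) and Benjamini–Hochberg (`p.adjust`). The multinomial
log-linear association reduces, for a single categorical predictor, to
the likelihood-ratio test of independence, implemented as the G-test
(G² = 2 Σ O ln(O/E)) — mathematically equivalent to fitting the saturated
vs independence log-linear model, and exactly testable. Because the
region-by-allele χ² depends on how rare alleles are pooled (a choice
rarely printed in surveys), the pipeline exposes a pooling threshold
(default: labels with fewer than 5 total copies pool into "rare") and
makes no claim to reproduce any particular published full-table χ².

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes: a
four-region cohort (255 individuals per region, 1020 total) in which each
individual draws an ancestry vector from a region-specific Dirichlet and
each of two gene-copy slots draws an ancestral origin and then a whole
star allele from that origin's frequency profile. Linkage within a
haplotype is perfect — haplotypes are whole star alleles, never
recombined — matching the star-allele model itself.

The default ancestral profiles are package defaults, not literature
estimates: they are constrained only to reproduce the qualitative
continental contrasts (no-function *4 enriched in Europeans,
reduced-function *17/*29 essentially African, high *1 in Amerindians, *5
present everywhere at a few percent). The regional Dirichlet means step
the European share up from the North to the South with the African share
peaking in the Northeast, at a concentration (total 7) that gives
realistic between-individual spread. Duplications strike a non-deleted
haplotype with probability 0.044 (≈8–9% carrier rate, the Latin-American
range), with multipliers 2–5 at probabilities 0.80/0.15/0.04/0.01 and the
total capped at 6 copies. The emitted relative quantification is
true CN/2 plus N(0, 0.04) noise; genotype calls go missing at 0.005 per
site. A crude self-reported color label is derived from the African
ancestry share plus noise, purely so color-stratified tables and tests
have something realistic to chew on.

Because reduced-function alleles are African-enriched, the IM phenotype
is mechanically associated with higher African ancestry — the direction
reported for admixed Brazilian cohorts — without any per-phenotype
tuning. What the generator does **not** emulate: linkage to flanking
markers, genotyping error in the SNP calls, exon-9 conversion alleles,
family structure, or any drug-response outcome. Passing tests on this
cohort therefore demonstrate pipeline correctness under the star-allele
model, not robustness to assay artifacts absent from the model.

## What the checks do and do not establish

The test suite separates three kinds of evidence:

* **worked-example arithmetic** against packaged published summary tables
  of a 1020-individual Brazilian survey (gene-counting percentages,
  duplication-carrier rates, the no-function activity row over the 2011
  evaluable chromosomes, and the region-by-activity χ² ≈ 10.7 on 9
  degrees of freedom reconstructed from the printed percentages);
* **oracle equivalence** of the statistical machinery (EM vs direct
  likelihood maximization, AMOVA vs distance matrices, θ vs nested
  ANOVA, hand-computed rank tests);
* **distributional properties** on the synthetic preset: EM is the modal
  phenotype, within-population variance exceeds 99% when regions share
  ancestral profiles, the permutation p is uniform under the null
  (Kolmogorov–Smirnov over 200 replicates), the 95% bootstrap interval
  covers a known parametric θ ≈ 0.0105 in at least 90% of 500 replicates
  (two fixed populations, 250 diploids each, 500 bootstraps), and IM
  individuals average more African ancestry than EM individuals.

Cohort-level statistics that require the survey's unpublished
individual-level genotypes (its exact Φ_ST, pairwise F_ST matrix,
per-phenotype ancestry means) are out of reach by construction and are
*not* claimed; the property checks above stand in for them. The problem
sizes used by the test suite and the acceptance script (a 1020-individual
preset; 1,000–2,000 permutations; 500–1,000 bootstraps per interval; 200
coverage replicates at 500 bootstraps) are the package's chosen defaults
for routine verification; the full 10,000-permutation / 3,000-bootstrap
configuration of a publication run is a function argument away.

## A short worked example

```{r example, eval = FALSE}
library(cyp2d6star)

preset <- brazil_like_preset(seed = 1)
sim <- simulate_cohort(preset$config, preset$profiles)
bundle <- run_pipeline(sim$cohort, seed = 1)

bundle$allele_freq_total      # gene-counting table over 2040 chromosomes
bundle$phenotype_by_region_color
bundle$amova_region           # Phi_ST, variance percentages, permutation p
bundle$fst_region             # pairwise theta with bootstrap CIs
bundle$ancestry_tests$kruskal # ancestry ~ phenotype, KW + pairwise MW/FDR
```

Known limitations, restated briefly: strict 11-site matching cannot
resolve alleles defined by variants off the panel; hybrid-gene alleles
and exon-9 conversions are invisible to the modeled assay; duplications
in heterozygous carriers are structurally ambiguous and therefore
under-counted; and a duplication co-occurring with a deletion hides at
copy number 2.
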