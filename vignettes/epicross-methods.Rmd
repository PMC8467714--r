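---
title: "Methods: simulating and dissecting the genetic architecture of binary heart defects in mouse crosses"
author: "epicross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and dissecting the genetic architecture of binary heart defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicross)
```

# Overview

`epicross` implements a complete analysis chain for case-control studies of
binary malformation phenotypes in two-strain mouse crosses carrying a
sensitizing heterozygous mutation (the motivating system is *Nkx2-5*^+/−^
mice, where the mutation's penetrance for each heart-defect class is shaped
by background modifier loci). Because real genotype data of this kind are
rarely deposited, the package is built around a simulator whose genetic
architecture is known exactly; every estimator can therefore be validated by
parameter recovery, not only by internal consistency.

The chain is: simulate cohorts → marker QC → HMM imputation → relatedness
(GRM) → QTL scans → per-locus effect measures → two-locus
physiological-epistasis decomposition → coadaptation statistics → severity
correlations.

# The cross simulator

**Meiosis.** Gametes are generated marker-by-marker under the Haldane
(no-interference) map function, r = (1 − e^{−2d})/2 with d in Morgans.
Interference has negligible influence on the statistics tested here, and the
closed form keeps transition models and the simulator exactly consistent.

**Designs.** An F2 is the union of two independent F1 gametes (the F1 is
heterozygous at every marker). Advanced-intercross generations (F10, F14)
are produced by repeated random non-sib mating from the F2 onward at a fixed
census (default 100 breeding pairs, configurable); the published breeding
scheme also excluded first cousins from the fourth generation onward, a
refinement we omit because its effect on LD decay at these census sizes is
negligible. The mutant flag is assigned to 50% of offspring, the Mendelian
expectation for a heterozygous-by-wild-type cross.

**Marker panels.** Default panels place markers every ~20 Mb (sparse,
F2-style custom panel) or ~3 Mb (dense, linkage-panel style) along 19
autosomes with approximate mouse physical lengths, converting physical to
genetic distance at 0.5 cM/Mb. Sex chromosomes are excluded throughout.

**Phenotypes.** Penetrance acts on the probability scale:
P(defect d | genotype) = baseline_d + single-locus offsets + two-locus
offsets. A single uniform draw per mutant is partitioned into consecutive
intervals, one per defect, so each defect keeps its exact marginal
penetrance and defect classes stay mutually exclusive (each defect is later
analyzed against the same shared normal controls, so comorbidity modeling is
unnecessary). Because deviations add on the probability scale, the
ground-truth higher-order interaction at a pair is exactly the main-effects
residual of the implied 3×3 penetrance table (`true_epistasis_effects()`),
which makes parameter recovery a sharp test. Default baselines (ASD 0.13,
membranous VSD 0.08, muscular VSD 0.055, AVSD 0.035) reproduce the observed
incidence ordering with ~30% of mutants affected.

**What the simulator does not emulate.** Genotyping-platform artifacts
(quality scores, batch effects), segregation distortion, embryonic
lethality, X-linked loci, and multi-allelic markers. Passing tests
demonstrate correctness of the estimators under a faithful meiosis model,
not robustness to platform-specific noise in real data.

# Marker QC and file formats

Markers with more than 10% missing genotypes are dropped — strictly greater,
so a marker at exactly 10% is retained. Minor allele frequency is reported
with the QC output but never filtered on: in an inbred strain cross both
alleles are common by construction. Genotypes travel as TSV (individuals ×
markers, codes 0/1/2/NA counting the non-reference-strain allele) or as
PLINK-style PED/MAP text, with missing genotypes exported as the `0 0`
allele pair.

# Genotype imputation

Missing and untyped genotypes are imputed per chromosome with a three-state
hidden Markov model: hidden genotype states {0, 1, 2} with stationary
distribution (¼, ½, ¼); transitions given by the two-gamete kernel, each
gamete switching parental origin with the Haldane recombination fraction of
the inter-marker distance; emissions correct with probability 1 − ε (default
ε = 0.005, configurable), the two wrong states sharing ε equally. Posteriors
are exact forward–backward quantities; the test suite checks them against
brute-force enumeration over all hidden paths on short chains.

Advanced-intercross generations accumulate recombination, so their
transition distances are scaled by the expected map expansion t/2 for
generation t (F10 → 5, F14 → 7); each generation is imputed separately with
its own factor. Imputation confidence is summarized as the maximum posterior
probability of a call; hard calls are the posterior argmax. The threshold
summaries (fraction of calls above 0.70, below 0.50) mirror the confidence
statements conventionally reported for this design.

# Relatedness and the mixed model

For combined F2 + advanced-intercross analyses the package builds a centered
GRM, G = WWᵀ/p, from column-centered genotypes with per-marker mean
imputation of missing calls (association tests instead drop missing
individuals marker-wise). F2 individuals are effectively full siblings with
essentially identical expected relatedness, so their block is overridden:
off-diagonal 0.5, diagonal 1. The override can leave the matrix indefinite,
so it is projected to the nearest positive semi-definite matrix in Frobenius
norm — with no diagonal constraint the Higham alternating projection reduces
to clipping negative eigenvalues — and the spectrum is floored at 1e-8 for
strict definiteness. The perturbation is verified to be small by the Mantel
similarity, implemented as the Pearson correlation of lower-triangle
off-diagonal entries (expressed as a percentage; the permutation test
shuffles rows and columns simultaneously). Whether the conventional ">95%
similarity" refers to a correlation or a permutation percentile is
ambiguous; the correlation reading is adopted and stated.

The association LMM is y = μ + xβ + u + ε with cov(u) = v_g·GRM and
cov(ε) = v_e·I, fit in the GRM's eigenbasis so one decomposition serves the
whole scan; the variance ratio is profiled out and optimized in one
dimension. Marker tests are 1-df likelihood-ratio tests of ML fits (ML, not
REML, for nesting validity); REML is used only for the reported variance
components, with the PVE standard error from the inverse observed
information by the delta method. Binary phenotypes are analyzed on the
observed scale, as in mixed-model case-control GWAS practice, and
transformed afterwards (below).

# F2 scans, thresholds, and effect measures

The F2 binary-trait scan is the 2-df likelihood-ratio statistic of the
saturated three-genotype-class binomial model (the G statistic of the 2×3
table, with 0·log 0 = 0), reported as LOD = LRT/(2 ln 10). Scans are
computed at markers only; imputed grid positions can be appended as markers
when an interval-style scan is wanted. Genome-wide thresholds come from
permutation of phenotype labels, recording the genome-wide maximum LOD;
α-level thresholds are the empirical (1 − α) quantiles.

For the combined scan, multiple testing uses a Li–Ji-style effective number
of tests from the eigenvalues of the marker correlation matrix,
M_eff = Σ I(λ≥1) + (λ − ⌊λ⌋), with thresholds 0.05/M_eff (significant) and
1/M_eff (suggestive). (At the conventionally cited M_eff = 542 these give
9.2 × 10⁻⁵ and 1.8 × 10⁻³; a printed value of "9.2 × 10⁻⁴" for 0.05/542
appears to carry a power-of-ten slip, which the package does not reproduce —
the formula is implemented as stated.)

Per-locus effects are reported two ways: the odds ratio per risk allele from
an additive logistic fit (a penalized-quasi-likelihood logistic mixed model
when a GRM is supplied: the working-response iteration refits the variance
ratio of the weighted LMM at each step), and the per-SNP variance explained,
PVE_SNP = MAF(1 − MAF)β²/PV. The conventional additive-variance formula
carries a factor 2; the one-factor form is the default and the factor-2
variant is available behind a flag. Observed-scale PVE estimates are
corrected for case-control ascertainment and moved to the liability scale by
PVE_l = PVE·P²(1−P)²/(A(1−A)z²), with z the standard normal density at the
population liability threshold; at P = A = ½ the factor reduces to π/2,
which the tests assert.

# Two-locus physiological epistasis

The package's central statistic treats the 3×3 table of defect incidences at
a locus pair. The expected incidence under independently acting loci is the
*unweighted* main-effects fit — expected_ij = row mean + column mean − grand
mean, every cell weighted equally regardless of counts, equivalently the
unweighted least-squares regression of the nine cell incidences on the two
single-locus margins (the equivalence is asserted in tests). The
higher-order interaction effect is observed − expected; by construction the
nine effects sum to zero along every row, column, and in total, so a
risk-raising deviation at one genotype is balanced by protective deviations
elsewhere.

Significance uses the variance-stabilized arcsine scale:
θ = asin(√p) with var(θ) ≈ 1/(4n). The effect at cell (i, j) is the linear
contrast of the nine θ values with the decomposition weights (+4/9 at the
cell, −2/9 sharing its row or column, +1/9 otherwise), its standard error
√(Σλ²/(4n)), and a two-tailed test against zero with the normal reference
(cell counts are large in the intended regime; the appropriate
degrees-of-freedom convention for small cells is genuinely open, and the
normal reference is the choice made here). Because the contrast combines all
nine cells, the covariance between a cell and its fitted expectation is
accounted for exactly under independence of cells. The family-wise threshold
is 0.05/(9x) over the x locus pairs analyzed per defect. Cells with zero
total count abort the pair with a report rather than being imputed — silent
imputation would corrupt the conservation identities.

Reported magnitudes stay on the incidence scale and are divided by the
unweighted average incidence (UWA) of the nine cells, making effects
comparable between defects of different incidence; signs are preserved
(positive raises risk). When a defect has only one mapped locus, the pair is
completed with the most significant scan marker not linked (within 10 Mb) to
an existing locus.

# Coadaptation statistics

Each two-locus genotype falls in one of four strain-configuration classes:
syn-homozygous (both loci homozygous for the same parental strain; 2 cells),
anti-homozygous (opposite strains; 2), double-heterozygous (1), and mixed
(4). Among significant interaction effects, the per-class fraction that is
protective (negative, risk-lowering) is tested against ½ with two-sided
one-sample z-tests and between classes with two-sample z-tests. The
syn/anti protective-fraction ratio is reported as a descriptive quantity; it
is data-dependent and not a fixed constant. Congruence tests ask whether a
significant protective syn-homozygous cell (or deleterious anti-homozygous
cell) predicts congruent signs at the companion syn and anti cells of the
same pair; denominators count locus pairs, not cells, to avoid
double-counting within a pair (the cell-level alternative is noted as an
open reading, and the pair-level choice is the one documented here).

# Nonparametric utilities

Kendall's τ is the tie-adjusted τ-b throughout (incidence and effect data
contain ties). Partial correlations come from the inverse of the pairwise
τ matrix of (x, y, covariates) — with one covariate this reduces to the
familiar first-order recursion, asserted in tests. Two-sided p-values use
the normal approximation with the effective sample size reduced by the
number of covariates. Severity analyses control for the cross and, for
interaction effects, the observed two-locus incidence, to avoid bias from an
underlying incidence-effect correlation. The Mann–Whitney U test uses exact
enumeration when the smaller sample has ≤8 untied observations and the
tie- and continuity-corrected normal approximation otherwise.

# The end-to-end pipeline

`run_end_to_end()` drives the whole chain from a single configuration (R
list or YAML): simulate each cross, mask genotypes, QC, impute per
generation, build/override/adjust the GRM for combined cohorts, scan each
defect against the shared normal controls (binary permutation scan for
F2-only crosses, mixed-model scan for combined ones), select loci, decompose
and test every pair, summarize coadaptation, and correlate incidences and
scaled significant effects with configured severity ranks (ASD 1, VSD types
2, AVSD 3 — severity is configuration taken from human survival data, not an
inference). Stage tables are written as TSV with a JSON manifest; a rerun
with the same configuration reproduces them byte-for-byte. The package's
functions and this configuration surface are the intended interface; the
`scripts/acceptance.R` entry point shows the same functions driven
non-interactively.

# Numerical choices and problem sizes

Default problem sizes in the examples, tests, and the acceptance script are
desk-scale choices that preserve the study's structure: F2 scans at
n = 1000–1500 with ~120 sparse markers and 1000 permutations; imputation at
n = 1000 over a 3 Mb untyped grid; combined cohorts of 1500 over ~820 dense
markers; recovery experiments sized to ~300 individuals per two-locus cell.
Variance-ratio optimizations run on log scale over e^±15 with boundary
flags; GRM eigenvalue floors are 1e-8; conservation identities are asserted
to 1e-12 and oracle equivalences to 1e-10.

# Known limitations

Binary traits enter the LMM on the observed scale; the liability transform
corrects scale but not model misspecification at extreme incidences. The
PQL logistic mixed model shares the well-known small-cluster bias of PQL.
The partial-τ p-value is an approximation whose exact null distribution
with covariates is not implemented. The simulator's random-mating AIC
slightly understates the effective population size of the published breeding
scheme. Natural-population extensions (multi-allelic, rare alleles) are out
of scope: with rare alleles the population and unweighted average incidences
decouple and these statistics lose comparability — which is precisely why
the two-common-allele cross design is the right instrument for them.
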