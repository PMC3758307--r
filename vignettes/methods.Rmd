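---
title: "Models and methods in flockgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in flockgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

flockgwas chains five analysis stages — read-depth region calling, genotype
QC, a multi-model association scan, two-locus LD, and production-trait mixed
models — around a synthetic-data generator that reproduces the statistical
structure each stage assumes. This vignette documents the models, the
defaults and why they were chosen, the numerical decisions, and what the
package's tests do and do not establish about real data.

## Read-depth region calling

Reads are represented by their start positions only; depth is the count of
read starts per window. This keeps each read's total contribution constant
across an overlapping grid (with 200 bp windows sliding by 100 bp a start
position falls in at most two windows) and matches how aligned read numbers
are counted in depth-of-coverage CNV pipelines. An `overlap` counting mode is
available as a dialect switch in `count_windows()`.

Two callers share a run rule: mark every frame of 7 consecutive unmasked
windows containing at least 5 qualifying windows; a window enters a call iff
it qualifies and lies in a marked frame; overlapping marked spans merge.
The rule is deterministic and order-independent, and masked windows (those
overlapping a gap or repeat annotation by ≥1 bp) break run continuity so
calls never bridge unreliable sequence.

* **Duplications** qualify a window when the count exceeds the animal's own
  mean + 2 SD, both computed over that animal's unmasked windows. The
  statistics are per-animal rather than pooled because sequencing depth
  varies across animals; this is an interpretation choice, exposed through
  `sd_mult` and documented as such.
* **Deletion/alternate regions** qualify a window when more than 4 animals
  sit above 0.5 of their average fold depth while at least one other animal
  falls below 0.1. "More than 4" is read literally as ≥5 and "some other
  animals" as ≥1; both are parameters (`min_high_animals`,
  `min_low_animals`). Fold depth is the count divided by the animal's own
  unmasked mean. Per region, an animal is reported in the high or low set
  when it meets the criterion in a majority of the region's defining
  windows; a strict all-windows rule proved fragile at region edges, where
  boundary windows straddle the breakpoint.

Coordinates are 0-based half-open everywhere inside the package; 1-based
positions appear only at the PLINK `.map` boundary, and BED output is
0-based half-open as the format requires.

The caller does not attempt GC correction, absolute copy-number estimation,
or junction/split-read analysis; its contract is interval recovery, and the
suite measures that as recall of implanted divergent regions (≥90% overlap
of truth) across 100 seeded replicates, with specificity checked on null
panels.

## Genotype QC

The screening cascade mirrors PLINK's documented order: individuals first
(missingness > 10%), then markers — missingness > 3%, then minor allele
frequency (kept only when MAF > 2%), then Hardy–Weinberg at p < 10⁻⁶, each
computed on surviving individuals. All comparisons are strict inequalities,
following the usual "missing > x%" phrasing. HWE is computed on all retained
individuals pooled across breeds; a per-breed procedure would be defensible
but is not what single-cohort PLINK screens do.

The HWE test is the conditional exact test: given the allele counts, the
heterozygote count follows a hypergeometric-type distribution, and the
two-sided p-value sums the probabilities of all heterozygote counts no more
probable than the observed one. It is computed through the standard ratio
recurrence between successive heterozygote probabilities, normalised at the
end, which is numerically safe for any counts the package will meet. A
chi-square variant exists behind the `chisq` flag for comparison only. The
suite verifies the exact test against an independent log-factorial
enumeration oracle exhaustively for all genotype configurations with total
count ≤ 100, and against a brute-force enumeration of allele pairings at
tiny n.

Re-running the cascade on its own output removes nothing under realistic
missingness structure. Strict idempotence can fail in adversarial fixtures
where an individual sits exactly at the missingness boundary on the reduced
marker set; the cascade is faithful to the stated order rather than to an
unconditional fixed-point property.

## Association scan

For each marker and each mode of inheritance the trait is regressed by
ordinary least squares on covariates plus the encoded genotype. Encodings
use the minor allele as determined in the analysed sample after QC (PLINK's
convention): additive counts minor-allele copies; dominant/recessive are
indicators; the genotypic model uses heterozygote and minor-homozygote
indicators against the major-homozygote reference. The p-value is the t-test
on the genotype coefficient, or the 2-df partial F-test for the genotypic
model. Effect size is the largest difference among covariate-adjusted
genotype means — a function of the genotype coefficients under each encoding
(2|β| additive; |β| dominant/recessive; max(|β₁|, |β₂|, |β₁−β₂|) genotypic)
— reported in trait units, invariant to allele flips and covariate
recentring.

The best-fitting model per marker is the one with the smallest nominal p,
ties broken in the fixed order additive, genotypic, dominant, recessive.
No correction for the four-model search is applied by default, reproducing
the common reporting practice; `bonferroni_models = TRUE` multiplies the
winning p by the number of models fitted for users who want the
conservative version.

Significance tiers default to p ≤ 5×10⁻⁸ (genome-wide) and p < 10⁻⁵
(suggestive). Both are arguments, since reasonable analyses also draw the
genome-wide line at 0.05/50,000 = 10⁻⁶; neither convention is hard-coded as
truth. p-values are floored at 10⁻³⁰⁰ to keep −log₁₀ finite. Population
structure enters only as fixed breed/cluster covariates; there is no kinship
mixed model, so the null-calibration results (uniform p, genomic inflation
λ ∈ [0.9, 1.1]) describe cohorts whose structure is captured by those
covariates.

Conditional re-analysis adds the chosen markers as genotypic fixed
covariates and rescans the rest; collinear conditioning columns are dropped
left-to-right by a QR rank check, with a message. Conditioning on the causal
locus flattens the LD-driven peak, and the suite measures exactly that on
synthetic cohorts.

## Linkage disequilibrium

`em_haplotype_freqs()` maximises the multinomial likelihood of the four
haplotype frequencies from unphased two-locus genotypes. Only the double
heterozygote is phase-ambiguous; the E-step splits it between coupling and
repulsion in proportion to current frequency products. Convergence is
declared when the largest frequency change drops below 10⁻¹⁰ (cap 1,000
iterations), and the log-likelihood trace is retained so the
monotonicity property can be asserted directly. Initialisation is at
linkage-equilibrium products; when double heterozygotes exceed 25% of the
sample — the regime where the likelihood can be bimodal — three extra random
restarts (deterministic given the seed) are run and the best likelihood
kept. Monomorphic loci yield an explicit undefined sentinel rather than a
number. D′ and r² follow the standard normalisations; the suite checks the
EM against a 1-D grid search of the profile likelihood in the coupling
frequency, exact haplotype counting when no double heterozygotes exist, and
invariance to locus order and allele relabelling.

## Production-trait mixed model

The trait model has fixed effects of birth year (a factor, the conventional
coding for year effects), breed and marker genotype, optionally age at last
lambing for lifetime traits, plus a random sire intercept nested within sire
breed — realised by making sire labels unique per breed — and i.i.d.
residuals. Because there is exactly one random effect, REML is profiled in
the variance ratio λ = σ²_sire/σ²_resid: the marginal covariance is block
diagonal by sire with closed-form inverse and determinant, so each λ
evaluation is O(n), and a coarse log-grid plus Brent refinement minimises
the criterion. λ = 0 is always evaluated; a boundary fit is flagged and then
equals OLS exactly. This deliberately avoids general mixed-model machinery;
the cost is that the optimiser's precision in the variance components is
~10⁻⁶ relative (Brent's limit without derivatives), which the tests respect.
Against lme4 on unbalanced designs the components agree to ~10⁻⁴ and fixed
effects to 10⁻⁶.

Adjusted (least-squares) genotype means average predictions over an equally
weighted grid of the other factor levels with covariates at their means,
matching SAS/emmeans LSMEANS semantics (verified against emmeans in the
suite). Pairwise contrasts use the model-based covariance; Tukey–Kramer
adjusted p-values are P(q(k, df) ≥ √2·|estimate|/SE) via the studentized
range distribution, with df taken as the GLS residual df n − p (a simple,
slightly liberal choice relative to Satterthwaite; with many sires the
difference is negligible, and the k = 2 identity with the t-test holds by
construction). Genotype classes observed fewer than 10 times keep their
adjusted means but have contrasts flagged `insufficient_n`; 10 is a
configurable convention for "too few homozygotes to compare", which real
reports leave undefined. Ordinal traits such as udder score are modelled as
continuous, a simplification inherited from standard livestock mixed-model
practice.

## Synthetic data

The generator exists so that every stage is testable with no download, and
its defaults are the study conditions the tests run under.

* **Depth**: read starts are drawn from a piecewise-constant Poisson process
  and counted by the package's own window counter, so overlapping windows
  carry the correlation real counting induces. The base rate gives an
  expected 30 read starts per 200 bp window. Implanted duplications multiply
  the rate by their fold-gain (all animals carry them by default; a carrier
  frequency is available). The divergent region multiplies the rate by 0.02
  for divergent homozygotes and 0.5 for heterozygotes — one versus zero
  mappable haplotypes; the heterozygote factor is an assumption of the
  generator, not an empirical value. Divergent genotypes are drawn in
  Hardy–Weinberg proportions.
* **Genotypes**: background markers are independent per animal at
  frequencies uniform on [0.05, 0.5] (HWE holds by construction). The tag
  SNP copies the divergent-locus genotype and resamples each animal with
  probability 1 − √(target r²), with rejection (tolerance 0.02 on realised
  r², best of 200 draws kept) — a transparent way to pin LD at, e.g.,
  r² ≈ 0.97, the regime of a tag SNP on a divergent haplotype.
* **Phenotypes**: intercept + breed offsets + an age slope + genotype effect
  (additive, or arbitrary per-genotype means to create the non-additive
  patterns red-cell traits show) + sire effects N(0, σ²_s) + residuals. The
  production generator plants per-genotype means of (225.6, 225.6, 241.1)
  units by default — a 15.5-unit dominant-pattern contrast — with sire and
  residual variances of a few units and ~20 offspring per sire.

Every generator derives its own stream deterministically from the single
config seed via a stable string hash, so runs are bit-reproducible and
sub-generators are independent.

What passing tests show — and what they do not: recovery, calibration and
LD results hold under Poisson depth noise, independent background markers,
equal-variance Gaussian traits and covariate-captured structure. Real
cohorts add GC-dependent coverage, LD between background markers,
relatedness beyond a one-level sire structure, and non-Gaussian traits;
none of these are simulated, so the suite validates the algorithms'
correctness, not their robustness to those complications.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run at deliberately moderate
sizes chosen to exercise each property well inside a desktop minute-scale
budget: 20-animal, 20 kb panels across 100 replicates for caller recall;
2,000–5,000 null markers at n = 150 for scan calibration; n = 1,000 cohorts
for LD; 400 animals × 20 sires for mixed-model recovery; exhaustive HWE
verification for totals ≤ 100. All stochastic results are driven by explicit
seeds, and `run_pipeline()` writes a JSON manifest (package version, seed,
parameters, row counts) alongside its outputs so any run can be reproduced
exactly.
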