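---
title: "Family-based variant prioritization and rare-variant burden testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based variant prioritization and rare-variant burden testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcascade)
```

# Scope and model

`varcascade` implements two linked analyses for candidate-gene discovery in
genetically heterogeneous congenital disease. The first is a deterministic
filtering cascade over a sequenced nuclear family of five — two unrelated
parents, an affected proband, two unaffected siblings — that reduces a
whole-genome variant call set to a handful of genes compatible with a
recessive or de novo disease model and supported by expression evidence
from proband- versus parent-derived iPSC lines. The second is a
case-control rare-variant burden framework for testing whether qualifying
variants in a candidate gene are enriched in affected individuals.

The package consumes standard formats (VCF v4.x with GT/DP/GQ, 6-column
PED, FASTA, tab-separated annotation and expression tables) and normalizes
everything into tidy tibbles; read alignment, variant calling, variant
effect annotation and differential-expression estimation are upstream of
this package and are consumed as inputs, never recomputed.

# The family cascade

## Quality rules

Three genotype/site-quality rules gate the cascade, each with a strict,
documented boundary:

* **Read depth** — every evaluated sample must have DP ≥ 10 (inclusive).
  The depth rule is applied to the proband and both parents for all
  variants, and additionally to siblings for inherited-mode candidates,
  the conservative reading when the evaluation set is not specified. A
  missing DP field fails in strict mode (the default) and passes in
  permissive mode, since the upstream filters presume the field exists.
* **Homopolymer adjacency** — a variant fails when the maximal single-base
  run *starting at the base immediately flanking its reference span*, on
  either side, exceeds five bases. The run never includes the variant's own
  reference base; a run of exactly five passes. This is the strictest
  reading consistent with "adjacent", and it is applied to the full
  reference span of indels.
* **Internal-cohort recurrence** — variants seen in ≥ 5 of 147 in-house
  exomes from unaffected individuals are removed (strict inequality).

## Rarity and function

Rarity is the maximum frequency over the configured population databases
being strictly below the mode threshold: 1% for dominant-acting candidates
(de novo, loss-of-function, panel screening), 3% for recessive ones. An
absent frequency is a novel variant and counts as 0. The `frequency_era`
switch exists because database frequencies drift across years: in
`study_initiation` mode the cascade consults exome-server-era columns (the
packaged fixture emulates these as the printed modern frequency capped at
2.9%, documented as an emulation, not historical data), while `current`
mode consults all columns including gnomAD. On the packaged worked example
the era switch reproduces both published outcomes: ten candidate genes
under initiation-era frequencies, eight under current ones.

Functional impact is a fixed consequence whitelist: protein-altering
classes, canonical splice sites, microRNA sites, enhancers, and
ENCODE-validated promoter/TFBS classes. One severity-ranked consequence is
carried per variant (frameshift > stop gain > stop loss > essential splice
> missense > splice region > synonymous > UTR > upstream > intronic).

## Inheritance classification

Classification is per gene, in a fixed order: homozygous recessive
(proband homozygous alternate, both parents heterozygous), then compound
heterozygous, then X-linked recessive; de novo variants are called
separately (carrier proband, both parents explicitly homozygous reference
with adequate depth — the depth demand guards against allele dropout
masquerading as de novo).

Compound-heterozygote phase is inferred by transmission: a variant
heterozygous in the mother and absent in the father is maternal, and vice
versa. A variant heterozygous in *both* parents has ambiguous origin; it
may fill either side of a compound pair but a single such variant can never
anchor a pair alone — two distinct variants are always required. This is a
design choice where the convention is genuinely open; the alternative
(allowing one both-parent-het variant to count as both sides) would admit
configurations indistinguishable from a simple inherited heterozygote.

**Sibling exclusion requires the full causal configuration.** The
published worked example retains genes whose unaffected siblings carry
*single* variants of a compound pair, so exclusion cannot be per-variant:
a call is voided only when a sibling's genotypes could reproduce the
proband's complete configuration — both alleles of a homozygous call, at
least one maternal-side plus one paternal-side variant of a compound set,
or the hemizygous/homozygous state for X-linked calls. Unaffected sisters
heterozygous for an X-linked variant are carriers and never void. The test
suite verifies this against a brute-force enumeration over all sibling
genotype combinations.

"Hemizygous" candidates are labelled `x_linked_recessive` with a
`hemizygous` flag in the supporting evidence, matching how the two
X-chromosome genes of the worked example are reported. Diploid-coded
heterozygous male X calls are inconsistent and dropped from X-linked
analysis. Inherited frameshift/stop variants in genes with pLI > 0.75
(strict) are retained as a separate `inherited_lof` mode.

Every input variant lands in exactly one audit category — a QC stage,
`not_rare`, `not_functional`, `sibling_excluded`, `no_inheritance`, or
`survived` — and the audit table is conserved by construction; the decoy
variants built into the synthetic fixture verify each removal stage
end-to-end.

## Expression intersection

A gene is concordantly differentially expressed at a timepoint when it is
significant versus *both* parents (FDR-adjusted p < 0.05) with the same
fold-change sign and |log2FC| ≥ 1. The fold-change cutoff is configurable
because the magnitude threshold of the original expression pipeline is not
recoverable from its description; the packaged worked example is
constructed to be insensitive to this choice. Final candidates must carry
an inheritance call and be concordant at both d0 and d25. Genes observed in
only one parental comparison are excluded and reported, never silently
dropped.

# The burden framework

## Site QC

Cohort genotypes with GQ < 20 are masked to missing; sites with call rate
< 0.95 or Hardy–Weinberg exact p < 1e-8 are excluded, and a PASS FILTER
label is required (recalibration verdicts are consumed, never refit). The
HWE test is the two-sided conditional exact test under the
probability-ordering definition — the convention the 1e-8 threshold is
normally applied to — computed by the standard recurrence across
heterozygote counts; a chi-square variant is available behind a flag for
comparison, and the exact path is verified against full enumeration for
every genotype table up to n = 50. HWE is computed on all samples after GQ
masking by default, with a controls-only mode exposed since the choice is
not dictated by the design.

## Weights, statistics, tails

Qualifying variants (strict-impact whitelist; CADD > 24 applied to
missense only; MAF < 1% across all populations) are weighted by
`dbeta(MAF, 1, 25)` of the observed cohort MAF, minor-allele oriented and
computed on all analyzed samples after QC. With the null-model residual
vector r (intercept-only logistic by default; a covariate matrix is
accepted), the two component statistics are

* variance-component: Q_S = Σ_j (w_j g_j' r)²,
* burden: Q_B = (Σ_j w_j g_j' r)²,

and the optimal test scans Q(ρ) = (1−ρ) Q_S + ρ Q_B over the standard grid
ρ ∈ {0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1}. Each Q(ρ) follows a weighted
mixture of 1-df chi-squares under the null; tail probabilities are computed
by numerical inversion of the characteristic function (Imhof's integral on
a fixed Simpson grid whose step resolves the oscillation and whose
truncation point comes from an integration-by-parts envelope bound,
absolute accuracy ~1e-8), with exact closed forms in the equal-eigenvalue
limits, a moment-matching (mean/variance/kurtosis) fallback if the
integration fails, and a saddlepoint approximation below p ≈ 1e-7 where
absolute integration accuracy no longer resolves the tail. A seeded
Monte-Carlo mode exists for cross-checking. Characteristic-function
inversion was promoted over moment matching as the primary method because
the package's own acceptance tolerance (three standard errors of a
million-draw Monte-Carlo oracle) is tighter than moment matching reliably
achieves mid-distribution.

The per-ρ p-values are combined through the minimum-p statistic: the score
vector is decomposed into the shared burden direction and its orthogonal
complement, and the acceptance probability is integrated over the 1-df
chi-square of the shared component. Two numerical details matter here.
First, the integrand contains an integrable 1/√x endpoint singularity, and
when the minimum p is large the entire mass concentrates in a narrow spike
at the origin; the integral is therefore evaluated after the substitution
x = y², bounded at the edge of the acceptance-region support. Second, the
per-ρ quantiles at the observed minimum p use a moment-matched starting
value refined by secant steps on the accurate tail. The combined p is
clamped to its analytic bounds [T, |grid|·T]. Against a 200 000-draw
multivariate-normal min-p oracle the combination layer is accurate to
roughly 0.002–0.02 across the regimes the tests exercise, small relative
to the finite-sample error of the per-ρ asymptotics at the instance sizes
where that matters.

A phenotype-label permutation path is provided as a cross-check (never the
production path): eigenvalues do not depend on the labels, so permutations
vectorize through a single score-matrix product, and per-ρ statistics are
mapped to p-values through one consistent monotone moment-matched
transform before taking the minimum. Both the standard inclusive (+1)
permutation p and the mid-p are reported; the mid-p is the right comparison
for a continuous approximation because the permutation null is discrete —
at sixty samples visibly so (the global case/control label swap alone
guarantees atoms).

## Small-sample behaviour

At n = 60 with Beta(1, 25) weights the analytic and permutation answers can
disagree by up to ~0.1: every variant observable in sixty samples is
common, the beta weights then concentrate nearly all mass on the single
rarest variant, the kernel is effectively rank one, and the permutation
distribution of one squared lattice-valued score is far from its
chi-square limit. The small-instance cross-check in the test suite
therefore runs unweighted — the regime such an instance can support —
while the beta-weighted path is validated where it is meant to operate: a
2000-replicate null simulation at 500 cases / 500 controls with 20 rare
variants (MAF 0.002–0.01), where the empirical type-I error at α = 0.05 is
within binomial tolerance of nominal and the p-value distribution passes a
Kolmogorov–Smirnov uniformity test, plus a power comparison in which a
planted carrier odds ratio of 3 at ~5% combined carrier frequency strictly
beats the null rejection rate at α = 0.025.

## Enrichment, subsetting, multiplicity

Carrier enrichment reports, per phenotype group, the fraction of samples
holding at least one alternate allele across the masked variants, the
case/control fold, and a two-sided Fisher exact p on the 2×2 carrier table
— clearly supplementary to the SKAT-O p. On a fixture planting 13 carriers
among 130 cases and 29 among 861 controls this reproduces the published
10% versus 3.4% with a fold that rounds to 3. Ancestry subsetting retains
samples with fraction strictly above 0.80; Bonferroni control divides α by
the number of tests (0.05 / 2 genes = 0.025 in the motivating design).
Category-stratified runs select variants by consequence class (with
rarity, without the CADD rule, matching the relaxed-constraint analyses);
the two regulatory categories accept BED-style interval tables or a
regulatory flag column.

# Synthetic data: what it does and does not emulate

The generators define the study conditions for every test:

* `make_quintet_fixture()` encodes the 22 distinct published worked-example
  variants with their printed genotypes, origins, sibling genotypes and
  population frequencies on synthetic contigs (one per autosomal gene, a
  shared X contig), plus three decoys per filter rule, each violating
  exactly one rule so the audit table can be checked stage by stage.
  Synthetic coordinates deliberately make no real-genome claims; dbSNP ids
  are carried in the VCF ID column for traceability.
* `simulate_quintet()` plants inheritance modes (and null configurations
  that must not be called) in random quintets; the classifier recovers
  planted modes at 100% with zero false calls across 200 seeded fixtures.
* `simulate_cohort()` draws Hardy–Weinberg genotypes at uniform MAFs and
  assigns exactly n_cases case labels by weighted sampling from a logistic
  carrier model, so arm sizes are exact and all-zero effects reduce to
  random labels. Missingness is uniform.
* `simulate_det_tables()` plants concordant/discordant/null expression
  structure with recorded truth.

None of the generators model linkage disequilibrium, sequencing-error
processes, population stratification, or transcript-level complexity;
passing tests demonstrate the correctness of the filtering and testing
logic under the stated statistical models, not robustness to those
real-data complications. Genotype-error injection exists as a dial
(default 0) for robustness exploration only.

# Problem sizes and runtime

The test suite's heavier components are sized for a single core: the null
calibration runs 2000 replicates at 1000 samples × 20 variants (about five
minutes), the power comparison 2×1000 replicates, the HWE enumeration
sweep covers all genotype tables to n = 50, permutation cross-checks use
10⁵ label permutations on 60-sample instances, and the inheritance sweep
runs 200 random quintets. The acceptance script runs the full worked
example (46 variants, five samples) in seconds.

# Known limitations

* Phase is inferred by transmission, not reads; mosaicism, imprinting and
  incompletely penetrant dominant models are out of scope by design.
* The analytic SKAT-O tail is asymptotic; at tens of samples its agreement
  with the exact permutation null is limited by the discreteness of the
  statistic (see above), and the permutation path should be preferred at
  such sizes.
* The clinical panel gene list for the pre-screen is user-supplied
  configuration (empty by default); panel membership is proprietary.
* No liftover: contig names are taken verbatim, and family and cohort
  inputs are assumed internally consistent in build.
* Relatedness and kinship adjustment in the burden model are not
  implemented; the null model assumes unrelated samples.
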