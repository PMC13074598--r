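---
title: "Leaf-trait analysis of a paired reciprocal transplant: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf-trait analysis of a paired reciprocal transplant: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transplantTraits)
```

## The experimental system

The package analyses a paired reciprocal transplant of clonal plant
genotypes between two contrasting light habitats. Two populations of the
clonal perennial *Iris pumila* — one native to an open sand dune ("Dune"),
one to a shaded woodland ("Woods") — are each represented by ten genotypes.
Every genotype contributes one ramet replanted in its home habitat and one
transplanted into the away habitat, so the design is a balanced 2
(population) x 2 (habitat) layout with the genotype as the experimental
unit (n = 20 per habitat, 40 records in all).

Thirteen leaf traits are carried per record: structural (SLA, LDMC),
physiological (SLWC, chlorophylls a and b, their total and ratio,
carotenoids) and biochemical (POD and GR specific activities, total
anthocyanins and phenolics, and MDA as a lipid-peroxidation marker).
`trait_names()` and `trait_units()` give the canonical vocabulary.

## From raw assays to traits

`derive_trait_table()` converts raw measurements into traits with the
standard wet-lab formulas:

* structure: `SLA = LA/LDM`, `LDMC = LDM/LFM`, `SLWC = (LFM - LDM)/LA`;
* pigments: Wellburn-style linear combinations of A665/A649/A480 on DMSO
  extracts, scaled by extract volume over leaf area. The solvent-specific
  coefficients live in `assay_config()` and are deliberately loud in the
  interface — different spectrophotometer bandwidths and solvents need
  different equations, and every result is conditional on them;
* enzyme kinetics: Beer–Lambert conversion of an absorbance rate,
  `rate = dA/(eps * l)` with eps 2.4 mM^-1 cm^-1 (POD, pyrogallol, 430 nm)
  and 6.2 (GR, NADPH, 340 nm), volume-scaled and divided by Bradford
  protein from a BSA standard curve (OLS fit, inverse prediction,
  triplicates averaged before inversion);
* phenolics: gallic-acid standard curve at 724 nm, times the pooled
  extract volume per g fresh weight (default 22 mL g^-1, encoding a
  two-step 1:15 + 1:7 methanol extraction as one pooled volume — only the
  total volume enters the unit);
* anthocyanins: carbohydrate-corrected absorbance `A530 - 0.24 A653`,
  Beer–Lambert with eps 26900 L mol^-1 cm^-1 and MW 445 g mol^-1
  (cyanidin-3-glucoside equivalents). A negative corrected absorbance is
  clamped to zero with a warning rather than an error: it is a plausible
  reading at very low pigment with a noisy A653.

MDA is accepted as supplied and never derived: its assay is outside the
package's scope.

Path length defaults to the 1 cm cuvette convention because the quoted
extinction coefficients are per cm; microtiter plates with other effective
paths must override `path_length`. Pigments can be referenced per cm^2 leaf
area (default) or per g fresh mass.

## The ODAC index

Oxidative balance is summarized by the ratio of lipid-peroxidation damage
to summed antioxidant investment,

$$\mathrm{ODAC} = \frac{\mathrm{MDA}'}{\mathrm{POD}' + \mathrm{GR}' +
\mathrm{PHEN}' + \mathrm{ANTH}'},$$

computed on min–max normalized components (`x' = (x - min)/(max - min)`),
so the five ingredients contribute on a common 0–1 scale with equal
weight. The primary normalization is within each light environment (both
populations pooled per habitat); a global normalization across all samples
is provided as a robustness variant, and the package's own simulations
confirm the population contrast keeps its sign under both
(`odac_table(table, mode)`). Population-wise normalization is deliberately
not offered: it would erase the local-vs-foreign contrast the index
exists to expose. Because within-habitat scaling fixes each habitat's
range separately, cross-habitat ODAC magnitudes are flagged as
secondary; within-habitat population comparisons are the primary reading.

Two degenerate cases have explicit contracts: a constant component column
normalizes to 0.5 (configurable to an error) — the formula is 0/0 and the
midpoint preserves the equal-contribution intent without collapsing the
denominator — and a zero antioxidant denominator yields a flagged `NA`,
never a silent drop.

## Phenotypic plasticity

Per genotype and trait, the Valladares-style plasticity index

$$PI_V = \frac{|X_1 - X_2|}{X_1 + X_2}$$

contrasts the open-habitat value \(X_1\) with the shaded value \(X_2\); it
is 0 for identical expression and approaches 1 for maximal plasticity, and
is symmetric and scale-invariant. The domain is non-negative values rather
than strictly positive ones: a min–max normalized composite such as ODAC
is exactly 0 for the per-group minimum genotype, and the index is still
well defined unless both habitat values are 0 (then it is flagged `NA`).
`plasticity_comparison()` reports population means, CV% and a two-sided
Wilcoxon rank-sum test per trait, with star codes at strict boundaries
(`*` p < 0.05, `**` p < 0.01, `***` p < 0.001).

## The statistical engine

All procedures are implemented from first principles (base R supplies only
distribution tails) and cross-checked in the test suite against
independent enumeration oracles and the reference implementations in base
R and vegan:

* one-way and balanced two-way ANOVA by sums-of-squares decomposition; in
  the balanced 2 x 2 design Type I/II/III sums of squares coincide, which
  is why unbalanced input is refused outright rather than silently
  resolved with one SS convention;
* a two-sided variance-ratio F-test reported in the given group order
  (ratios below one are not inverted). The individual-variability
  comparison is phrased on CV% in the field, but a single CV per group
  admits no F-test; the implemented test compares raw group variances,
  which is the standard software reading;
* Wilcoxon rank-sum with midranks; the exact two-sided p-value comes from
  a subset-sum dynamic program over the rank-sum distribution (used up to
  N = 20 without ties), otherwise a tie-corrected, continuity-corrected
  normal approximation;
* Pearson correlation with the t transform; Spearman as Pearson on
  midranks with full n! enumeration of the permutation null up to n = 9;
* the Mantel test on vectorized lower triangles with simultaneous
  row/column permutation of the second matrix, seeded, defaulting to 999
  permutations and the one-sided "greater" alternative; full enumeration
  is available for small matrices;
* standardized OLS (z-scored response and predictors) with SEs, t and F
  statistics, refusing rank-deficient designs by naming the collinear
  columns.

No multiple-testing correction is applied by default: the analysis is
designed around consistent patterns across a-priori trait groups rather
than isolated borderline p-values, and raw p-values keep the report
auditable.

## The analysis pipeline

`run_full_analysis()` chains the stages: design validation, group
summaries (mean, SE = sd/sqrt(n) with the sample sd, CV% = 100 sd/mean),
ODAC under both modes, plasticity indices and their population
comparison, a two-way habitat x population ANOVA per trait (a significant
interaction flags population-specific plasticity), the two reciprocal
transplant batteries — "home vs. away" (each population across habitats)
and "local vs. foreign" (populations within each habitat), both one-way
ANOVAs with df = 1, N - 2 — cost-of-plasticity regressions, and
significance-filtered correlation networks with Mantel comparisons.

Decisions worth making explicit:

* mSLA, the performance proxy of the cost-of-plasticity regressions, is
  defined as the per-genotype mean of SLA across the two habitats — the
  only definition yielding one value per genotype for a per-population
  regression. SLA's own regression is marked self-referential and drops
  the redundant mean-SLA predictor;
* correlation analyses exclude Chl a and Chl b (keeping Chl tot and the
  a/b ratio) to avoid mathematically induced associations, and raw MDA
  (already inside ODAC). Edges are kept only at p < 0.05 and classed by
  |r| (> 0.80 thick, 0.60–0.80 thin); significant-but-weak edges stay in
  the machine-readable output for auditability even though displays
  typically omit them;
* Mantel comparisons follow the transplant structure — the two
  populations within each habitat, the two habitats within each
  population, and the two populations' Spearman matrices of plasticity
  indices — rather than an all-pairs sweep;
* report generators are pure functions of the trait table: row order and
  file naming never affect a statistic, and a rerun with the same
  configuration is byte-identical.

## The synthetic-data generator

Because the study's genotype-level data are not deposited, the generator
is the package's substrate for every downstream test. It emulates exactly
the design above: for genotype g of population p in habitat h the trait
value is a positive random variate with location

$$\mu_{p,\mathrm{open}}\,(1 + G_g)\,\bigl(1 + \delta_p (1 + PL_g)\,
\mathbb{1}[h = \mathrm{shaded}]\bigr),$$

where \(\delta_p\) is the relative habitat effect implied by the group
means, \(G_g \sim N(0, \sigma_G)\) a genotype intercept (default 0.05) and
\(PL_g \sim N(0, \sigma_{PL})\) a genotype-specific multiplier on the
habitat effect (default 0.30) that produces the crossing reaction norms
and occasional rank shifts characteristic of genetic variation in
plasticity. Dispersion matches per-group CV targets. The default group
means and CVs are the published genotype-level values for the two
*I. pumila* populations (`default_trait_means()`); they are the study
conditions, not tuning knobs.

Noise is lognormal by default — the traits are strictly positive and CVs
reach 40%, where a truncated normal would distort the mean — with a
truncated-normal alternative for sensitivity analysis. One global seed
feeds a per-trait substream keyed on the trait name, so adding or removing
a trait never perturbs the other columns, and identical configurations are
bit-for-bit reproducible.

Three couplings deserve note:

* Chl tot and the Chl a/b ratio are derived from the simulated Chl a and
  Chl b rather than drawn, so every table satisfies the additivity and
  ratio invariants. A consequence: the published group mean of the ratio
  (a mean of per-genotype ratios) differs by ~1–2% from the ratio of the
  published means, so the ratio column's zero-noise value is the latter;
* MDA is simulated as a baseline of 1 (arbitrary units) with CV 30% and a
  multiplicative elevation (`odac_offset`, default 1.78) for the Dune
  population. The default was calibrated once by Monte Carlo so that the
  open-habitat Dune:Woods grand-mean ODAC ratio under within-habitat
  normalization is about 3.9, the contrast implied by the published group
  means (0.51 / 0.13); realized group means land near 0.46 / 0.12;
* SLA, LDMC and SLWC are mutually constrained for any single leaf
  (SLWC = (1/LDMC - 1)/SLA) but are simulated as separate traits, as the
  published summary statistics themselves are only approximately
  consistent. `synthesize_raw_assays()` therefore emits two leaf records
  per sample — a structural leaf inverted from SLA + LDMC and a hydration
  leaf inverted from LDMC + SLWC — mirroring leaf-to-leaf variation; the
  zero-noise forward/inverse round trip is then exact (< 1e-9 relative)
  for all thirteen traits.

What the generator does not model: within-habitat microenvironmental
autocorrelation, within-genotype technical replication (the analysis
collapses to one value per genotype x habitat, as the study design did),
seasonal dynamics, and any genuine fitness component. Passing tests
demonstrate that the pipeline recovers structure the generator plants
under these idealizations; they cannot certify behavior on field data
with spatial structure or measurement artefacts.

## Numerical choices and test calibration

* Chlorophyll consistency cross-checks use a relative tolerance of 1e-6;
  the forward/inverse assay round trip is asserted at 1e-9 relative.
* Exact-test implementations are verified against brute-force enumeration
  (all rank-subset labelings for Wilcoxon at n1, n2 <= 6; all 120 rank
  permutations for Spearman at n = 5; all 24 simultaneous permutations
  for Mantel on 4 x 4 matrices) and against base R / vegan.
* Seeded recovery checks use 200 replicates at the reference effect
  sizes: the habitat effect on SLA is detected in >= 95% of replicates in
  both populations, and the ODAC population contrast (true open-habitat
  ratio ~3.9) in >= 90% by the local-vs-foreign ANOVA. Null calibration
  uses 1000 replicates with all effects flattened and iid noise
  (genotype random effects off, since the fixed-effects F null is what is
  being calibrated) and requires each two-way term to reject at
  0.05 +/- 0.02. These problem sizes keep the default suite under a
  minute while leaving the Monte-Carlo error well inside the asserted
  margins.
* The Wilcoxon power to separate population plasticity at the reference
  ODAC contrast (~1.7x with CVs of 50–90%) is limited at n = 10 per
  population (~0.3–0.45 in simulation); the corresponding test asserts
  preferential detection of a planted contrast over the false-positive
  background rather than near-certain detection.

## Known limitations

The two-way decomposition requires the balanced paired design; unbalanced
field data must be subset or analyzed per cell. The fixed-effects ANOVA
treats the two habitat records of a genotype as independent, as the
study framework does; with genotype intercepts present this is an
approximation (conservative for habitat terms, slightly liberal for
population terms). Pigment equations are only as good as their
configured coefficients. ODAC is a comparative index: its absolute value
depends on the normalization group and should not be read as a
mechanistic ROS quantity.
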