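---
title: "Dosage-QTL mapping of wood anatomy traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-QTL mapping of wood anatomy traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosetra)
```

## The problem

Irradiation-hybrid pedigrees in *Populus* carry large, genomically mapped
insertions and deletions. Each lesion changes local gene copy number, so
every F1 line is a natural dosage perturbation experiment. When a
quantitative trait — tree height, mean vessel diameter (MVD), vessel
frequency (VF), vessel grouping index (VGI), vessel circularity (MVC),
non-lumen fraction (NF), bark thickness (BT) — co-varies with local dosage
across lines, the region is a candidate dosage QTL (dQTL). `dosetra`
implements the full chain from segmented vessel tables and indel calls to
called dQTL regions, together with a calibrated synthetic population
generator so every stage can be validated without access to a physical
pedigree.

## The scan model

**Bins.** All indel start/end positions on a chromosome are pooled, sorted
and deduplicated; the half-open intervals between consecutive breakpoints
that are overlapped by at least one indel become genomic bins. Within a
bin, no line's copy number changes, so dosage is a single number per line
and bin. Genome coverage is the kept bin length over the genome length.

**Relative dosage score (RDS).** Copy number at a bin is the background
ploidy plus the number of overlapping insertions minus deletions for that
line; RDS divides by ploidy. A diploid line with a single-copy deletion
scores 0.5, an insertion 1.5, and unaffected lines 1.0. Lines without any
indel records are dosage-normal controls with RDS 1 everywhere.

**Association test.** At each bin the scan computes Kendall tau-b between
the RDS column and the trait (genotype means by default). A rank statistic
is the right choice here: RDS is massively tied (most lines are 1.0 at any
bin), tau-b's denominator corrects for ties on both sides, and the test is
invariant to any strictly monotone transform of the trait, so the optional
Box-Cox step cannot change the scan. The two-sided p-value uses the normal
approximation with the tie-adjusted variance of the concordance statistic
S; at two hundred lines exact enumeration is impractical and unnecessary.
The implementation counts pairs group-wise over the distinct RDS values,
which is exact and fast; tests verify exact agreement with brute-force
pair counting and with `stats::cor.test`.

**Multiplicity.** Contiguous bins are spanned by the same indels and are
strongly correlated, so a plain Bonferroni over all bins would be far too
severe. Instead, pairwise Pearson correlations between bin RDS columns are
turned into a dissimilarity `1 - r`, clustered with average linkage, and
the tree is cut at 0.7; the number of clusters is the effective number of
independent bins, and raw p-values are multiplied by it (capped at 1).
Signed `1 - r` (rather than `1 - |r|`) is used because insertions and
deletions give dosage correlations a meaningful sign; the cut height and
linkage are configurable. The count is computed once, genome-wide, and
shared by all traits. Bins with constant dosage have no defined
correlation and are treated as their own singletons.

**Regions and effect size.** Bins with adjusted p below alpha (default
0.05) are merged into regions when they are consecutive in the sorted bin
list on the same chromosome — physical gaps that contain no bin do not
split a region, matching how multi-bin dQTL are reported in practice. Each
region's representative bin is its minimum-adjusted-p bin (ties broken by
smaller start). Percent variance explained per trait is the adjusted
R-squared (floored at 0) of the linear regression of the genotype-mean
trait on the representative bins' RDS.

## Trait-level statistics

**Vessel morphometrics.** From a segmented vessel table (centroid, lumen
area, perimeter) per section: equivalent-circle diameter `2*sqrt(A/pi)`;
circularity `4*pi*A/P^2` (the standard particle-analysis shape factor;
records below the isoperimetric bound are rejected as segmentation
artifacts); VF as vessel count over xylem area; VGI as vessels per contact
group, where two vessels are in contact when their centre distance is at
most the sum of their equivalent radii plus a tolerance (default 1 um,
standing in for wall thickness since the input is a vessel table rather
than pixels) and groups are connected components of that relation. NF is
implemented as one minus the lumen fraction (mean lumen area times VF,
unit-reconciled): that is the quantity consistent with the trait's name,
its published range (about 0.66-0.91 with mean 0.8), and the fact that the
lumen fraction itself evaluates to roughly 0.19 at the published trait
means. All section-level means weight every vessel equally.

**Height correction.** MVD and VF scale allometrically with tree size, so
height-corrected adjuncts (cMVD, cVF) are the residuals of an OLS fit of
log10(trait) on log10(height). Residuals are exactly orthogonal to log
height; a line with a near-zero residual has the trait value expected for
its height.

**Box-Cox.** Traits are transformed only when a Shapiro-Wilk screen on the
trait rejects normality at 0.01 (the source analysis says "when
appropriate" without a criterion; a screen at a strict level keeps
well-behaved traits untouched). Lambda maximises the profile
log-likelihood on the grid -2 to 2 by 0.1. The decision and lambda are
recorded per trait in the scan object and the run log. Height-corrected
traits are already residuals and are never transformed.

**Heritability.** Broad-sense heritability is clonal repeatability from a
one-way genotype ANOVA: `V_g = (MS_geno - MS_error) / r_bar` with `r_bar`
the expected-mean-squares replicate coefficient `(N - sum(n_i^2)/N)/(k-1)`
— equal to the replicate count when balanced, and robust to ramet loss
when not; `H^2 = V_g / (V_g + MS_error)`, with negative `V_g` clipped to
zero. The 95% interval follows from F-distribution bounds on the
genotype/error variance ratio. No REML mixed model is fitted; the
estimator is deliberately the moment-based repeatability.

**ANOVA and post hoc.** Per-trait linear models with genotype and height
(and optionally their interaction) use sequential Type I sums of squares
in that order, the base-R convention. Tukey HSD pairwise comparisons come
with a compact letter display derived by insert-and-absorb from the
adjusted-p significance matrix.

**Correlations** are Pearson on genotype means (matching the granularity
of the heritability estimate and the scan), with t-distribution p-values
and the usual significance stars.

## The synthetic population generator

The generator's defaults describe the study population the package is
built around, and they are fixed: 201 genotypes, 173 of them carrying
lesions, three clonal ramets each, a 19-chromosome poplar-like genome of
about 390 Mb.

* **Indels.** Each lesion line draws `1 + Poisson(0.4)` indels (mean 1.4).
  Lengths are log-normal (median 8 Mb, log-sd 0.9) plus a 100 kb floor,
  truncated to the chromosome; starts are uniform; chromosomes are chosen
  proportional to length; insertions and deletions are equally likely.
  Same-line indels never overlap (a single irradiated gamete cannot lose
  one region twice); different lines overlap freely, which is exactly what
  creates shared bins. These values were chosen so the emergent bin
  structure matches the study: across seeds the generator yields roughly
  450-500 bins, 5-7 overlapping indels per bin, and >90% genome coverage.
* **Heights.** Tree height is hierarchical log-normal: a line effect plus
  ramet noise calibrated to a population mean of 64 cm and SD of 32 cm,
  with 45% of log-variance between lines, truncated at 1 cm. Lesion lines
  have their expected height multiplied by 0.75, reproducing the observed
  deleterious mean effect of carrying lesions.
* **Traits.** Each trait is `c * height^b + g + sum(effect * (RDS - 1)) + e`,
  with line-level genetic value `g ~ N(0, V_g)` and ramet noise
  `e ~ N(0, V_e)`. The allometric exponent `b` is solved in closed form
  from log-normal mixture moments so the model-implied height correlation
  hits the published values (+0.76 for MVD, -0.78 for VF, +0.52 for BT;
  zero for VGI, MVC, NF), and `c` is set so the trait mean matches the
  published mean. Given `b`, the residual variance is split into `V_g` and
  `V_e` by the configured heritability. `expected_th_correlation()`
  exposes the closed form and is the oracle for Monte-Carlo checks.
  Planted dosage effects shift the line value by `effect * (RDS - 1)`, so
  deletions and insertions push in opposite directions; one-sided effects
  (`del_only` / `ins_only`) emulate loci where only one direction is
  phenotypically visible. Trait values are floored at a tiny positive
  value to keep log transforms defined.
* **Cross-sections.** Vessels are placed as discs in a square xylem
  region; with clustering 0 all are solitary (separated by a safety gap
  larger than the contact tolerance), with clustering > 0 they form
  touching chains with geometric lengths capped by `max_group_size`. Each
  disc is jittered into a 48-gon whose shoelace area and edge-sum
  perimeter are the emitted measurements, so circularity is below 1
  whenever jitter is positive and the isoperimetric bound holds by
  construction.

What the generator does *not* emulate: irradiation physics and breakpoint
hotspots (placement is uniform), aneuploid or triploid lines (ploidy is
configurable but uniform by default, since the background ploidy
distribution of the real pedigree is not published), genotype-environment
interaction, spatial greenhouse effects, and measurement error structure
beyond i.i.d. ramet noise. Passing recovery tests therefore demonstrates
that the statistical machinery is correct under the stated model, not
that the model captures every feature of real pedigrees.

## Numerical choices and degenerate inputs

* Seeds fix all randomness; the trait stage offsets the configured seed by
  one so indels and traits are independently reproducible.
* Constant dosage columns are skipped by the tau test (flagged `NA`) and
  are singletons in the effective-bin clustering; copy numbers below zero
  (possible only with inconsistent inputs) are floored at zero with a
  warning.
* `MS_error = 0` gives `H^2` exactly 1 (or 0 when the genotype variance is
  also zero); collinear representative bins in the variance-explained
  regression are reduced to an independent subset with a warning.
* Region merging ties (equal minimum adjusted p) resolve to the smaller
  start coordinate.
* The NF computation clips to [0, 1] with a warning; valid vessel tables
  cannot leave the interval.

## Problem sizes used in validation

The shipped validation suite runs the population-scale checks at the study
shape (201 lines, 19 chromosomes) with 200 null replicates for the
family-wise error bound, 100 simulations for planted-effect recovery
(effects sized to 15% of genotype-mean variance at a typically covered
bin) and 100 simulations at 500 lines for heritability recovery; oracle
sweeps use about ten thousand tau cases and one hundred random interval
sets and sections. On the null simulations the observed fraction of scans
with any adjusted p below 0.05 sits near 0.10 rather than the nominal
0.05: the effective-bin Bonferroni is mildly anti-conservative under this
correlation structure, which is worth keeping in mind when interpreting
borderline regions.

## Known limitations

* The scan tests marginal dosage-trait dependence; it fits no kinship or
  polygenic background term and performs no interval mapping or
  permutation thresholding.
* Power collapses at bins carried by very few lines regardless of effect
  size — a rank statistic saturates when only two or three lines are
  informative. This mirrors the real design, where bins overlap 1-16
  indels.
* The effective-bin count depends on the configured cut height (0.7 by
  default); it is reported alongside results and should be read as a
  modelling choice, not an estimate with error bars.
* Variance explained by adjusted R-squared is a population-level summary
  conditional on the called regions; with weak signals it is biased
  toward small values by the flooring at zero.
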