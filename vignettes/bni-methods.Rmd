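---
title: "Methods: quantifying biological nitrification inhibition from root-exudate metabolomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying biological nitrification inhibition from root-exudate metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bniscreen)
```

`bniscreen` implements the quantitative chain of a root-exudate BNI
screen: genotype panels are assayed against ammonia-oxidizing bacteria
(AOB) and archaea (AOA), their exudate metabolomes are profiled by GC-MS
and LC-MS, and the two data views are integrated to nominate inhibitory
metabolites. This vignette documents the models, the tunable parameters
and the design decisions; it states no empirical result that the package's
tests do not themselves compute.

## Mass utilities

Annotation tables carry a molecular formula, an ion species, an observed
m/z and a reported ppm accuracy per metabolite. The theoretical m/z of a
singly charged adduct is

$$ m/z = \frac{M + \Delta}{|z|}, \qquad
   M = \sum_e n_e \, m_e^{\mathrm{mono}} $$

with monoisotopic masses C 12 (exact), H 1.00782503207, N 14.0030740048,
O 15.9949146196, P 30.97376163, S 31.97207100 Da. The protonated adduct
uses the **proton** mass 1.00727646688 Da (hydrogen-atom mass minus the
electron mass): this electron-corrected convention reproduces
high-resolution annotation m/z at the 4-decimal precision such tables
print, which the hydrogen-atom mass does not. `[M-H2O+H]+` additionally
subtracts one monoisotopic water. Display rounding is half-away-from-zero
at 4 decimals (`round_half_away`), matching how instrument software
prints m/z.

Reported ppm accuracies originate from unrounded instrument masses, so
they are treated as metadata rather than recomputable ground truth:
`annotate_records` recomputes ppm against the *printed* observed m/z and
flags rows whose recomputed value differs from the reported one by more
than 2 ppm. One worked annotation row (hydroferulic acid) prints a
formula whose water-loss adduct is ~10^5 ppm away from its printed m/z —
the printed m/z is only consistent with a different formula (C10H12O4).
The package records the row as given and flags it; it does not guess the
intent. Only CHNOPS elements are supported; anything else is an error,
never a silent zero mass. Isotope patterns, multiple charges and negative
mode are out of scope.

## The bioassay model

Ammonia-oxidizer activity is read out as nitrite accumulation.
`nitrite_from_absorbance` inverts an ordinary least-squares standard
curve (at least 3 standards), clipping negative predictions to zero with
a warning. The **ammonia oxidation inhibition percentage** is

$$ \mathrm{AOI\%} = \Bigl(1 - \frac{\overline{\mathrm{treated}}}
   {\overline{\mathrm{control}}}\Bigr) \times 100 , $$

either at a single timepoint (the AOA protocol) or from per-concentration
nitrite-vs-time regression slopes (`aoi_slope_based`, the AOB protocol
for linear kinetics). AOI% is unit-free, so rescaling nitrite units
leaves it unchanged. Values above the control give negative AOI% — growth
*stimulation* — and are never truncated; the synthetic generator bounds
them at −40% (there is no natural floor; −40 comfortably spans observed
stimulation while keeping the scale interpretable).

`fit_ec50` fits the four-parameter logistic
$\mathrm{AOI}(c) = b + (t - b)/(1 + (\mathrm{EC50}/c)^h)$ by bounded
Levenberg-Marquardt least squares on log10 concentration, with
$b \in [-40, 20]$ and $t \in [60, 110]$, from a 6-point multi-start grid
(3 location quantiles x 2 slopes) to avoid local minima. The reported
EC50 is where the *fitted curve* crosses 50% inhibition, which decouples
the estimate from boundary values of $b$ and $t$. When the fit fails or
never crosses 50%, the estimate falls back to log-linear interpolation
between the doses bracketing 50%; a series with no bracketing pair is an
explicit "EC50 not estimable" error. Series whose AOI never spans 50% are
flagged `extrapolated`.

Group comparisons follow standard nonparametric practice: Wilcoxon
rank-sum for two groups — the reported `W` is the **rank-sum of the
first-listed group** (not the Mann-Whitney `U`, which is also returned),
the convention under which published test statistics of order
n1 x n2 x replicates make sense — and Kruskal-Wallis with tie correction
plus Dunn's z-tests under Bonferroni adjustment for more groups, with a
compact letter display (insert-and-absorb). Heatmap clustering uses
Euclidean distance; the linkage is unspecified in common practice, so the
default is complete linkage, configurable, with leaf orders made
deterministic by reordering dendrograms against row/column ids.

## Preprocessing

GC-MS tables are normalized by root dry weight then log10(x+1)
transformed — division first, then the offset log, so exact zeros
("not detected") remain exactly zero. LC-MS tables are
*abundance-balanced*: each sample row is divided by its total intensity
and multiplied by the mean total, which equalizes row sums while
conserving total matrix intensity. The volcano contrast uses a **signed
ratio** convention: FC = mA/mB when A is enriched, −(mB/mA) otherwise,
so "FC ≤ −2" is meaningful without logs; significance is a two-sided
Wilcoxon rank-sum at P ≤ 0.01 with fold change ≥ 2. Venn membership
deems a feature present in a group when nonzero in at least 50% of that
group's samples (the fraction is configurable; common practice is
unstated, so the default is the midpoint rule). PCA is a centered
(optionally scaled) singular value decomposition. Genotypes are ranked by
mean AOI% across strains into quartiles Q1 (most inhibitory) to Q4, sizes
differing by at most one, ties broken by genotype id.

## Association screening

Spearman's rho is computed as the Pearson correlation of average ranks,
with a two-sided p from the t approximation on n − 2 degrees of freedom.
Flags use an effect-size *and* significance rule: positive when
rho ≥ 0.40 and p ≤ 0.05; negative cutoffs are strain-specific (−0.45 for
NF and NM, −0.40 for NV and NU). No multiple-testing correction enters
the flags — the screen is a thresholded effect-size filter, not a
familywise test — but a Benjamini-Hochberg column is emitted for
transparency. At n = 5–7 the t approximation deviates from the exact
permutation distribution by up to ~0.08 absolute; the package accepts
this (screens run at n ≈ 44, where the approximation is good).

## PLS networks

`fit_pls` is classical NIPALS two-block PLS in regression mode on
standardized blocks, deterministic up to sign; the sign is fixed by
forcing the largest-magnitude x-weight of each component positive, so
networks are reproducible across runs and platforms. Coefficients are
$B = W (P^\top W)^{-1} Q^\top$. The number of components is not dictated
by the screening design; the default is 2, typical for these ordination
plots, and configurable. Edge scores are mixOmics-style **relevance
similarities**: $\mathrm{sim}_{ij} = \sum_h \mathrm{cor}(x_i, t_h)\,
\mathrm{cor}(y_j, t_h)$ over the latent components, clipped to [−1, 1] —
the correlation between variable and response as transmitted through the
latent space. Networks retain edges with |sim| at or above per-strain
cutoffs 0.40 (NF), 0.35 (NV), 0.38 (NM), 0.45 (NU); the quartile PLS-DA
network defaults to 0.40 (reported practice for such networks varies
between 0.35 and 0.40; 0.40 is the stricter choice and both are one
argument away). PLS-DA one-hot-encodes the quartile assignment as the
response block and classifies training genotypes by the largest fitted
class score. Whether such networks are built from relevance scores or raw
correlations varies across studies; both are available here
(`pls_similarity` vs. plain `cor`), relevance being the default because
it matches the "correlation cut-off on a PLS network" description.

## GA + CCA combinatorial selection

A genetic algorithm searches metabolite **triplets**; the fitness of a
triplet is the canonical correlation between its (standardized)
abundances and the strain's AOI% vector.

* **Linear backend** (default for testing and batch runs): the canonical
  correlation of a 3-column block with a single response is the multiple
  correlation $\sqrt{R^2}$ of the regression of the standardized response
  on the block, computed in closed form.
* **Deep backend**: two small encoders (default hidden layers 16-16,
  tanh, scalar latents) trained by full-batch Adam (300 epochs, learning
  rate 1e-2) to maximize the correlation of their latent outputs, with a
  small ridge (1e-4) on the latent variances for numerical stability.
  The fitness is the absolute final training correlation; the *absolute*
  value is used because the direction of the latent axis is arbitrary.
  Fitness is evaluated on the full data rather than held out: the 80/20
  resplits serve as a *stability check of the rankings*
  (`stability_check`), not as fitness estimation. Initialization is
  seeded, so fitness is bit-reproducible.

The GA (per repetition: population 40, 30 generations, tournament
selection of size 3, uniform crossover with duplicate repair, per-slot
mutation 0.10 replacing a slot with a uniformly random unused metabolite,
elitism 2) records the single best triplet; repetition r is seeded
`seed + r`. Frequencies count **best-triplet memberships only** — the
observed frequency ceiling (about 30 in 200 repetitions in published
screens) is consistent with top-1 counting and inconsistent with counting
whole final populations — so frequencies sum to exactly
3 x repetitions. Two selection tiers are reported: `selected` at f > 10
(the headline threshold) and `highlighted` at f ≥ 5 (the supplementary
tier); published descriptions use both, so both are kept. Fitness values
are memoized per sorted triplet across repetitions.

All multivariate stages (PLS and the GA) consume log10(x+1) abundances:
raw MS intensities are log-normal over several decades and their linear
second moments would be dominated by a handful of extreme values.

## The synthetic-study generator

The generator defines the study conditions the tests exercise. Defaults
emulate the screen's shape: 44 genotypes split 20/24 between two origin
groups, 357 annotated metabolites in 12 chemical classes, strains NF and
NV (AOA) and NM and NU (AOB). Abundances are log-normal — per-metabolite
log10 means from U(3, 7), per-class log10 sd from U(0.2, 0.6) — with 10%
of entries zeroed ("not detected", supporting presence/absence logic),
origin-shifted metabolites getting +1 log10 unit in group A (a ten-fold
enrichment, comfortably beyond the two-fold volcano threshold), and root
dry weights from U(0.2, 2.0) g.

Inhibition is built from the standardized log abundances $z$ through a
logistic squashing $\sigma(z)$ (abundance effects saturate — doubling an
already-abundant inhibitor cannot double its effect):

$$ \mathrm{AOI}_{gs} = \mathrm{clip}\Bigl( \sum_{m \in \mathrm{active}_s}
   w_m \sigma(z_{gm}) + w_{\mathrm{syn}} \prod_{m \in \mathrm{triplet}}
   \sigma(z_{gm}) + \sum_{m \in \mathrm{stim}} w'_m \sigma(z_{gm}) +
   \varepsilon, \; -40, 100 \Bigr) $$

with cell noise sd 5 AOI units and replicate noise sd 2 over 3
replicates. Synergy is **multiplicative** — triplet members are
individually weak but jointly strong, exactly the structure combinatorial
selection must detect and marginal screens miss; an additive-only switch
exists for ablation. The default truth plants one shared synergistic
triplet (weight 60), three additive inhibitors per strain (weights
20–40), one stimulator per strain (−15), and 20 origin-shifted
metabolites.

Two weight regimes matter. At the default $w_{\mathrm{syn}} = 60$ the
synergy contributes at most ~40 AOI points (the triple product rarely
exceeds 0.7) with sd ≈ 7 against noise sd 5 — detectable but not
dominant, and on some data realizations an overfit null triplet
out-scores the planted one at n = 44, as verified by exhaustive
enumeration of all triplets. The *dominant-synergy* regime used by the
recovery validation sets $w_{\mathrm{syn}} = 120$ (the triplet at
saturation approaches complete inhibition, an order of magnitude above
the noise); there the GA with the linear backend recovers all three
planted members in the top-5 frequency ranks in 10 of 10 master seeds
(50 repetitions each). Dose-response series accumulate nitrite linearly
in time at a dose-dependent rate — four-parameter-logistic inhibition for
"sigmoidal" kinetics, a linear ramp crossing 50% at the EC50 for
"linear" — with multiplicative replicate noise.

What the generator does **not** emulate: correlated metabolite modules
(biosynthetic pathways), heteroscedastic or batch-structured measurement
error, missingness that depends on abundance, strain-specific
dose-response shapes, or real chemical identities. Passing tests
therefore demonstrate correctness of the *computations* and
recoverability of *planted* signal under idealized noise; they do not
certify discovery performance on real exudate data.

## Null behavior of the GA

On a fixed dataset with no planted signal, the best triplet by canonical
correlation still exists — at n = 44 and 200 metabolites the best null
triplet reaches R ≈ 0.7 by overfitting — and a functioning optimizer
finds it reproducibly, so selection frequencies on a single null dataset
*concentrate* rather than spread uniformly. Uniform frequencies under the
null are a property of independent null realizations (fresh noise per
repetition), not of repeated searches on one realization. The practical
safeguard the package offers is `stability_check` (does the ranking
survive resplitting the genotypes?) together with the permutation
comparison of fitness values; a high GA frequency alone, without
stability, is not evidence.

## Numerical and reproducibility choices

* All randomness flows from integer seeds through R's default generator;
  repetition and stage seeds are derived additively and recorded in the
  pipeline manifest, and two runs with the same config are byte-identical
  (hashes compared in the tests).
* Quartile and leaf-order ties break by id; PLS signs are fixed
  deterministically; GA triplets are stored sorted.
* Constant metabolite columns: correlation undefined — flagged `ns` with
  a warning in the screen, dropped with a warning from CCA fitness.
  Constant responses are errors.
* Zero-variance calibration standards, all-zero abundance rows, empty
  formulas, unknown elements, unknown ion species, missing weights and
  truth entries referencing absent metabolites are all explicit errors
  naming the offender.
* Default problem sizes in the tests (e.g. 100–200 metabolites, 50 GA
  repetitions, 10 master seeds) were chosen to exercise the full study
  shape at n = 44 genotypes while keeping a complete run of the suite in
  the minutes range on a single core.

## Known limitations

* The deep CCA backend supports scalar latents only; multi-dimensional
  latents would need whitening-based objectives and are not required for
  a single activity vector.
* The EC50 fallback interpolates on log concentration between bracketing
  doses; with strongly non-monotone AOI it inherits that noise.
* The t-approximation p of the Spearman screen is coarse below n ≈ 10
  (see above).
* GA frequencies on a single dataset concentrate under the null (see
  above); interpret them jointly with `stability_check`.
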