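---
title: "Measuring 1,6-hexanediol sensitivity: models, parameters and design choices"
author: "hexasense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 1,6-hexanediol sensitivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexasense)
```

# The measurement problem

1,6-hexanediol (1,6-HD) dissolves condensates maintained by weak
hydrophobic interactions. Treating cells with it and asking *what falls
off chromatin* (quantitative proteomics) and *what structure relaxes*
(Hi-C) turns condensate dependence into two measurable quantities. This
vignette explains the models implemented in `hexasense`, the defaults and
their units, the synthetic-data generators used to validate every stage,
and the places where the design was genuinely open and a choice had to be
made.

# The proteomics arm: AICAP

## Pipeline

Protein-level iBAQ abundances pass through four steps
(`aicap_pipeline()` composes them):

1. **Fraction of total** (`ibaq_to_fot()`): each protein's iBAQ divided by
   its sample's summed iBAQ, times $10^6$. This removes per-sample loading
   and depth; present values in each sample then sum to exactly $10^6$.
2. **Minimum-value imputation** (`impute_missing()`): each missing cell
   receives the *minimum present value of its own sample column*. Missing
   label-free values are overwhelmingly left-censored (below the detection
   floor), which is what imputing at the floor presumes. The floor is
   per-sample rather than global because detection limits vary between
   runs; with a shared floor the choice is immaterial.
3. **Quantile normalization** (`quantile_normalize()`, via
   `limma::normalizeQuantiles`): rank $r$ in every column receives the
   mean of the columns' $r$-th order statistics; tied values share the
   average of their tied ranks' targets.
4. **AICAP + significance** (`compute_aicap()`): the ratio of mean
   normalized FOT, treated over control, with a two-sided Welch two-sample
   $t$-test. Replicates are averaged rather than paired because batch
   pairing carries no information after quantile normalization. Proteins
   with a zero control mean have no defined ratio; they are flagged and
   excluded from rankings.

Sensitivity groups (`assign_aicap_group()`) use six left-closed bins
$[0,0.3), [0.3,0.5), [0.5,0.7), [0.7,0.9), [0.9,1.1), [1.1,\infty)$: the
lowest bin is anchored at the conventional "highly sensitive" range
(Mediator-class proteins sit near 0.07, bromodomain proteins near 0.5),
the remaining edges continue in 0.2-wide steps symmetric around 1, and
everything above 1.1 — predominantly cytoplasmic background — is pooled.

## What a compositional index can and cannot measure

AICAP is a *compositional* quantity: FOT only knows relative abundance,
and quantile normalization afterwards forces every sample onto a common
distribution. Two consequences are worth stating explicitly because they
shape both the synthetic-data generator and what validation can promise:

* **A uniform change is invisible.** If every protein were depleted
  two-fold, FOT (and hence AICAP) would read 1.0 everywhere. The index
  measures depletion *relative to the bulk*, and is interpretable as
  per-protein depletion exactly to the extent that the bulk of chromatin
  mass (histones and other structural proteins) is unaffected — which is
  the observed biology.
* **Rank-preserving effects are erased.** Quantile normalization maps
  values through their ranks. In the degenerate case where the planted
  effect is comonotone with abundance (every protein's depletion a
  monotone function of its abundance), treated ranks never change and the
  normalized index reads 1.0 for everyone. Real effects are not rank
  order-preserving, but simulations must avoid this degeneracy
  deliberately.

Quantitatively, on synthetic data the raw ratio-of-means estimator
recovers planted depletion with Spearman rank correlation 0.97–0.99,
while the full pipeline (quantile normalization plus minimum imputation
at 20% missingness) plateaus at about 0.83–0.89: the rank-to-value warp
of quantile normalization costs roughly 0.05 whenever a substantial
minority of the proteome shifts, and proteins censored in *both*
conditions are pinned near AICAP 1 by floor imputation. These are
properties of the published normalization scheme itself, not of this
implementation; the test suite asserts the measured behavior and the
acceptance checks record it.

## The synthetic quantification experiment

`simulate_quant_experiment()` draws, per protein, a log-normal abundance
(`meanlog = log(1e6)`, `sdlog = 2` — an iBAQ dynamic range of several
orders of magnitude, as in real label-free data) and a planted response
factor $d$: treated expectation $= d \times$ abundance. Defaults encode
the study conditions:

* **Three replicates per condition** (biological duplication batches),
  multiplicative log-normal noise with CV 0.2.
* **Response factors** log-symmetric around 1 (`sdlog = 0.9`, clipped to
  $[0.02, 3]$): condensate proteins lose association ($d<1$, down to a
  few percent retention) while cytoplasmic background proteins gain
  relative abundance ($d>1$), matching the roughly two-decade span of
  observed indices. The exactly-insensitive block ($d = 1$, 20% of
  proteins) is assigned to the *most abundant* proteins, emulating the
  histone-dominated insensitive bulk that keeps sample composition
  approximately conserved.
* **Missingness** is abundance-dependent (missing-not-at-random): a cell
  goes missing with probability $\sigma((\mu-\log v)/s)$, $s = 0.5$, and
  $\mu$ is calibrated by root finding so the expected overall missing
  rate is 20%. Censoring on the *realized* (depleted, noisy) value makes
  treated cells of depleted proteins more often missing — informative
  left-censoring, which minimum imputation then handles as designed.

What the generator does **not** emulate: peptide-level identification and
roll-up, batch effects beyond i.i.d. noise, interference/ratio
compression, or correlation between proteins. Passing tests therefore
demonstrate the pipeline's algebra and its recovery behavior under clean
MNAR censoring, not robustness to every failure mode of real MS data.

## Enrichment and residue composition

`preranked_enrichment()` implements the weighted Kolmogorov–Smirnov
running sum on the ascending AICAP ranking with hit weight
$\max(1-\mathrm{AICAP}, 0)$ (weight exponent 1) and miss decrement
$1/(N-N_\mathrm{hit})$; significance comes from membership-label
permutations, reported as $(1+\#\{|ES_\pi|\ge|ES|\})/(1+n_\mathrm{perm})$.
The weight metric saturates at 0 for AICAP $\ge$ 1 on purpose: the
sensitive end is the only directional hypothesis.

`residue_composition_correlation()` computes, for proteins with AICAP
below 1, each amino acid's fraction within four region classes (whole
sequence, sequence minus IDRs, IDRs, prion-like domains; regions given as
0-based half-open intervals) and the Spearman correlation (average ranks)
with AICAP. Proteins lacking a region class drop out of that class only;
residues absent everywhere report an undefined correlation rather than 0.

# The chromatin-structure arm

## The synthetic Hi-C model

`hic_truth()` + `simulate_hic_pair()` draw Poisson counts with expectation

$$\lambda_{ij} \;=\; D\, b_i b_j\, (|i-j|+1)^{-\alpha}\,
\bigl(1 + c_i c_j \sqrt{\delta_i \delta_j}\bigr)\, T_{ij}\, L_{ij}\, S_{ij}$$

with per-bin biases $b_i$ (log-normal, `bias_sdlog = 0.2`), decay exponent
$\alpha = 1$ (the canonical fractal-globule slope), compartment signs
$c_i \in \{\pm 1\}$ in alternating blocks of 5–15 bins with per-bin
strength $\delta_i$ (default 0.3), a within-TAD factor $T$ (default 2,
TADs 10–25 bins or an explicit partition), loop factors with a Gaussian
spill of $\sigma = 0.5$ bins (so aggregate analysis sees a peak, not a
delta function), and stripe lines. $D$ scales the expected upper-triangle
total to `depth`. Poisson (not negative-binomial) counts are the simplest
model consistent with raw Hi-C; overdispersion is future work. The
"after" condition shares the layout and the random stream — a paired
design — and differs only through perturbed parameters; the default
perturbation halves $\delta_i$ on A bins (active compartments weaken) and
drops the loop factor from 10 to 4 (a 60% loop-signal reduction).

Not emulated: trans contacts, ligation artifacts, read-level processing,
copy-number variation, and TAD nesting.

## Balancing, expected model, compartments

`kr_balance()` computes weights $w$ with the Knight–Ruiz Newton iteration
(inner conjugate gradient) so that $w_i\,\mathrm{raw}_{ij}\,w_j$ has unit
row sums over unmasked bins; a damped symmetric Sinkhorn fixed point is
the fallback, and non-convergence is an explicit error naming the
chromosome. Defaults: `tol = 1e-6` on the row-sum deviation,
`max_iter = 3000`, and bins with fewer than `min_nnz = 10` nonzero pixels
masked (the standard low-coverage guard; small synthetic matrices use a
lower value). The expected model in `observed_over_expected()` is the
per-chromosome, per-distance mean of balanced values with no smoothing —
the plainest reading of observed-over-expected.

`call_compartments()` takes the leading eigenvector of the Pearson
correlation matrix of O/E rows, orients it by correlation with a
gene-density reference (A compartments are gene-dense), and returns it at
unit norm together with its leading eigenvalue. For cross-condition
comparison, `classify_compartment_change()` multiplies each profile by
$\sqrt{\lambda_1}$ — the principal-component *score* scale. This is the
one genuinely open design point in the compartment arm: eigenvectors are
defined only up to scale, yet the PC1-ratio rule needs magnitudes
comparable across libraries. Rescaling each vector to unit variance
(an obvious alternative) silently deletes any library-wide strengthening
or weakening — a uniform 30% gain would classify as "stable" everywhere —
so the eigenvalue-carrying scale is used instead; profiles built by hand
without an eigenvalue are compared as given. The rule itself: opposite
signs → flipped; otherwise $r = \mathrm{PC1}_\mathrm{after} /
\mathrm{PC1}_\mathrm{before}$, stable for $0.8 \le r \le 1.2$ (the
boundaries read inclusively), strengthened above, weakened below; zero or
missing PC1 → undefined, excluded from reported fractions.

A structural caveat measured during development: a Pearson correlation
matrix of noiseless rank-one compartment structure saturates at $\pm 1$,
so per-bin strength is invisible to PC1 in the high-depth limit.
Directional recovery of an A-only weakening is therefore a
moderate-depth phenomenon; the property test plants $\delta = 0.7$ on
300 bins at $3\times10^5$ counts, where a majority of A bins classify
weakened and a majority of B bins stable.

## Insulation and TADs

`insulation_profile()` slides a `window` × `window` square (default 1 Mb,
i.e. 25 bins at the conventional 40 kb resolution) along the diagonal:
the raw score of bin $i$ is the mean balanced signal between the windows
left and right of $i$; bins within a window of the edge, or whose square
touches a masked bin, are undefined; the reported track is
$\log_2(\mathrm{raw}/\text{chromosome mean})$. `call_boundaries()`
reconstructs the classic insulation-script behavior: the delta vector is
the right-window mean minus the left-window mean of the score over
200 kb; candidate boundaries sit at negative-to-positive zero crossings
(score minima; of the two crossing bins the one with the lower score is
taken); boundary strength is the delta amplitude
$\max_{[i,i+d]}\Delta - \min_{[i-d,i]}\Delta$, filtered at 0.1. The
strength formula is a behavioral reconstruction — the reference script's
internals are not published alongside the cutoff — so only the cutoff
value is treated as fixed.

`match_boundaries()` pairs boundaries across conditions greedily, closest
centers first (ties to the leftmost), each at most once, within
`slop = 80 kb` (two 40-kb bins); unmatched before-boundaries are lost,
unmatched after-boundaries gained. Greedy matching is symmetric in the
sense that swapping inputs swaps lost and gained.

`tad_interaction_change()` pools subcompartments as A1 | A2+B1 | B2+B3 by
default (neighboring classes with similar chromatin character; the
grouping is an argument), assigns each TAD its majority-overlap
subcompartment, and reports after/before ratios of depth-normalized
contact probability within TADs and between *different TADs of the same
group*, capped at 10 Mb separation so the inter-TAD sum is not dominated
by ultra-long-range noise. Cross-group pixels are skipped entirely.

## Loops and stripes

`loop_signal_change()` evaluates contact probability (balanced value over
total balanced sum — the depth normalization that makes libraries of
different sizes comparable) at each loop pixel, anchors mapped to bins by
midpoint, and reports per-loop after/before ratios plus their mean;
masked or zero-baseline loops are flagged, not silently dropped.

`apa()` averages $(2h+1)\times(2h+1)$ O/E windows (default $h = 10$)
centered on loop pixels, drops loops whose window leaves the matrix or
crosses the diagonal, optionally splits by a loop attribute with each
group divided by its own loop count, and scores the center against the
mean of the $h \times h$ corner block below-left of the center (the
standard aggregate-analysis background). Working on O/E rather than raw
counts cancels distance decay, which is what makes windows at different
distances addable. On planted factor-10 loops the measured center
enrichment is ~8.6–8.9: balancing and the loop's own contribution to the
per-distance expectation absorb a modest share of the raw factor, a
known property of balanced aggregate analysis rather than a bias of this
implementation.

`stripe_aggregate()` reads the O/E profile along a stripe (row for
left-anchored, column for right-anchored, `extent` bins), averages over
stripes, and takes as background the same profile offset ±5 bins
perpendicular to the stripe — a construction chosen here, since stripe
aggregation geometry has no published standard. The same balancing
attenuation applies: a planted raw factor of 3 reads out near 2 after
the anchor row's weight absorbs part of its excess; on matrices balanced
with identity weights the construction recovers the factor exactly.

`differential_loops()` follows pair-to-pair overlap semantics: both
anchors expanded by 10 kb, order-preserving (anchor1 against anchor1),
same chromosome pair; a before-loop with no overlapping after-loop is
lost. `classify_loops_by_stripe()` counts plain overlaps of the two loop
anchors with stripe-anchor intervals (no slop) into both/one/none.

# FRAP

`normalize_trace()` subtracts the extracellular background from both
channels, divides bleached by unbleached control at each time point
(cancelling acquisition photobleaching — the order of operations,
background first, is a choice; the ratio makes it immaterial for common
drift), and rescales so the pre-bleach mean (3 baseline frames) is 1.
`fit_frap()` fits $A(1-e^{-t/\tau}) + y_0$ to post-bleach points by
bounded Levenberg–Marquardt least squares with $t = 0$ anchored at the
first post-bleach frame, so $y_0$ is literally the first post-bleach
intensity. Start values: $A_0$ = last minus first intensity, $y_{0,0}$ =
first intensity, $\tau_0$ = first time the trace passes half-recovery
(fallback: a third of the span); bounds $A \in [0,2]$,
$\tau \in (0, 10\,\mathrm{span}]$, $y_0 \in [0, 1.5]$. Flat traces return
$A = 0$ with an explicit `wide_tau` flag instead of an arbitrary time
constant. The half-time is reported analytically as
$t_{1/2} = \tau \ln 2$. `mobility_regression()` is ordinary least squares
of mobile fraction on AICAP with the slope's two-sided $t$ test.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; BED/BEDPE/bedGraph keep
  their native conventions on disk; interval midpoints use
  $\lfloor(start+end)/2\rfloor$.
* Quantile-normalization ties get averaged targets; note this means
  sorted columns are bit-identical only on tie-free data — with ties
  (e.g. after imputation) the averaged targets legitimately differ per
  column.
* Welch (unequal-variance), two-sided $t$ tests throughout; a protein
  constant in both conditions gets $p = 1$ when means agree.
* Bin-state assignment is by majority overlap, ties to the state first
  seen in the file.
* KR non-convergence and empty/malformed inputs raise errors naming the
  offending object; they are never silently patched.

# Problem sizes

The shipped tests and the acceptance script run on 500-protein tables
with 3 replicates, single chromosomes of 160–300 bins at 10–100 kb, total
depths of $3\times10^5$–$2\times10^6$ contacts, 100-seed FRAP noise
calibrations, and 100–1000 enrichment permutations — sizes at which every
planted structure is comfortably recoverable and the full suite runs in
seconds while exercising the same code paths a genome-scale analysis
would.

# Known limitations

* The compartment eigenvector uses PC1 only; on real chromosomes whose
  PC1 tracks arms rather than compartments a PC2 fallback would be
  needed.
* Poisson counts understate the variance of real Hi-C replicates.
* AICAP's compositional ceiling (section above) bounds rank-recovery of
  per-protein depletion under the published normalization; analyses that
  need absolute depletion require spike-in normalization, which is out of
  scope here.
* Stripe detection itself is not implemented — stripes are consumed as
  annotated inputs, and only their aggregation is provided.
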