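---
title: "Mapping auditory temporal-processing deficits to lesion anatomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping auditory temporal-processing deficits to lesion anatomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlsmpipe)
```

## The problem

After a left posterior temporal stroke, some patients lose the ability to
resolve rapid auditory events: they need hundreds of milliseconds to judge
the order of two tones that healthy listeners separate at tens of
milliseconds, and their speech perception degrades selectively for phonemic
contrasts carried by fast spectro-temporal fine structure (place of
articulation), while slower cues (voicing, manner) survive. The analysis
chain in this package links such behavioral deficits to lesion anatomy:

1. estimate temporal thresholds with adaptive staircases,
2. compare groups with non-parametric tests and standardized effect sizes,
3. classify patients as deficit-positive (LG+) or -negative (LG-) by a
   2-SD rule against controls,
4. relate lesion status to group membership voxel by voxel (Liebermeister
   test) with max-statistic permutation FWE correction, and
5. post-process tractography streamline counts seeded in the significant
   region.

Because clinical lesion/behavior data of this kind are access-restricted,
the package ships a synthetic cohort generator with a known ground truth, so
every stage can be validated by parameter recovery rather than by eyeballing
maps.

## Adaptive staircases and the 79.4% level

Both psychophysical tasks control the stimulus onset asynchrony (SOA)
between two complex tones with a transformed up-down rule: three consecutive
correct responses lower the SOA, one error raises it, and a run terminates
after eight reversals of movement direction; the threshold is the mean SOA
at the last five reversal points. At equilibrium the probability of a
decrease equals that of an increase, so the tracked proportion correct
solves $p^3 = 1/2$:

```{r}
convergence_level(3)
```

i.e. the 79.4% correct level. Simulated observers have logistic psychometric
functions in log-SOA,
$P(\mathrm{correct}) = \gamma + (1-\gamma-\lambda)\,
\mathrm{logistic}(\beta(\log s - \log m))$, with guess rate $\gamma = 0.5$,
lapse rate $\lambda$, midpoint $m$ (ms) and slope $\beta$ per log-ms
(default 8, a steep but realistic slope for temporal-order judgments;
lapse default 0.02).

Two numerical choices matter:

* **Reversal bookkeeping.** A reversal is a change of *realized* movement
  direction. Moves fully absorbed by the 2 ms floor or 1000 ms ceiling
  produce no realized movement and never count, which prevents spurious
  reversal chatter when a degenerate observer pins the staircase at a bound.
  An incorrect response is *not* itself counted as a reversal.
* **Step asymmetry.** The published task configurations use fixed,
  strongly asymmetric steps (task 1: 50 ms down / 5 ms up; task 2:
  20 ms down / 2 ms up). With a 10:1 step ratio the 3-down/1-up rule has no
  equilibrium at 79.4% — zero average drift would require
  $p^3 = s_\mathrm{up}/(s_\mathrm{up}+s_\mathrm{down}) = 1/11$, a level
  below chance — so the staircase drifts toward the floor and the
  last-reversal average systematically *underestimates* the 79.4%-correct
  SOA (by roughly 40–60% for control-range observers in our simulations).
  The package reproduces the published configurations exactly
  (`task1_config()`, `task2_config()`), and its test suite demonstrates
  both facts: with symmetric steps the estimator recovers the
  79.4%-correct SOA to within a few percent, and the long-run percent
  correct converges on $0.5^{1/3}$; under the asymmetric configuration the
  same estimator is biased low. The asymptote simulations therefore use
  symmetric 2 ms steps, which probe the response rule rather than the step
  geometry. Users estimating thresholds for new experiments should prefer
  (near-)symmetric steps.

The safety cap (`max_trials = 1000`) guarantees termination for degenerate
observers; such runs are flagged non-converged and their threshold is
reported as missing, never extrapolated.

## Non-parametric statistics and effect sizes

Group comparisons use the Mann-Whitney U (mid-ranks; exact p by the full U
null distribution when the pooled sample is at most 20 without ties),
within-group contrasts the Wilcoxon signed-rank test (zero differences
dropped; exact p by enumerating all $2^m$ sign patterns for up to 15
non-zero pairs, which remains valid under ties in $|d|$), omnibus
repeated-measures effects the Friedman chi-square with tie correction, and
monotone associations one-sided Spearman correlations. Effect sizes follow
the $r = |Z|/\sqrt{N}$ convention with the normal-approximation $Z$
computed *without* continuity correction and with the untied variance in
the $U \to Z$ mapping — the convention under which published triplets such
as $U = 114$ (12 vs 12) $\to r = 0.495$ reproduce exactly:

```{r}
effect_size_r(u_to_z(114, 12, 12), 24)
```

$N$ is the pooled sample size for between-group or pooled analyses and the
group size for within-group analyses. A known edge: for tied data the
tie-corrected variance changes $Z$ slightly, so published values computed
from unavailable raw data with heavy ties may differ in the third decimal.
Bonferroni adjustment is plain $\alpha/k$.

## Deficit classification

Each patient's score on five subtests (temporal-order threshold,
micropattern threshold, word/pseudoword/phoneme error rates — all oriented
worse-high) is z-transformed against the control mean and SD. A patient
impaired (z strictly greater than +2, one-sided: only *worse* performance
counts) on at least two subtests is LG+; everyone else is LG-. Borderline
z exactly equal to 2 does not count as impaired. Missing subtests count as
not impaired, and feature-level error rates are deliberately excluded from
the rule. The rule is monotone: improving any score can never move a
patient from LG- to LG+.

## Voxelwise Liebermeister mapping with permutation FWE

Within the analysis mask (voxels lesioned in at least one patient — voxels
no lesion touches carry no information), each voxel's 2×2 table of lesion
status against LG+/LG- membership is scored with the Liebermeister
quasi-exact measure: the one-tailed hypergeometric tail probability of the
table augmented by +1 on the concordant diagonal. This is slightly less
conservative than Fisher's test and is the standard choice for binary
lesion-symptom data. p-values map to z via $z = \Phi^{-1}(1-p)$, positive z
meaning lesion more frequent in LG+ (the opposite tail is available via
`direction = "negative"`).

Family-wise error is controlled by the single-step max-statistic
permutation method: group labels are permuted, the maximum z over the mask
recorded, and the critical z taken as the smallest observed max-statistic
value whose exceedance proportion is at most $\alpha$ — conservative under
ties, and every corrected p is at least $1/M$. When the number of distinct
relabelings $\binom{n}{k}$ does not exceed the requested permutation count
the enumeration is exhaustive; for the 12-patient 6/6 split,
$\binom{12}{6} = 924 < 4000$, so the conventional request of 4000
permutations silently becomes an exact test with zero Monte-Carlo error
(requesting more permutations than distinct relabelings exist cannot be
honored and is logged in the result as `exhaustive = TRUE`). Voxels
reaching the critical z form the seed mask, whose 26-connected components
are labeled and sized for downstream tractography.

## Tract-map post-processing

Streamline visit counts from probabilistic tractography are divided by the
waytotal (samples per voxel × seed voxels), thresholded at $\tau$ of the
total — default $\tau = 10^{-9}$, the fraction reading of the conventional
"$10^{-7}$ percent" cut, which for waytotals near 4 million keeps every
voxel visited by at least one streamline; the percent reading is available
via `tau_is_percent = TRUE` — then binarized. Zero-count voxels are never
retained, so thresholding is idempotent and monotone in $\tau$. Per-subject
binary maps are averaged into a group variability map (fraction of subjects
per voxel, 0.0–1.0) and displayed above a strict 75% cut; averaging
precedes the cut, so the full fraction map is retained alongside the
display mask.

## The synthetic cohort and what it does (not) show

`cohort_config()` fixes the study conditions: 12 patients (6 with the
deficit) and 12 controls on a 32³ voxel 1-mm grid; a spherical critical
region of radius 3 at a posterior-temporal-like locus; control
temporal-order thresholds 15–60 ms (micropattern 5–40 ms) on a log scale
with a shared latent factor (weight 0.6) correlating the two thresholds; a
deficit multiplier of 10 placing deficit thresholds in the 150–600 ms
patient range; baseline feature error rates of 0.08 with a +0.35
place-of-articulation increment (half on the combined place+voicing
feature) for deficit observers; lognormal measurement noise with CV 0.08.
Rates are clipped to [0, 1] after incrementing.

Lesions are coherent blobs: an ellipsoid level-set deformed by smoothed
Gaussian noise, thresholded, largest 26-connected component kept. Deficit
lesions are centred on the critical region (jitter SD 1 voxel) with radii
`critical_radius + [1, 4]`, so each covers the region (coverage at least
50% is enforced, with union as a last resort) while their margins vary
individually — the territory shared by all deficit lesions, which is what a
perfect-association voxel map recovers, then approximates the region
itself. Non-deficit lesions (radii 5–9) are displaced away from the region
and cover at most 10% of it. With six LG+ patients, a voxel must be
lesioned in all six and intact in all six LG- patients to reach the exact
critical z, so recovery hinges on that intersection structure, not on the
50% coverage floor alone.

The generator reproduces the *statistical* structure the analysis assumes —
not vascular-territory anatomy, MRI intensities, registration error, or
lesion-volume confounds. Passing recovery tests therefore show that the
pipeline correctly extracts a deficit-linked region from data with this
structure; they do not certify performance on real cohorts with correlated
lesion topographies.

Problem sizes used in the validation suite: family-wise error is checked on
200 null cohorts at 16³ (labels drawn independently of lesions; empirical
FWE compared against 0.05 plus two binomial SEs), region recovery on 50
cohorts at 32³ (Dice ≥ 0.5 against ground truth in at least 80% of seeds),
staircase properties on 500-run batches. These sizes give stable
Monte-Carlo estimates while keeping the whole suite in the minutes range.

## A worked run

```{r}
fx <- make_fixture(seed = 42)
res <- lesion_symptom_pipeline(fx$lesions, fx$behavior, seed = 1)
table(res$profiles$group_label)
res$perm$exhaustive
res$perm$n_perm
round(res$perm$critical_z, 2)
sum(res$seed_mask$mask$values)
round(dice_coefficient(res$seed_mask$mask, fx$truth$critical_region), 2)
```

The 6/6 split is recovered, the permutation test runs exhaustively over 924
relabelings, and the extracted seed mask overlaps the ground-truth region.
All volumes read and write NIfTI-1 via `read_mask_volume()` /
`write_volume()`; grids are checked for identity (dims and affine to
10⁻⁶ mm) before any multi-volume operation, and a mismatch raises rather
than resamples.

## Known limitations

* The staircase threshold estimator inherits the bias of the published
  asymmetric step sizes (see above); the package measures it rather than
  repairs it.
* The Liebermeister augmentation makes the voxel test quasi-exact, not
  exact; its FWE control is nevertheless exact under exhaustive
  permutation, which is the regime of the default 6/6 design.
* Continuous-score lesion mapping (t / Brunner-Munzel variants), spatial
  smoothing, and lesion-volume regression are out of scope.
* `space_label` is metadata only; no registration or resampling is
  performed.
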