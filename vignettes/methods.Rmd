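---
title: "Models and methods behind telka"
output: rmarkdown::html_document
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`telka` does two things: it turns a teloblot scan into per-lane telomere
length estimates, and it turns per-streak relative-length measurements into
validated kinetic groups. This vignette explains the models, the defaults
and the numerical choices, including the places where the design was
genuinely open and what we decided.

## 1. Densitometry

### Migration model

Fragment migration on agarose is approximated as linear in the logarithm of
fragment size: `row = a − b·log10(size_bp)` with `b > 0` (larger fragments
migrate less). The two marker bands (2044 and 779 bp from an *Xho*I
chromosome-II fragment, hybridized on the same blot as the telomeric probe)
determine `a` and `b` exactly — a two-point fit, not a regression — so the
calibration reproduces the anchor sizes to machine precision. Evaluation
beyond the `[779, 2044]` interval is permitted but flagged
(`extrapolated`), because wild-type TRF smears reach the neighbourhood of
the upper marker. Passing anchors that imply `b ≤ 0` raises an orientation
error: the scan is most likely upside down and should be re-read with
`flip = TRUE`.

### Lane geometry and profiles

Lanes are peaks of the smoothed column-sum projection (prominence at least
`lane_prominence_fraction` of the projection maximum, spacing at least
`lane_min_spacing` px). Rendered and real lanes are nearly flat-topped, so
the argmax of the projection is a poor center estimate; each detected peak
is therefore refined to the local intensity centroid over ±`lane_halfwidth`
columns. Manual centers in the config override detection — the assay is
deliberately semi-automated, and crooked gels are better handled by a human
than by a heuristic. All row/column intervals are half-open; profiles are
per-row sums (or means) over the lane's columns.

### Background

The baseline of an autoradiogram profile (fog, exposure ramps) is estimated
by 1-D morphological opening — a running minimum followed by a running
maximum — and subtracted with clipping at zero. The structuring element
**must be wider than the widest genuine feature in the profile**: an
opening whose element is narrower than the smear reproduces the smear in
the baseline, and subtraction would then delete the very signal being
quantified. The default `background_width = 201` rows exceeds the smear
width at the default geometry (a 150 bp-SD smear spans roughly 150 rows)
while staying far below the profile length. Two known, bounded artefacts
remain: within half an element of the profile ends the baseline is
underestimated, and under a feature that sits on a ramp the baseline is
overestimated by at most `slope × width`. At realistic fog slopes both
effects move the weighted median by about one row; the unit tests pin
those bounds explicitly.

### Markers, smear, and the weighted median

Marker bands and the smear hybridize on the same membrane, so they are
discriminated by width: a peak is a marker candidate only if its FWHM is at
most `marker_fwhm_max = 12` rows, while the smear is several times broader.
The two most prominent narrow peaks win (a third narrow peak is reported
with a warning); centers are refined by 3-point parabolic interpolation,
which is adequate at gel-scan resolution. Fewer than two narrow peaks is a
hard per-lane error — without both anchors no size can be assigned.

Marker windows (center ± `marker_mask_fwhm`·FWHM) are masked out of all
smear statistics. The smear is the maximal contiguous run of rows at or
above `smear_threshold_fraction` (default 10%) of the maximum unmasked
intensity; masked rows may lie inside the run but contribute no weight.
Masking is a deliberate trade-off: where a smear overlaps a marker, the
masked wedge biases the weighted median by up to a few tens of bp, but the
alternative — letting marker signal leak into the smear — is worse and
unquantifiable. The render→measure recovery test keeps the overall error
budget at |bias| ≤ 5 bp and SD ≤ 20 bp over median TRFs drawn from
600–1900 bp.

The lane summary is the intensity-weighted median: the smallest row whose
cumulative unmasked intensity reaches half the total (smallest-row tie
rule). Because the size map is monotone, the median commutes with it — we
compute the median row and map it through the calibration, and a property
test checks this equals the median computed directly in size space. The
weighted *mean* does not commute and is therefore computed in size space.
The median is scale-invariant, so exposure differences between blots cancel.

Telomere length is `median TRF − subtelomere_offset_bp`. The offset is a
laboratory constant of the probe/digest combination and is not measurable
from a blot alone; the default 950 bp makes the canonical ~1.3 kb wild-type
TRF correspond to a ~352 bp telomere. The synthetic fixtures use the same
constant, so recovery tests are offset-independent. Whether duplicate lanes
of one sample should be averaged is left to the user: the package reports
per-lane values only.

## 2. The synthetic teloblot

The renderer inverts the measurement model. Markers are Gaussian bands at
specified rows; the smear is a Gaussian **in size space** (median
`smear_median_trf_bp`, spread `smear_sd_bp`) mapped into row space through
the lane's own calibration *including the Jacobian* `|ds/dr|`, so
integrated intensity is preserved and the size-space median remains the
controlled ground truth — and the rendered smear is asymmetric in row
space, as real TRF smears are. Fog (constant + ramp) and additive Gaussian
pixel noise (default SD 0.008 on the `[0,1]` scan scale, a typical good
film scan) are added last; rendering is bit-identical under a fixed seed.
The default wild-type fixture has a 1302 bp median TRF (352 bp telomere
after the 950 bp offset), SD 150 bp, markers at rows 150 and 450 in an
800-row image.

What the renderer does **not** emulate: lane smiling/curvature, probe
stripping artefacts, saturation, spatially correlated film grain, partial
digestion. Passing the recovery suite therefore demonstrates correctness of
the algorithmic chain under the stated image model, not robustness to every
pathology of real blots — which is one reason manual lane override exists.

## 3. Kinetics

### Matrix assembly

Trajectories span streaks 1–9 (~25 generations each); the spore itself
(streak 0) is at wild-type length by construction and is not a column.
Entries are `length(mutant, streak) / length(wt, streak)` with a scalar or
per-streak reference. Mutants need at least 7 of 9 streaks and at most 2
consecutive missing ones; qualifying gaps are linearly interpolated (edge
gaps take the nearest observed value), and failing mutants are excluded
with a warning. The thresholds are a pragmatic choice — with 2 of 9 points
missing a trajectory's shape is still well constrained; beyond that,
imputation would invent kinetics.

### Archetypes

Four mean curves generate the simulated groups (relative length vs streak
`t`):

| group  | curve                                   | defaults            |
|--------|-----------------------------------------|---------------------|
| group1 | `1 − (1−f)(1 − e^{−t/τ})`               | `f = 0.85, τ = 2`   |
| group2 | linear to `f` at streak 3, flat after   | `f = 0.80`          |
| group3 | at plateau `f` from streak 1            | `f = 0.55`          |
| group4 | `1 − (1−f)(1 − e^{−t/τ})`               | `f = 0.82, τ = 0.6` |

Group 2's 80% plateau is the one empirically reported level; every other
plateau and time constant is a package default chosen to reproduce the
described *shapes* (mild exponential plateauing by streaks 5–6; acute drop
within one streak; rapid-but-mild), **not** a biological claim. `τ = 2`
puts group1 within 1% of its plateau at streak 6; `τ = 0.6` puts group4
essentially at plateau by streak 2. Noise is multiplicative mean-one
lognormal per streak, default `noise_sd = 0.003`: trajectories are
within-blot ratios, in which blot-level calibration and migration errors
largely cancel, and this default also keeps the smallest between-archetype
mean-curve separation (groups 2 vs 4, ~0.10) above five times the expected
within-archetype noise distance — the regime the simulated study design
assumes. The default dataset is 30 mutants: 10/8/4/8 in groups 1/2/3/4.

### Clustering and the gap cut

Average linkage on plain Euclidean distances is the default (complete and
centroid are available; z-scoring is available but off, since the rows are
already commensurable ratios). With `k` unspecified, the flat cut is placed
in the **largest relative gap** — the largest ratio between consecutive
merge heights. The absolute-gap rule fails structurally on exactly the data
this method targets: one strongly divergent group (the acute group3 sits
~0.9 units from everything else) makes the top gap dominate, so an absolute
rule always returns k = 2 regardless of how cleanly the remaining groups
separate. The ratio rule is scale-free, returns k = 1 when all merge
heights are zero (identical rows), and breaks ties toward the smaller k.

### Permutation significance

"Is this partition tighter than chance?" is answered by permuting cluster
labels while preserving cluster sizes, recomputing the intra-cluster
distance sum on the cached distance matrix (a compiled kernel; 10⁶
permutations of a 30×9 dataset take ~2 s), and reporting the add-one
p-value, whose floor with 10⁶ permutations is just below 10⁻⁶. With labels
chosen independently of the data this p is uniform (verified by a
calibration test against binomial bounds). An entry-shuffling variant
(`method = "entries"`) destroys trajectory structure entirely and is
offered as a sensitivity analysis.

### Sub-cluster validation and selection bias

Re-clustering a cluster and then testing *the split you just fitted* with
the plain label-permutation null is anti-conservative by construction: the
fitted split nearly minimises the statistic over partitions, so its p-value
approaches 1/#partitions even for homogeneous data (≈ 0.008 for 10 members
split 5/5 — below a 0.01 threshold). `iterate_subclusters()` therefore
defaults to a selection-adjusted null: each permutation shuffles every
streak column independently within the cluster (preserving per-streak
marginals, destroying row structure) and **refits** the clustering at the
same k before computing the statistic. Homogeneous groups are then retained
intact and genuine sub-structure is still detected; the plain null remains
available via `null = "labels"`. Clusters with fewer than 4 members are
never split, and recursion stops at depth one.

## 4. Problem sizes in the test suite

The suite regenerates everything in code: 100 random lane renderings for
the recovery property, 50 wild-type replicates for reproducibility, 20
seeds for archetype recovery, 200 replicates × 399 permutations for null
calibration, and one 10⁶-permutation run; the whole suite completes in
well under a minute on a laptop-class CPU.

## 5. Known limitations

- Straight lanes only; curvature must be handled upstream or via manual
  lane centers.
- The subtelomeric offset is a config constant, not an estimate; absolute
  telomere lengths inherit its uncertainty unchanged.
- The weighted median is reported on the integer row grid (~2–4 bp at the
  default geometry); sub-row median interpolation was deliberately left
  out to keep the tie rule exact.
- Real kinetic group plateaus (other than group 2's 80%) are unknown;
  simulation defaults are placeholders for testing separability, and
  conclusions about real mutants require real trajectories.
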