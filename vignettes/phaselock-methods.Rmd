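---
title: "Phase-locking state dynamics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking state dynamics: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`phaselock` treats a resting-state scan as a sequence of recurrent
*phase-locking (PL) states*: configurations of brain regions whose
band-limited BOLD phases align. The observable at each timepoint is the
phase-coherence matrix

    dFC(n, p, t) = cos(theta(n, t) - theta(p, t)),

where `theta(n, t)` is the instantaneous Hilbert phase of region `n` after
band-pass filtering to 0.04–0.07 Hz. Because `dFC` depends only on phase
*differences*, it is invariant to a global phase shift; its leading
eigenvector `V1(t)` captures the dominant pattern of (anti-)alignment at
time `t` in a single vector over regions. Clustering the pooled `V1(t)` of
all subjects with k-means yields K centroids — the PL states — and a state
label per timepoint per subject. Condition-resolved temporal metrics of
those labels (switching frequency, fractional occupancy, mean dwell time,
switch probabilities) are then compared across an event condition (e.g.
hallucination periods marked by the subject) and rest, and across groups,
with permutation repeated-measures ANOVA.

Assumptions worth keeping in mind: the narrow band makes instantaneous phase
well defined but also imposes a temporal resolution floor of roughly the
band's inverse width (~30 s ring-down; see below); k-means imposes convex,
equally-weighted clusters on the eigenvector cloud; and the per-volume state
label is a hard assignment even when the eigenvector sits between centroids.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| band | 0.04–0.07 | Hz | standard slow-oscillation band for resting BOLD; carrier default 0.055 Hz is its centre |
| filter order | 5 | — | Butterworth per pass; applied forward–backward, so the magnitude response is effectively squared |
| edge trim | 10 + 10 | volumes | discards Hilbert edge effects; 800 volumes become 780 |
| K range | 3–15 | — | scanned by the Dunn index; ties break toward the smaller K (parsimony) |
| k-means restarts | 20 | — | best-inertia solution kept; seeded, deterministic |
| Dunn subsample | 8000 | points | the exact index is O(N²); a seeded uniform subsample caps cost on pooled matrices |
| hemodynamic shift | 8 | TR (4.8 s at TR 0.6 s) | moves event labels later to match the BOLD peak lag of ~4–6 s; vacated head volumes become rest |
| permutations | 10,000 | — | ANOVA and post hoc t-tests; p uses the add-one estimator (1 + exceedances)/(1 + n) |

## The filter is zero-phase by construction

Only "fifth-order Butterworth" is inherited from the reference procedure;
whether it was applied one-pass or two-pass is unstated. A single causal
pass would add a frequency-dependent phase lag to a pipeline whose entire
signal *is* phase, so the filter here is applied forward and backward. The
implementation cascades second-order sections (the direct polynomial
recursion of an order-10 narrow band-pass is numerically ill-conditioned and
leaves ~1e-6 interior noise; biquads reach ~1e-12), over an odd-reflection
padded series long enough (2000 samples per side, iterating the reflection
for short series) for the band's ring-down to decay inside the padding.
Rows are demeaned before the Hilbert transform as a numerical safeguard;
the band-pass already suppresses DC.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces, per subject, `cos(2*pi*f*t + phi_s(n)) +
N(0, sd)` where the planted state `s` follows a Markov chain and each state
is a region-wise phase-offset pattern (an anti-phase block covering 25–45 %
of regions; blocks are distinct across states and in the minority so the
majority-negative eigenvector orientation is stable). Event timelines use
alternating exponential on/off durations calibrated so that the defaults
reproduce the reference cohort's event statistics (~14 episodes of ~9.5 s
mean covering ~25–30 % of a 480 s scan); during events the Markov switch
probability is multiplied by `condition_coupling`, giving a plantable
condition effect on switching and dwell for power studies.

The generator deliberately omits hemodynamic convolution, head motion,
physiological noise, scanner drift and spatial structure. Passing tests
therefore demonstrate that the *method* recovers planted phase-locking
structure under in-band signal and white noise — not that it is robust to
every artifact of real fMRI.

**Planted dwell time.** A planted switch is an instantaneous phase jump,
which the narrow band smears over a transition zone of about ±3 volumes; in
a 90-region cohort at noise SD 0.1 the label errors concentrate entirely in
that zone. The default planted dwell is therefore 72 s (~120 volumes),
keeping smeared volumes below ~5 % of a segment so that planted labels are
recoverable — the generator's contract. This is a property of the *planted*
dynamics, not a claim about empirical dwell times (which the reference
analysis finds in the 3–10 s range; those are outputs of clustering real
data, not generator inputs). Note the dwell floor implied by the band: with
a ~30 s ring-down, very short genuine states are not resolvable by any
analysis in this band.

**Model selection and boundary smear.** The same transition zone explains
why Dunn-index model selection is tested on the planted-partition route
(eigenvectors of planted phases plus observation jitter): boundary
eigenvectors interpolate between cluster centroids, and the Dunn index — a
ratio of extreme statistics — collapses once bridges exist between
clusters. On bridge-free pools the index peaks sharply at the planted K;
on full-pipeline pools it remains useful for *relative* comparison (its
empirical values on real data are small, order 1e-2) but its argmax is not
a reliable estimator of a planted K. Recovery of the labels themselves
(adjusted Rand index ≈ 0.9 at noise SD 0.1) runs through the full
filter-plus-Hilbert pipeline.

## Condition handling

Event onsets/offsets in seconds are mapped to the volume grid by rounding
`time/TR` to the nearest integer (half away from zero), the rule with the
smallest total duration deviation; volume `t` covers `[t*TR, (t+1)*TR)` and
episodes mark half-open index ranges, so adjacent episodes cannot
double-count a boundary volume. Event times are interpreted on the original
800-volume clock and shifted by the front trim, preserving the 780-length
condition array. Rounding-induced overlaps are merged and counted;
zero-length episodes are dropped and counted.

The per-subject analysis window opens at the first change of state *or*
condition and closes at the last, because the first and last states of a
scan have no observed onset/offset. This operator is intentionally not
idempotent: the window opens exactly at a change, so reapplying it to the
windowed data would discard the first (now boundary-less) run; the tested
invariant is that re-derived windows nest inside the first.

Masking the other condition to the label 0 prevents two same-state episodes
separated by the other condition from concatenating into one inflated
dwell, and makes transitions into/out of 0 carry information about which
states precede or follow a condition change. Following the stated procedure,
switching frequency and occupancy are computed on condition-restricted
volumes *without* masking (transitions straddling a condition boundary count
for neither condition); masking is used for dwell time and switch
probabilities only. The switching-frequency denominator is the condition
duration in seconds (condition volumes × TR).

## Permutation repeated-measures ANOVA

Observed statistics are the classical mixed-design F values: one
between-subject factor (group, error = subjects within groups) and fully
crossed within-subject factors (error = effect × subject-within-group mean
square), computed by the balanced inclusion–exclusion sums-of-squares
decomposition and verified to 1e-10 against `stats::aov` error strata. The
permutation schemes respect exchangeability: between effects permute
whole-subject group labels; within main effects permute that factor's levels
independently within each subject; interactions use Freedman–Lane residual
permutation (residuals of the model without the tested effect, permuted
within subjects for pure-within effects and across subjects for
group-involving effects). This is an approximation to the referenced
permutation package's defaults at the level of type-I error control, not a
claim of identical p-values; the empirical type-I rate at α = 0.05 is
measured in the acceptance script (500 null replicates).

Two deliberate conventions: p-values use the add-one estimator, so the
smallest attainable p is 1/(n_perm + 1); and an effect whose numerator and
error sums of squares are both exactly zero is reported as `F = NaN`,
`p = NA` rather than permuted. The latter arises structurally for
fractional occupancy: occupancies sum to 1 over states for every subject ×
condition, so the group and condition main effects (and their interaction)
are inestimable for that metric — consistent with the near-unity p-values
the reference analysis prints for them. Missing state × condition cells
(a state never visited by a subject in a condition) are imputed by the
group × condition × state cell mean only where the ANOVA requires complete
cells, and the imputation count is reported in the run log.

Interaction degrees of freedom are derived from the design actually fitted
(products of factor-level counts minus one); a reference analysis with
structural zeros in its transition design may print different numerator df.

## Numerical choices and degenerate inputs

- Eigenvector orientation: flipped so the strict majority of components is
  negative; an exact tie flips so the first component is ≤ 0. Required for
  clusterability; matches common LEiDA practice.
- k-means: Euclidean distance (monotone in cosine distance on unit
  vectors), seeded restarts, empty-cluster retries (up to 5), error if
  persistent.
- Dunn: single-linkage inter-cluster over complete-diameter intra-cluster;
  all-singleton diameters yield a flagged `+Inf` sentinel; ties in the K
  scan break toward smaller K.
- Rounding ties (x.5): half away from zero; documented because only
  "nearest integer" is inherited.
- Shift direction: events move *later* (the BOLD response lags experience);
  labels pushed past the scan end are discarded with a warning.
- Constant (all-zero after demeaning) regions, empty analysis windows, zero
  contingency margins, fully missing imputation groups, and bands outside
  (0, Nyquist) are errors naming the offending region/subject/input.

## Problem sizes used in validation

The test-suite and acceptance-script cohorts are scaled-down versions of the
reference design chosen for desk-scale runtimes: the structural-count checks
use the full 42 × 800-volume layout; recovery checks use 40 regions × 400
volumes × 6 subjects (and the full 90 × 800 × 42 for the noisy-recovery
index); ANOVA calibration uses 2 × 5 subjects × 2 conditions with 200
permutations and 500 null replicates. These sizes are the package's own
validation design; the pipeline itself runs the full-scale layout in
minutes.

## Known limitations

- Hard state assignments: no soft/fuzzy membership, no uncertainty on the
  per-volume label.
- The Dunn argmax is fragile under cluster bridging (see above); on real
  data, inspect the full K table rather than trusting the argmax blindly.
- The permutation schemes are exchangeability-based approximations; exact
  agreement with any specific published permutation implementation is not
  claimed.
- No hemodynamic forward model anywhere: the rigid 8-TR shift is the only
  concession to the BOLD lag, mirroring the reference procedure.
- Unbalanced group sizes are supported by the weighted (proportional-cell)
  decomposition; severely unbalanced designs deserve a dedicated mixed
  model instead.
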