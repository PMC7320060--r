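---
title: "Spatiotemporal context and recognition memory: models and methods"
author: "walkmem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal context and recognition memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkmem)
```

## The problem

When people encode items while physically moving through an environment,
later recognition of an item depends not only on the item itself but on the
spatiotemporal context it was encoded in. Three context signatures are of
interest for old/new recognition of items encoded along a walked route
through two distinct rooms:

* a **spatial boundary effect** — when two old items are probed on
  consecutive recognition trials and the first is correctly recognised, the
  second is recognised more often if both were encoded in the *same* room
  than across rooms;
* an **ordinal proximity (temporal contiguity) effect** — among same-room
  sequential probes, recognition of the second item is better when the two
  items were encoded at close ordinal positions along the route
  (|lag| <= 3) than at remote ones (|lag| >= 4);
* a **travelled-distance effect** — the probability of recognising the
  second item declines with the spatial (meters walked) or temporal
  (seconds elapsed) distance physically travelled between the two items
  during encoding. This is quantified by the *distance-based mnemonic
  probability function* (d-MPF) and tested with a sign-flip permutation
  t-test.

`walkmem` implements the full analysis chain for such experiments —
trajectory logs to distance matrices, trial sequences to conditional hit
rates, d-MPFs to permutation tests — plus a generative simulator that
produces complete synthetic sessions with *known injected* effect sizes, so
that every stage can be validated end to end without any real data.

## Data model

A session consists of:

1. **Trajectory logs** — one CSV per participant and room with columns
   `t_s, x_m, y_m, heading_deg`, sampled strictly at 10 Hz (0.100 s) with
   millimeter position resolution. Heading is yaw in degrees
   counter-clockwise from the +x axis in `[0, 360)`. `read_tracklog()`
   validates these invariants; in its default non-strict mode it repairs
   isolated single-sample gaps by linear interpolation (counted and
   warned), while shuffled or heavily gapped files raise a classed
   `corrupt log` condition, which downstream analysis converts into a
   participant-level exclusion from the trajectory analyses only.
2. **Recognition responses** — a 77-trial old/new task per participant:
   50 old-item probes (the four *boundary* paintings — first and last of
   each room, encoding positions 1, 9, 10, 18 — twice each; the other 14
   paintings three times each), 18 lures and 9 new items once each. Each
   "old" answer is followed by a source-room attribution and a 4-level
   confidence rating (1 = Sure ... 4 = Completely unsure; the direction is
   configurable).
3. **Room layouts** — nine paintings on the walls of a 4 x 6 m floor, and
   the instructed route that passes a viewing point ~1.2 m in front of each
   painting in ordinal order.

## Trajectory features

**Gaze attribution.** A sample is attributed to a painting when the
painting lies within `max_dist_m` (default 4 m), within `ang_thresh_deg` of
the heading vector, and its canvas faces the walker (negative dot product
of the wall normal with the walker-to-painting vector); the nearest-angle
candidate wins ties. No pitch and no wall occlusion are modelled; the
facing test is what prevents attribution through walls in these layouts.
The default half-angle is 15 degrees. This value is deliberately narrower
than a nominal visual field: with wide cones, straight walking legs
attribute long approach phases to paintings several meters ahead, which
inflates viewing times well beyond the time actually spent in front of a
painting. At 15 degrees, walking-phase attribution is incidental while
dwell-phase attribution (heading noise of a few degrees around the canvas
direction) is essentially unaffected. The threshold is a free parameter of
`analysis_config()` and results should be checked for sensitivity to it.

**Visits.** All samples attributed to a painting pool into one visit:
`viewing_time` is 0.1 s per attributed sample; runs separated by gaps up to
`gap_tol_s` (default 0.5 s) count as a single run. The **central time** of
a visit — the representative moment used to delimit traverses — is the
closest-approach sample within the gaze span. The alternative
(`central_time_mode = "gaze_midpoint"`) is provided for sensitivity
analysis because "the central position of a visit" admits more than one
reasonable reading. Paintings never gazed at are retained (flagged, with
the whole-log closest-approach time as central time) so distance matrices
stay complete; flagged entries are excluded from d-MPF eligibility.

**Distances.** For two paintings with central times $t_i < t_j$, the
spatial distance is the *cumulative path length* walked between $t_i$ and
$t_j$ (not the straight line), and the temporal distance is $t_j - t_i$.
Cumulative path length makes the matrix additive through any intermediate
visit — `spatial(i,j) = spatial(i,k) + spatial(k,j)` — which the package
asserts at 1e-9 on every computation, together with
`temporal >= spatial / v_max` for the log's maximal sample speed.
Spatial and temporal distances are strongly collinear in practice (the
walker's pace varies little), so the spatial and temporal d-MPFs are
near-redundant views of the same signal, as the pooled correlation
reported by `analyze_cohort()` shows.

## Recognition statistics

Conditional hit rates condition on the *first* member of a consecutive
old-old probe pair being a hit: the reported rate is
$\Pr(\text{second "old"} \mid \text{first hit, condition})$, per
participant, for the conditions same/across room, close/remote lag, and the
forward/backward splits of the lag classes. Consecutive repeats of the same
item are not pairs (lag 0 would otherwise form a degenerate "close" class);
repeated probes of a painting participate independently in the pairs they
bound. Participants with fewer than `min_pairs` (default 1) qualifying
pairs are flagged ineligible and removed listwise per contrast — the small
per-condition pair counts of a 77-trial design make this the main source of
varying degrees of freedom across contrasts.

Signal detection is computed per room: HR over that room's old probes, FAR
over that room's 9 lures only (new items belong to neither room), and
$d' = z(\mathrm{HR}) - z(\mathrm{FAR})$ after the 1/(2N) extreme-rate
adjustment, which keeps $d'$ finite at ceiling/floor without touching
interior rates. Source attribution scores the proportion of hits whose
source response matches the encoding room and is tested against the
two-room chance level of .5.

Group contrasts are paired (or chance-level one-sample) t-tests with
Cohen's $d_z = \bar{d}/s_d$, a t-based 95% CI of the mean difference, and a
JZS Bayes factor. The directional forward/backward lag splits use
one-tailed tests; everything else is two-tailed.

## Bayes factors and power

`jzs_bf01()` computes the default-prior (JZS) Bayes factor for the null: a
Cauchy prior with scale $r = \sqrt{2}/2 \approx 0.707$ on the standardized
effect, evaluated through the scale-mixture representation (normal effect
given $g$, inverse-gamma(1/2, $r^2$/2) mixing) as a one-dimensional
integral over $g$ solved by adaptive quadrature (relative tolerance 1e-10;
non-convergence is an error, never a silent fallback). Supplying a second
group size switches to the independent-samples form with effective sample
size $n_1 n_2/(n_1+n_2)$ and $df = n_1+n_2-2$. BF01 is symmetric in the
sign of t, strictly decreasing in |t|, and > 1 at t = 0. One caution this
package's tests encode: BF01 and BF10 are reciprocal, and published values
labelled one way occasionally turn out to be the other — recomputing from
(t, n) makes the orientation unambiguous.

`power_paired_t()` is exact noncentral-t power: with $n$ pairs and effect
$d_z$, the statistic is noncentral t with $df = n-1$ and noncentrality
$d_z\sqrt{n}$; two-tailed power at $n = 30$, $\alpha = .05$, $d_z = .5$ is
0.75, the usual benchmark for samples of this size.

## The d-MPF and its permutation test

Eligible pairs are same-room sequential probes whose first item was hit and
whose distances are unflagged. Binning is **pooled**: five equal-width bins
spanning the minimum-to-maximum range of all participants' eligible
distances, both rooms collapsed, with the top edge inclusive. Pooled edges
(rather than per-participant edges) make bin $k$ mean the same physical
distance for everyone, which is what makes the per-bin group average
interpretable. Per participant and bin, the d-MPF is the hit rate of the
pairs' second items; empty bins are `NA`, and bin counts must sum back to
the participant's eligible pair count (asserted).

The group test reduces each participant's d-MPF to one number. Two
reductions are first-class:

* `extreme_bins` (default): HR(bin 5) − HR(bin 1), i.e. *far minus near*,
  so memory that fades with distance gives negative contrasts, a negative
  group T and negative Cohen's d — the sign convention in which such
  effects are conventionally reported. Participants lacking either extreme
  bin are excluded listwise, which is why the test's df is typically well
  below the cohort size (in simulated 26-participant cohorts, around
  12-20 complete participants are typical).
* `linear_trend`: the least-squares slope of HR on bin midpoint over a
  participant's non-empty bins (>= 2 required). It uses all bins and
  excludes fewer participants, at the cost of imposing linearity.

Under the null of no distance effect each participant's contrast is
symmetric about zero, so the null distribution is built by **sign-flipping**
the contrasts: 2,000 random assignments of +/-1 (or exhaustive enumeration
of all $2^n$ for n <= 20), recomputing the one-sample t each time. The
two-tailed permutation p is the proportion of surrogate |T| at or above
|T_obs|, add-one smoothed to $(1+k)/(B+1)$ so p is never exactly zero; the
raw proportion is available as an option. Sign-flipping (rather than
shuffling bin labels within participants) is the correct scheme for a
within-participant contrast: it preserves each participant's binning and
pair counts exactly and only randomises the sign that the null declares
exchangeable. The test requires at least 3 complete participants.

## The synthetic-data generator

The generator is a *generative twin* of the analyses, with defaults chosen
once to emulate the target study's conditions:

| parameter | default | emulates |
|---|---|---|
| `n_participants` | 30 | cohort size |
| `base_hit` | .62 | overall old-item HR ~ .6 |
| `base_far_lure`, `base_far_new` | .20, .05 | lure FAR ~ .2, rare new-item FAs |
| `beta_room` | +.07 | same- vs across-room conditional HR gap (~.65 vs .58) |
| `beta_lag` | +.13 | close- vs remote-lag gap (~.71 vs .58, net of `beta_room`) |
| `beta_dist` | −.03 / m | bin1-to-bin5 HR drop of ~.25, the d ~ −0.9 scale |
| `source_acc` | .78 | source HRs ~ .74/.81 |
| `dwell_mean` (s) | 20 | per-painting viewing times ~ 19-20 s |
| `walk_speed_mean` (m/s) | 0.11 | room times ~ 285-290 s on a 4 x 6 m floor |

Responses are drawn trial by trial: an old probe's hit probability is
`base_hit`, plus `beta_room` if the directly preceding probe was a distinct
same-room old item answered "old", plus `beta_lag` if that item was also
within lag 3, plus `beta_dist` times the pair's travelled spatial distance
*centred on the room's mean pairwise distance*. Centring is a deliberate
design choice: travelled distance and the room/lag indicators are
physically confounded (same-room pairs have finite distances, close-lag
pairs short ones), and an uncentred distance term would shift the average
same-room hit probability by `beta_dist` times the mean distance,
contaminating `beta_room`. With centring, each beta is separately
recoverable: the same-vs-across gap estimates `beta_room` (plus the
close-pair share of `beta_lag`), and the d-MPF slope estimates `beta_dist`.
The same confound is why null-calibration simulations of the *distance*
test must set `beta_lag = 0` as well as `beta_dist = 0`: a lag effect *is*
a true distance signal, and the permutation test is right to find it.

Boost-adjusted probabilities are clipped to [0.01, 0.99]; intentionally
degenerate base rates (0 or 1) are honoured so the degenerate limits remain
exact. Confidence is `1 + Binomial(3, 1 - p_trial)` — any scheme monotone
in trial strength suffices for pipeline validation, and this one needs no
extra parameters. Source responses are correct with probability
`source_acc` (a fair coin for new items). Room order is a seeded fair coin
per participant. Data loss is emulated by dropping both log files of
`n_drop` participants and scrambling the timestamps of one log for
`n_corrupt` further participants; recognition data are unaffected, so
trajectory-based and recognition analyses have different ns, as in real
sessions.

Walks quantise leg and dwell durations to the 0.1 s grid so that samples
lie exactly on the route polyline: a noiseless walk's sampled path length
equals the polyline length to 1e-9, which is the anchor for the
distance-matrix oracles. Speeds are truncated at +/-3.5 SD and durations
rounded upward, guaranteeing the per-sample displacement bound
`(mean + 4 SD) * 0.1 m`. Room geometry places paintings so that, on the
noiseless walk, gaze is attributed only during dwells (verified across
jitter seeds); with the default 5-degree heading noise, attributed viewing
time scatters about +/-3 s around the true dwell.

**What the generator does not emulate:** volitional route choice or
backtracking (the route is instructed), head pitch, gaze occlusion by
interior walls, item-level memorability differences, fatigue or serial
position effects, and response times. Passing the pipeline's tests on
synthetic cohorts therefore demonstrates correctness of the *computations*
and recoverability of effects under this generative model — not that real
data satisfy the model.

## Numerical choices and degenerate inputs

* Proportions use plain ratios; conditional rates with empty denominators
  are `NA` and excluded listwise, never imputed.
* Zero-variance difference vectors: t = 0 with p = 1 when the mean is also
  zero (and Cohen's d defined as 0); otherwise the infinite-t limit with p
  floored at the smallest representable double and a flag — p is never
  reported as exactly 0.
* d-MPF edges collapse to a +/-1e-6 band if all pooled distances are equal
  (a degenerate case only synthetic data can produce).
* Permutation ties: surrogate |T| >= |T_obs| is evaluated with a 1e-12
  tolerance so exact sign-symmetric ties count toward p.
* All randomness flows from explicit seeds; a master seed derives labelled
  substreams (`derive_seed`) so each participant, walk, trial order and
  permutation run is independently reproducible and modules can be rerun
  in isolation.

## Problem sizes used in the validation suite

The shipped tests validate calibration and recovery at the study's own
conditions: 200 null cohorts of 26 participants for the permutation test's
type-I rate (5% +/- 3%), 50 cohorts of 30 participants for joint recovery
of the three injected effects, exhaustive-vs-Monte-Carlo agreement at 8
participants, and 50,000 simulated experiments for the power oracle. These
sizes were chosen as the smallest that give the stated binomial tolerances
meaningful resolution.

## Known limitations

* Gaze attribution ignores occlusion; layouts were designed so the facing
  test compensates, but unusual custom layouts should re-check this.
* The greedy sequential-pair reorderer is a heuristic: it reaches the
  default pair targets essentially always, but offers no optimality
  guarantee, and emits a warning with the achieved counts when a target is
  unreachable within its proposal budget.
* The d-MPF's extreme-bins reduction discards participants missing an
  extreme bin; with very sparse designs the `linear_trend` mode is the more
  robust choice and both are reported side by side by the pipeline.
* Real-data headline statistics depend on the original dataset and are not
  reproduced numerically by synthetic cohorts; what the package reproduces
  are the desk-scale quantities (power, Bayes factors, task structure) and
  the direction/calibration properties of the group effects.
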