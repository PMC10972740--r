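---
title: "Methods: behavioral and population analysis of 2CAP sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral and population analysis of 2CAP sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twocap)
```

## The task and the scientific question

In the two-way cued access protocol (2CAP), a rat shuttles between the
two ends of a chamber; a 4 s visual CS+ on one side predicts that, after
a 1 s delay, a sipper with 10% alcohol descends for 8 s. A CS−
(illuminated on both sides) predicts no access. A session has 96 trials,
48 of each type. On *congruent* sessions alcohol appears on the CS+
side; on *incongruent* sessions on the opposite side, so an animal that
keeps applying the learned cue rule approaches the wrong port.

The analyses ask whether the neural population encodes the upcoming
left/right choice *before* the approach (proactive control: a goal
representation maintained in advance) or only *at/after* it (reactive
control: the representation generated when alcohol becomes available).
The package implements the full chain from raw-format inputs to that
contrast, and a generator that produces sessions in either regime with
known ground truth.

## Behavioral extraction

Pose tables carry x/y/likelihood triplets for four body parts and six
static landmarks at 30 frames/s, in pixel units with the video-frame
convention (origin top-left, y downward); the chamber is taken as
640 × 480 px and no pixel-to-cm calibration is applied, since none is
defined for this rig. Frames whose tracker confidence falls below 0.90
are linearly interpolated between the nearest confident frames (edge
frames take the nearest confident value); the likelihood threshold is
interpreted on the tracker's [0, 1] confidence score.

An *approach* is the first frame during sipper access at which the
snout marker is within 9 px (Euclidean) of a sipper landmark. A CS+
trial is *correct* if the first port visited is the alcohol side,
*incorrect* if the other port is visited first (the later arrival at
the correct port is still recorded, since animals typically correct
themselves), and an *omission* if neither port is reached. Latency is
measured from sipper entry; port visits during the cue but before the
sipper descends do not define latency, though the animal may already be
waiting at the port (in which case latency is effectively zero at the
first access frame). CS− trials have no sipper events; for the CS
discrimination ratio (CS+ approaches over all approaches, 0.5 = chance)
a CS− "approach" is scored in the window where access would have
occurred, 5–13 s after cue onset. Approach-probability curves use a
centered three-trial moving average with shrinking edge windows — the
edge rule is our choice, as is scoring epoch speeds as the change in
snout-to-sipper distance per second (with signed variants that
distinguish closing in on a port from moving away, which the absolute
value cannot).

## Firing rates

Units enter analysis only with strictly fewer than 5% of inter-spike
intervals below the 2 ms refractory period. Rates are binned at 100 ms
and smoothed per neuron with a Gaussian kernel whose width is the
square root of the mean ISI multiplied by the inverse coefficient of
variation. Three numerical choices:

- The CV uses the sample (n − 1) standard deviation.
- Sigma is evaluated with the mean ISI in seconds and capped at 2 s;
  a zero CV (perfectly regular train) takes the cap. The rule's
  dimensional form is odd (seconds^1/2), so a configuration switch
  (`sigma_units = "bins"`) evaluates it in bin units instead; the
  default is seconds.
- The kernel is truncated at ±3σ and renormalized to unit mass, so
  smoothing conserves spike count for spikes away from the window edge
  (testable to 1e−6) and is linear: merged spike trains give summed
  rates.

Windows include both endpoints on the 0.1 s grid: the cue-centered
window [−4, 18] s therefore has 221 bins (the half-open convention
would give 220; the inclusive convention is the one consistent with the
printed bin count). Cue-centered tensors use the first 15 trials of a
session, since engagement declines over a session.

## Population geometry

Two PCA strategies operate on trial-averaged unit × time matrices with
units as variables: observations are timepoints, each unit's (row) mean
is removed before decomposition, and the decomposition itself is
delegated to `stats::prcomp`. Component signs are fixed by making each
component's largest-magnitude loading positive; without this, sign
indeterminacy would scramble left-minus-right difference signs between
runs.

- *Cue-centered*: session matrices over the 221-bin window are stacked
  vertically per strain (units pooled across sessions and both session
  types) and decomposed once.
- *Side-concatenated*: per session, the mean over up to 15 correct left
  trials and up to 15 correct right trials are concatenated in time
  (left half, then right half), sessions are stacked within a session
  type, and the scores are split back into left and right halves after
  the decomposition. The approach sits at the window midpoint bin.

Components are retained by the broken-stick rule
$b_k = \frac{1}{p}\sum_{i=k}^{p} \frac{1}{i}$: retention proceeds from
the first component and stops at the first component whose explained
fraction does not exceed its threshold. The thresholds strictly
decrease and sum to one for every $p$.

The left/right separation statistic enumerates every 3-subset of the
leading $n$ components. By default $n$ is derived from the broken stick
on the data at hand (floored at 3 so the statistic is always defined);
for cross-condition comparisons at a fixed subspace count the pipeline
exposes `n_components` (e.g. 9, giving 84 subspaces). Single trials are
projected by subtracting the fit's per-unit means and multiplying by
the loadings — the standard score map. Within each subspace, 1000
(left, right) trial *pairs* are drawn with replacement under a fixed
seed; the Euclidean distance between the paired trajectories is taken
at each pre-approach time sample and averaged over samples and pairs.
Sampling pairs rather than the full 10^6 cross product is our reading
of the procedure's ambiguity and costs a factor of 1000 less; both
yield one mean per subspace, and the pairing is exposed through
`n_bootstrap`. The statistic is zero on identical pools, equals the
offset norm on translated pools, and is invariant to rotations applied
identically to both pools within a subspace.

Loading splits classify units as positive (≥ 0.01), negative
(≤ −0.01) or an excluded middle band. Pre/post side differences
average the sign-group's left-minus-right mean rate over the bins
strictly before and strictly after the approach bin (the approach bin
itself belongs to neither half). Components with time-by-side
interactions are screened with a repeated-measures ANOVA (session as
the error stratum); when several components qualify in both session
types, all are returned and the choice is left explicit to the user.

## Group statistics

Standard tests are delegated: `kruskal.test` for the distance omnibus
with `TukeyHSD` on the unequal-n one-way layout (the Tukey–Kramer
case) for pairwise follow-ups; per-trial 2 × 3 chi-squared tests with
Benjamini–Hochberg correction across the 15 trial positions, falling
back to Fisher's exact test when an expected cell drops below 1;
`manova` per strain over the session-metric vector with constant or
collinear metrics dropped (omissions are excluded by the caller, being
collinear with the other counts); `aov` with an `Error()` stratum for
the repeated-measures screens, with no sphericity correction applied —
the screen is a coarse filter, not a confirmatory test; and `lm` for
`Latency ~ Distance × Session` with per-session-type Pearson
correlations. This module owns only marshaling, corrections and
reporting.

## What the generator emulates — and what it does not

`generate_session()` produces a schedule, a pose track and a spike
population under one seed, all deterministic in (parameters, seed).

The *agent* rests at the chamber center, departs after a truncated
Gaussian latency from cue onset (mean 4.5 s, SD 1 s, floor 0.5 s —
placing typical arrivals one to two seconds after sipper entry, in the
range of observed latencies), travels at 150 px/s, dwells 1 s at a
wrong port before correcting, and holds at the correct port until the
sipper retracts. Decision rules: a proactive agent follows the cue side
with probability `p_follow_cue` (so it errs on incongruent sessions); a
reactive agent approaches the alcohol side with probability
`p_correct_congruent` regardless of contingency. Ground-truth labels
are computed from the noise-free trajectory geometry — the first port
whose 9 px radius is entered during access — so they stay faithful
under any latency draw, and on noise-free sessions the behavioral
module recovers them exactly (a closed-loop test).

The *population* draws baseline rates from a gamma distribution (shape
2, scale 2.5: mean 5 Hz, right-skewed, as cortical populations are) and
assigns 25% cue-modulated, 25% sipper-modulated and 30% side-selective
units, the remainder untuned; gains default to 3. Spikes are sampled by
thinning an inhomogeneous Poisson process with a 2 ms absolute
refractory period; the thinning hazard is inflated to
$\lambda/(1-\lambda r)$ so the realized rate matches the nominal rate
despite the dead time. Side units fire above baseline for 1.5 s before
the approach (proactive regime) or after it (reactive regime) on trials
toward their preferred side.

Not emulated: within-session disengagement (an optional linear decay
was considered and left out — no quantitative drift model is defined
for it), bursting or non-Poisson spike statistics, electrode drift,
correlated noise across units, video artifacts beyond i.i.d. jitter
and injected low-confidence frames, and intoxication dynamics. Passing
tests therefore demonstrate that the *analysis chain* recovers the
structure the generator puts in; they cannot certify performance on
recorded data with slow drifts or correlated variability.

## Problem sizes

The analysis workflow runs 16 sessions (2 strains × 2 session types ×
4 replicates) of 96 trials and 40 units each — large enough for every
stage to operate at its native shape (221-bin tensors, 84-subspace
distributions) while a full run stays in the minutes range. The
parameter-recovery suite uses 10 seeded runs per regime at 40 units,
up to 15 correct trials per side and side gain 2, and requires the
proactive regime to win the pre-approach distance comparison (and the
reactive regime the post-approach rate-difference comparison) in at
least 9 of 10 runs. Null calibration of the omnibus tests uses 200
seeded replicates and requires an empirical size of at most 7% at a
nominal 5%.

## Known limitations

- The latency–distance regression in the workflow has four sessions
  per cell; its coefficients illustrate the contract, not a powered
  inference.
- Broken-stick retention on strongly structured synthetic populations
  typically keeps 2–3 components; comparisons at the published
  subspace counts (84/56) therefore fix `n_components` explicitly.
- Duplicating every unit leaves explained-variance fractions and score
  directions unchanged but scales scores by √2 (loadings renormalize);
  exact score invariance under duplication does not hold for a
  norm-constrained decomposition.
- The CS− "approach" scoring window is a design choice; no access
  window exists on those trials.
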