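# twocap

Behavioral and neural-population analysis of the two-way cued access
protocol (2CAP), a shuttle-box task in which a visual CS+ predicts timed
sipper access to 10% alcohol. The package is built for the question of
*proactive versus reactive cognitive control* in alcohol seeking: does a
population of prefrontal neurons encode the upcoming left/right choice
before the animal moves (proactive — a maintained goal representation),
or only once alcohol access begins (reactive)?

It provides, as an R package plus a numbered analysis workflow:

- **Behavioral event extraction** from pose-tracking tables
  (three-row-header CSV dialect, 30 frames/s): interpolation of
  low-confidence frames, the 9-pixel snout-to-sipper approach rule,
  trial classification (correct / incorrect / omission), latencies,
  occupancy, CS discrimination ratio, per-epoch approach speeds.
- **Adaptive-kernel firing-rate estimation**: 100 ms bins smoothed with
  a per-neuron Gaussian kernel of width
  `sigma = sqrt(mean ISI) / CV(ISI)` (capped at 2 s), after strict
  sub-5% ISI-violation unit QC.
- **Population geometry**: cue-centered PCA (window [−4, 18] s, 221
  bins, first 15 trials, sessions stacked per strain) and
  side-concatenated PCA (left|right trial means concatenated in time,
  grouped by session type); component retention by the broken-stick
  rule
  `b_k = (1/p) * sum_{i=k..p} 1/i`
  (for p = 7 the first component must exceed 37% of explained
  variance); enumeration of all C(n, 3) three-component subspaces
  (84 for n = 9, 56 for n = 8); a bootstrap left/right distance
  statistic (1000 trial pairs per subspace, averaged over pre-approach
  time samples); loading-sign population splits at ±0.01 with
  pre/post-approach left−right rate differences.
- **Group statistics**: Kruskal–Wallis omnibus with Tukey–Kramer post
  hocs on the distance distributions, per-trial outcome chi-squared
  tests with FDR, per-strain MANOVA over session metrics,
  repeated-measures time-by-side interaction screens, and the
  `Latency ~ Distance × Session` regression with per-session-type
  Pearson correlations.
- **A synthetic-session generator** that emulates all three inputs
  (schedules, pose tracks, spike trains) with ground-truth labels,
  including the two encoding regimes: *proactive* populations carry
  side information before the approach, *reactive* populations after
  it. Every downstream stage is testable end to end without any
  recorded data.

## Worked example

```r
library(twocap)

# a congruent session from a proactive agent/population
s <- generate_session(session_type = "congruent", seed = 11)

# behavior: interpolate, detect approaches, summarize
pose <- interpolate_low_confidence(s$pose)
ev   <- detect_and_classify(pose, s$schedule, radius_px = 9)
m    <- session_metrics(ev, s$schedule)
c(m$n_correct, m$n_incorrect, m$n_omission)
#> [1] 43  2  3
round(m$cs_ratio, 2)
#> [1] 0.92

# the full approach-centered pipeline: QC, rates, side PCA,
# subspace distances, loading splits
res <- side_encoding_analysis(s, seed = 11, n_components = 9)
length(res$distance$mean_distance)   # 84 three-PC subspaces
#> [1] 84
round(mean(res$distance$mean_distance), 1)  # mean pre-approach L/R distance
#> [1] 19.6
```

The counts say 43 of 48 CS+ trials ended at the alcohol sipper on the
first attempt; the CS ratio of 0.92 (0.5 = chance) says the animal
discriminates CS+ from CS−. The 84 subspace distances measure how far
apart the left- and right-choice trajectories sit in each 3-PC space
before the approach — the quantity that separates proactive from
reactive populations (see `analysis/05_side_distance.R`, which runs the
Kruskal–Wallis comparison across strain × session-type conditions).

## Analysis workflow

`analysis/` contains numbered drivers that run the full study pipeline
on a synthetic cohort (2 strains × 2 session types × 4 sessions) and
write their tables under `results/`:

1. `01_simulate.R` — generate the cohort, tally ground truth
2. `02_behavior.R` — events, session metrics, MANOVA, per-trial tests
3. `03_rates.R` — QC, kernel widths, cue/sipper modulation indices
4. `04_cue_pca.R` — per-strain cue-centered PCA with broken stick
5. `05_side_distance.R` — side PCA, subspace distances, loading splits,
   interaction screen
6. `06_latency_regression.R` — latency ~ distance × session fits

Run each from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

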