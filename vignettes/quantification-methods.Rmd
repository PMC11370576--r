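---
title: "Quantification methods: leukocyte track behavior and calcium response scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods: leukocyte track behavior and calcium response scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitaltrace)
```

vitaltrace quantifies two live-imaging readouts used in airway
neuro-immunology: the motility behavior of leukocytes tracked by
intravital lung microscopy, and the stimulus responses of vagal sensory
neurons recorded by ratiometric (Fura-2) calcium imaging. This vignette
explains the models behind each stage, the parameters that matter, what
the synthetic generators do and do not emulate, and the design decisions
taken where the underlying conventions were open.

## Track metrics

A track is an ordered series of timed planar positions (seconds,
micrometres) of one cell in one field of view (FOV). Image stacks are
maximum-intensity projections, so positions are strictly 2-D; an
incoming `z_um` column is dropped with a warning. Four metrics are
computed per track:

* **duration** — last minus first timestamp (s);
* **total displacement** — the path length, i.e. the sum of Euclidean
  step lengths (μm);
* **net displacement** — the straight-line distance from first to last
  point (μm);
* **Track Speed Mean** — total displacement divided by duration (μm/s).

Track Speed Mean is deliberately the *duration-weighted* mean of step
speeds (path/duration) rather than the unweighted mean over steps. The
two coincide for evenly spaced frames; the weighted form is robust to
dropped frames and is applied identically to real and synthetic tables,
so classifier thresholds mean the same thing everywhere. Single-point
tracks have no speed; readers keep them but the metric and
classification stages exclude them with a logged count, since tracking
exports state no minimum track length.

Readers require explicit timestamps; when an export carries frame
indices instead, a frame interval (s/frame) must be supplied, because
intravital frame rates vary between rigs and are not recoverable from
the table itself.

## Behavior classification

Each track receives exactly one of four classes from Track Duration and
Track Speed Mean, evaluated as an ordered decision tree:

1. duration < 150 s → **tethering** (brief capture-and-release);
2. else speed ≤ 0.03 μm/s → **adherent** (immobile);
3. else duration ≥ 600 s → **crawling** (persistent motile movement —
   at least half of a 20-minute movie);
4. else → **patrolling** (motile transit of the FOV).

The published rule predicates do not pin down boundary equalities, so
the package fixes them explicitly: exactly 150 s is *not* tethering
("under 150 seconds" read strictly), exactly 600 s *is* crawling
(duration ties go to the more persistent class), and exactly 0.03 μm/s
is adherent (the cut is inclusive). The narrative cues about entering
and exiting the FOV are treated as descriptive, not as additional
predicates: only duration and speed are operational. The evaluation
order makes the rule set total — every finite (duration, speed) pair is
classified — which the tests verify against an independently coded
brute-force rule table on 10^4 random pairs plus the boundary values.

All three thresholds are configurable (`classifier_thresholds()`); for
a 1-hour macrophage movie the persistent-movement cut would be 1800 s.
Per-FOV summaries report class counts and frequencies over classified
tracks; frequencies always sum to 1.

## Synthetic tracks

`simulate_movie()` generates movies whose tracks realize the four modes
with controllable separation from the classifier cuts. Each track is a
correlated random walk: step lengths are gamma-distributed (positive,
unimodal) with mean `speed × Δt` and configured spread; headings turn by
a wrapped-normal angle whose standard deviation is `(1 − persistence)·π`
(0 maps to uniform headings, 1 to straight-line motion). Adherent and
crawling tracks reflect off the field borders (mirror reflection, which
preserves step lengths); patrolling and tethering tracks enter at a
border heading inward and terminate on border contact once past their
minimum lifetime, emulating FOV exit.

Defaults: frame interval 10 s (a realistic intravital sampling choice;
the rate is configurable because rigs differ), FOV 400 × 400 μm (a 20×
objective's field, order of magnitude), 20-minute movies. The
well-separated preset places modes clear of the cuts: adherent
0.005 μm/s for 1000–1200 s, crawling 0.12 μm/s for 700–1100 s,
patrolling 0.15 μm/s for 200–500 s, tethering 0.15 μm/s for 60–120 s
(speed spreads are 25 % of the mean). Under this preset the classifier
recovers ≥ 95 % of generation labels over 400 tracks — in practice 100 %,
because per-track mean speeds concentrate tightly around the mode mean.

One top-level seed draws an independent sub-seed per track, so changing
track counts does not perturb earlier tracks, and identical
seed + scenario yields bitwise-identical output.

What the generator does *not* emulate: chemotaxis gradients, cell–cell
interactions, alveolar geometry, tracking errors (gaps, switches) or
within-track behavior switching. Passing label-recovery tests therefore
demonstrates that the metric and rule pipeline is wired correctly — not
that the four classes are cleanly separable in real movies, where speeds
straddle the cuts.

## Calcium response scoring

Traces are F340/F380 ratio series per neuron, grouped by dish and batch,
sampled every 3–4 s. All scoring runs, by default, on a compressed trace:
the maximum ratio in each half-open 15-s bin `[k·15, (k+1)·15)`, stamped
at the bin start (`compress_max()`, idempotent by construction). A flag
(`compress = FALSE`) scores the raw trace instead, since whether peak
detection used the compressed or raw series is a recording-pipeline
convention; with maxima the two agree on peaks and differ only slightly
on baselines.

For each stimulus window the response score is

* **baseline** — the *mean* ratio over the 30 s preceding stimulation
  onset. A mean, not an endpoint value, because "measured 30 seconds
  prior" is ambiguous and the mean is noise-robust.
* **peak** — the maximum ratio from window start to window end plus a
  pad (default 30 s, always capped at the next window's onset), because
  calcium peaks can lag agonist washout.
* **amplitude** — peak / baseline (dimensionless, scale-invariant).

Windows sharing a stimulus name form an ascending concentration series
(e.g. AITC 10 → 30 → 100 μM at 60–90/90–120/120–150 s, then KCl 40 mM
at 420–435 s, available as `protocol_aitc_series()`); every window of a
series is scored against the single baseline before the series' first
window, since later windows have no clean local baseline.
`protocol_sensitization()` encodes the single-dose variant (AITC 300 μM
at 240–270 s, capsaicin 300 nM at 320–335 s, KCl 40 mM at 720–735 s).

**Responder calling.** A cell responds to a stimulus iff its amplitude
is ≥ the threshold, default 1.2 (a 20 % ratio rise over baseline). The
threshold is a scoring choice, not a published constant; it is exposed
everywhere and the CLI prints fractions at neighbouring thresholds so
its influence is visible. Cells enter denominators only if they respond
to the KCl window — depolarization recruits every viable neuron, so
KCl-negative cells are dead or not neurons. Downstream summaries follow
the dish-nested design: per-dish mean amplitude over responders only
(dishes with zero responders are excluded with a warning), per-dish
responder fractions, and fraction normalization by the mean of the
vehicle dishes within each batch (so each batch's vehicle mean is 1 by
construction).

## Synthetic traces

`simulate_batch()` draws per-cell responder labels (Bernoulli at the
configured fraction per condition; KCl independently at 0.95) and builds
each trace as a constant baseline plus, per stimulus responded to, a
transient rising linearly through the window to `baseline × amplitude`
at window end and decaying exponentially afterwards, plus Gaussian
noise. Defaults — baseline ratio 0.8, noise SD 0.03, decay constant
20 s, 3-s sampling, response amplitude 1.5, KCl amplitude 2.0 — are
plausible Fura-2 scales chosen once; no numeric trace values are
published to match.

Two numerical details make noise-free generation exactly recoverable:
the transient peaks at the window end, so whenever that end lies on the
sampling grid the sampled maximum equals the generated peak (scored
amplitude = configured amplitude to 1e−12); and the decay is truncated
at six time constants, so stimuli separated by more than 6·τ see an
exactly clean baseline. Closer windows are genuinely contaminated by the
decay tail — e.g. a capsaicin window 50 s after AITC washout scores an
amplitude slightly below 1 on an AITC-responding, capsaicin-negative
cell — which mirrors real recordings and is why protocols space their
windows.

The generator does not model photobleaching, baseline drift, dish-level
random effects, dose–response saturation across a concentration series,
or mechanistic channel kinetics; recovery results validate the scoring
pipeline, not robustness to those artefacts.

## Statistics

Hierarchical readouts (neurons within dishes) are aggregated to dish
means before testing (`nest_aggregate()`): the "nested one-way ANOVA"
is implemented as ordinary one-way ANOVA on per-dish averages, which
matches plotting per-dish averages and keeps the degrees of freedom on
the independent experimental units. A mixed model with dish as a random
effect would be the alternative reading; dish-mean aggregation was
chosen as the simpler, more conservative interpretation consistent with
the per-dish figures.

`one_way_anova()` is the classical between/within decomposition (tested
against a hand-coded sums-of-squares oracle to 1e−10), Bonferroni
post-hocs are per-pair Student t-tests multiplied by k(k−1)/2 and capped
at 1 (guaranteeing adjusted ≥ raw), Tukey post-hocs use the studentized
range, and `two_sample_test()` is the unpaired equal-variance Student
t-test (Welch by flag). SEM uses the n−1 standard deviation.

## Reports and determinism

`run_pipeline()` chains simulate → classify/score → `report()`. All
outputs are plain delimited text plus `report.json` with stable key
order; numbers in the JSON are rounded to 10 significant decimals purely
so that byte-identical reruns are achievable across platforms. Two runs
with the same seed produce byte-identical files — the basis of the
determinism test.

The bundled three-arm presets (`arm_presets()`) encode a qualitative
integration scenario: a control-like arm with few, mostly sessile
tracks; an exposure-like arm with many tracks dominated by
adherent/tethering behavior; an ablated-like arm with fewer tracks but a
larger motile fraction. The integration test checks that the report
reproduces the configured ordering (more tracks in the exposure-like
arm than the ablated-like arm; higher median total displacement in the
ablated-like arm). This is a statement about the synthetic scenario
wiring — counts and displacement statistics flowing correctly into the
report — not a biological claim.

## Problem sizes

The validation suite runs at deliberately modest sizes: 10^4
(duration, speed) pairs for the rule-table comparison, 400 tracks for
label recovery, 100 random tracks for metric invariances, 200 cells
(4 dishes × 50) for responder recovery, and 100 random datasets for the
ANOVA oracle. These sizes put Monte-Carlo noise well below the margins
being asserted while keeping a full run in seconds.

## Known limitations

* One class per track: no within-track behavior switching or HMM
  segmentation.
* Planar metrics only; no mean-squared-displacement or diffusion-model
  fitting.
* Responder threshold and baseline convention are documented choices;
  alternative conventions (instantaneous baseline, raw-trace peaks) are
  available by flag but conclusions should be checked under both.
* Vehicle normalization requires at least one vehicle dish per batch
  with a nonzero mean fraction; batches without one are an error rather
  than silently skipped.
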