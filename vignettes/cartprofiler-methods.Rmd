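---
title: "Methods: multiparametric potency profiling of CAR T cell products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric potency profiling of CAR T cell products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartprofiler)
library(dplyr)
```

## The problem

Clinical CAR T cell products vary widely in composition and function, and
that variability associates with patient outcome. `cartprofiler` implements
a desk-scale version of a multiparametric product-profiling workflow for
GD2-directed CAR T cells (with or without a constitutively active IL-7
receptor, C7R): high-dimensional spectral flow cytometry phenotyping, an
image-based serial tumor-killing assay, composite potency scorecards, and
post-treatment correlate statistics. Because clinical product data of this
kind are not publicly deposited, the package ships a synthetic-data module
that generates study-shaped inputs with known ground truth; every
downstream stage is exercised and tested against that ground truth.

## Synthetic data: what it emulates and what it does not

`simulate_event_tables()` draws cytometry events from a log-normal mixture
over a 33-marker panel. Each population has a log-location per marker
(baseline `log(50)`, bright `log(5000)`, spread 0.35 on the log scale) —
raw intensities are therefore strictly positive and right-skewed, as
unmixed spectral data are. A ten-product cohort (three CAR-only, seven
C7R co-expressing; outcomes one PR, four SD, five PD, encoded PD=0 < SD=1 <
PR=2) is simulated in unstimulated and stimulated conditions; stimulation
adds log-scale shifts to activation markers (CD137, IFN-γ, TNF-α, IL-2,
CD154, HLA-DR). CAR and C7R transduction are independent Bernoulli draws
(defaults 56.71% and 23.07%, the cohort means), and transduced events are
bright on the detection channels. Ground-truth population labels ride in a
`.population` metadata column that clustering operations never see:
`clustering_markers()` exposes marker channels only, and also excludes
CD3, viability and the transgene-detection channels by design.

The generator deliberately does **not** simulate spectral spillover or
unmixing error (inputs are post-unmixing), autofluorescence, doublets, or
negative baseline values. Population locations were chosen once for clear
separability (several log-SD apart), not for fidelity to any particular
clinical product — no per-population marker distributions are published.
Consequently, green clustering-recovery tests demonstrate algorithmic
correctness on well-posed mixtures, not performance on real products,
whose populations overlap far more.

`simulate_killing_series()` emulates an 11-round, 33-day serial
re-challenge assay imaged every 7 h. Within a round the tumor GFP area
follows `area0 * exp((g - k_r) t)` with `k_r = kill_rate * et_scaling *
round_decay^(round-1)`; the area resets to `area0` at each round's anchor
frame (fresh tumor added). Frames per round default to 11 (0–70 h by 7 h):
the assay cadence fixes 7-h imaging and 3-day rounds but not a frame
count, so the package picks the densest grid consistent with both.
Optional log-normal area noise is off by default. Because the model is
closed-form, the 33-day integrated value of any parameter setting has an
analytic double-sum oracle used directly in the tests.

`simulate_correlates()` gives each patient a latent responsiveness factor.
Cytokine concentrations follow `baseline * exp(effect * latent *
course(t))` with a rise-peak-wane time course over the grid {pre, 3 h,
week 1, week 2, week 4}; the default group effects plant a positive
inflammatory association and a negative regulatory one. Transgene
persistence rises linearly to a week-1 peak scaled by the latent factor,
then decays exponentially. The planted directions make Spearman-recovery
simulations well-defined.

## Cytometry processing

**Scaling.** `transform_arcsinh()` applies `asinh(x / cofactor)` per
channel. The cofactor defaults to 150 for every channel, the conventional
choice for flow data when panel-specific cofactors are not published; it
is configurable per channel. The table's `scale_state` attribute tracks
raw vs arcsinh so gates and thresholds are always interpreted on a known
scale, and double transformation is an error.

**Drift cleaning.** `clean_time_drift()` is a simplified acquisition-drift
cleaner: events are segmented along the time channel (500 events per
segment), each channel's segment means are standardised robustly (median
and MAD across segments), and a segment is removed when any channel
exceeds the threshold, capped at 30% of segments. The default threshold of
7 robust SDs follows the removal multiplier conventional in flow-cytometry
drift cleaning; a plain 3-SD rule over the ~dozens of segment-channel
statistics in a typical file would flag genuinely stationary data roughly
one file in ten, which is the wrong operating point for a cleaner. The
full valley/continuity cleaning heuristics of dedicated tools are
intentionally not reproduced, and the package does not claim equivalence
with them.

**Subsampling.** `subsample_events()` draws a seeded uniform subsample of
at most 100,000 events per sample (after viability/CD3 gating), the
standardisation that prevents donor bias in pooled analyses.

**Gating.** Gate trees are tibbles of interval predicates with strict
parent nesting; boolean signatures are conjunctions of per-marker
positivity calls inside a gated parent (by default single, viable
CD3+CD8+ cells). Per-marker positivity thresholds are not published for
this panel, so they come from configuration; the pipeline default places
them at the arcsinh image of the geometric midpoint (raw 500) between the
generator's dim (50) and bright (5000) modes. The four default signatures
mirror the response-associated CD8 phenotypes: GrzB+CD26+ (cytotoxicity),
BCL-2+CD26+CD154+ (activation), CD103+TIGIT+CD26+ (infiltration), TIGIT+
(resilience).

## Clustering and profiling

`fit_som()` trains a batch self-organizing map (default 10×10 grid, 10
epochs, seed 3421) with a Gaussian neighbourhood shrinking linearly from
half the grid width to 0.5. The final assignment is an exact
nearest-codebook search, so it can be (and is) verified against brute
force. Batch training was chosen over online updates for determinism and
vectorised speed; empty nodes are allowed and excluded downstream.

`metacluster()` consolidates occupied codebook vectors by average-linkage
hierarchical clustering cut at `k` — the automated counterpart of
refining SOM clusters by marker similarity, matching the linkage used for
the profile heatmaps. The two study-style analyses are config presets of
the same operations: an activation-focused run (k = 25, activation markers
plus embedding coordinates) and a full-marker run (k = 50 consolidated to
35).

`profile_clusters()` computes cluster × marker mean intensities, min-max
scales each marker across clusters to [0, 1] (a marker constant across
clusters scales to 0 by convention — no range, no evidence of presence),
calls presence at a scaled threshold of 0.58, and orders rows and columns
by average-linkage dendrograms. `cluster_abundance()` rows sum to 100 by
construction; `delta_mean_abundance()` fixes the subtraction convention as
C7R-group mean minus CAR-only mean (the captions in the source material
conflict on order; the convention is echoed in the output's `convention`
attribute). `outcome_association()` formalises the visual
lowest-in-PD/highest-in-PR trend as a Spearman correlation against the
ordinal outcome.

`embed_2d()` delegates to the established `umap-learn` implementation via
a Python subprocess with the study parameters (15 neighbors, minimum
distance 0.4, Euclidean metric, spectral initialisation, seed 2553).
Embedding internals are out of scope; the package asserts only contract
properties (determinism under a fixed seed, duplicate coherence, blob
separation).

## Killing scores

`percent_killing()` normalises each round to its anchor frame:
`100 - (area / area_t1) * 100`. The anchor is per-round — each
re-challenge resets the reference, which is what makes rounds comparable
— and negative values (net growth) are retained unclamped so growth
penalises the integrated scores. `killing_iv3()` sums a round's per-frame
percentages (anchor contributes 0); `killing_iv33()` sums the eleven
round IVs per product and E:T ratio. With 10 post-anchor frames, instant
full clearance gives exactly 1000 per round and 11,000 over the assay,
which the tests assert exactly. `quantify_gfp_area()` (Otsu or fixed
threshold, pixel counting) covers the upstream image step when raw frames
rather than pre-tabulated areas are available.

## Scorecards

`build_scorecards()` assembles five metrics per product — the four
signature frequencies and the 33-day IV at the 2:1 E:T ratio — z-scales
each metric across the cohort (sample SD), maps z-scores to radii, and
reports the radar polygon's shoelace area. How negative z-scores map to
radii is not published; the package's convention is a per-axis min-max map
onto [0.05, 1], the floor keeping every vertex off the origin so the
weakest product still has a polygon. Areas are therefore arbitrary units,
comparable only within a cohort scored together, and no numeric equality
with any published per-product area is claimed — ordering properties
(dominance monotonicity, cyclic-rotation invariance) are what the tests
assert. The axis order is fixed (cytotoxicity, activation, infiltration,
resilience, serial killing) because polygon area is not invariant to
arbitrary axis permutations; the order is recorded on the result.

## Correlate statistics

Cytokine group scores are member means per patient and timepoint (log
option available; whether the original scores used raw or log
concentrations is unstated, so raw is the default). Deltas are
later-minus-earlier for pre→wk1, pre→wk4, wk1→wk4. Associations use
Spearman rank correlation with midranks; persistence summaries use
trapezoidal AUC on the day grid (3 h = 0.125 days); the scorecard-area vs
persistence-AUC relationship uses Pearson correlation with OLS and 95%
CIs. No multiple-testing correction is applied by default — the analyses
are exploratory and labelled as such in the output — with a
Benjamini–Hochberg option available.

## Panel QC

`stain_index()` implements `(MFI_pos - MFI_neg) / (2 * SD_neg)` with MFI
as the arithmetic mean (median optional). `select_titration()` takes the
stain-index argmax, breaking ties toward the more dilute antibody (equal
resolution at lower cost). `fmo_variability()` computes per-marker SDs of
positive-cell frequencies across donors and applies the 8-percentage-point
pass rule; the threshold is interpreted in absolute percentage points.
The proprietary spectral complexity index is intentionally not
implemented.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → preprocess → cluster → killing →
scorecard → associate → qc from one configuration (R list or YAML), with
every stage seed derived deterministically from the global seed, and
writes CSV/JSON outputs plus a manifest carrying the package version,
seeds, a parameter echo and per-file MD5 checksums. Reruns with the same
seed are bit-identical; disabling a stage another depends on fails fast
with a stage-named error. The package's functions are the interface — the
stage subcommands map one-to-one onto exported functions, so partial runs
are ordinary R calls.

## Problem sizes and numerical choices

The test suite and the reproduction script run everything at desk scale,
chosen once as the smallest sizes at which each property is
well-conditioned: mixture-weight and transduction checks at 100,000
events (3-binomial-SD bands), subsampling at 250,000 → 100,000,
metacluster recovery at 20,000 events across 5 populations with centroids
≥ 3 SD apart (adjusted Rand index ≥ 0.9 via the independent `mclust`
implementation), nearest-codebook verification at 1,000 events × 100
nodes, correlation recovery as 200 simulations of 10-patient cohorts, and
the default pipeline demonstration at 10 products × 2,000 events. Exact
identities (IV arithmetic, shoelace areas, z-scaling, trapezoids, stain
index) are asserted at 1e-9 to 1e-12; statistical checks use 3-SD
binomial bands or ≥ 95%-of-simulations criteria.

## Known limitations

- Synthetic populations are separably placed; real products overlap, and
  clustering performance there is not evidenced by these tests.
- The drift cleaner is a segment-mean outlier rule, not a full
  valley/continuity algorithm.
- Scorecard areas depend on the z-to-radius convention; only orderings are
  meaningful across conventions.
- The FCS codec covers float list-mode files (as written by this package);
  integer or multi-dataset FCS files are out of scope.
- Printed clinical quantities (per-product 33-day IVs, the persistence
  correlation r = −0.07) derive from undeposited patient data and are not
  reproduction targets; the package reproduces the *methods*, with
  property-based evidence.
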