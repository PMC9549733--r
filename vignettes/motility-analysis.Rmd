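---
title: "Motility state-space analysis of single-cell tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motility state-space analysis of single-cell tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Time-lapse imaging of migrating cells — here, human iPSC-derived myogenic
progenitors whose motility responds to NOTCH/PDGF pathway stimulation —
yields per-cell trajectories: a position in micrometres at every frame.
The scientific questions are (i) which quantitative signatures distinguish
a motile, directed cell from a barely moving one, (ii) whether a cell
population decomposes into discrete motility phenotypes, and (iii) whether
a treatment shifts the balance between those phenotypes. `cellmotility`
implements that analysis chain for 2D dish assays and, with a rigid
drift-correction front end, for cells migrating on 3D bioengineered tissue
constructs.

Because the raw tracking data behind the original study is not deposited,
the package pairs every analysis stage with a seeded synthetic trajectory
generator whose statistics are known in closed form. All calibration claims
below are properties the test suite actually computes.

## Track model and filters

A track is a sequence of 2D or 3D positions (μm) at strictly increasing
integer frames with a fixed frame interval (minutes). The default 2D
acquisition emulates imaging every 10 min for 12 h (72 frames); the default
3D scene uses 12-min frames for 8 h (40 frames). Two inclusion filters are
applied before feature extraction:

* **length**: at least 61 observed frames (i.e. more than 60), the
  inclusion rule used for the 10-minute assays;
* **in-field**: optionally, any track that ever leaves the field-of-view
  bounds is dropped, since a cell that exits the field has a truncated,
  biased trajectory.

Tracking exports occasionally skip frames. Speeds are always normalised by
each step's own time span, so gapped steps are not inflated. Lag-based
statistics (MSD, Hurst, displacement autocorrelation, the non-Gaussian
parameter) require even sampling: gaps of at most 2 frames are bridged by
per-axis linear interpolation, larger gaps exclude the track from those
features only (the track keeps its path metrics, and the exclusion is
counted). Single-point tracks are dropped on ingestion with a logged count
rather than raising an error.

## The feature battery

For a track with positions $x_0 \dots x_{n-1}$ and steps
$s_i = x_{i+1} - x_i$:

* `total_distance` $= \sum_i |s_i|$ (μm); `net_distance`
  $= |x_{n-1} - x_0|$ (μm); `progressivity` $=$ net/total, 1 for a straight
  path, 0 for a closed loop, and defined as 0 for a track that never moves.
* `max_speed`, `min_speed`, `avg_speed` (μm/min) over per-step speeds.
* `linearity`: squared Pearson correlation of the x and y coordinate
  series; `spearmanrsq`: squared Spearman rank correlation. The squared
  correlation is symmetric in x and y, so a vertical track is not a
  singular case; a track with a constant coordinate is exactly axis-aligned
  and both metrics are defined as 1. For 3D tracks the two highest-variance
  axes are used. These two features are deliberately axis-dependent and are
  the only ones not rotation-invariant.
* `msd_slope`: the time-averaged mean-squared displacement
  $\mathrm{MSD}(\tau) = \langle |x_{i+\tau} - x_i|^2 \rangle_i$ is fitted by
  least squares in log–log space over lags $1..\min(20, \lfloor n/4
  \rfloor)$; the slope is 1 for diffusive and exactly 2 for ballistic
  motion (the ballistic case is a test assertion, not an approximation).
* `hurst_rs`: a rescaled-range persistence index (see below); 0.5 for
  memoryless motion, towards 1 for persistent/directed motion.
* `nongauss`: the non-Gaussian parameter $\alpha_2 = \langle \Delta x^4
  \rangle / (3 \langle \Delta x^2 \rangle^2) - 1$ per axis on lag-1
  displacements, averaged over axes; 0 for Gaussian steps, $-2/3$ for
  fixed-magnitude (Rademacher) steps, positive for heavy tails.
* `rw_linearity`, `rw_netdist`, `rw_kurtosis`: the observed linearity, net
  distance, and sub-track displacement kurtosis minus their means over 100
  matched random walks (same step count, step lengths resampled with
  replacement from the track's own steps, isotropic directions). These
  deltas are centred on zero for a true random walk — verified on a
  Brownian ensemble — and positive for directed motion.
* `time_moving`, `avg_moving_speed`: a step is "moving" if its speed
  exceeds a threshold (defaults 0.5, 1, 2 and 5 μm/min); per non-overlapping
  sub-track of 20 frames the moving fraction and the mean moving speed are
  computed and then averaged across sub-tracks.
* `autocorr` (lags 1, 2, 5): mean cosine between step directions a lag
  apart — 1 for constant direction, −1 for strict reversal, ≈0 for
  memoryless motion.
* `tm_*`: the TrackMate-style summaries — total distance, total
  displacement, mean straight-line speed (net distance over duration), and
  velocity (mean step speed).

The original tracking literature names these features but fixes none of the
windows, lags, or thresholds; all of them live in `feature_params()` with
the defaults above, and the documentation flags them as conventions of this
package rather than published constants.

Any feature that is undefined on a given track (stationary track, zero
variance, too short for a window) is recorded as `NA` — never silently 0 —
and per-feature missing counts are attached to the feature table.

### The Hurst estimator

Textbook rescaled-range analysis subtracts each window's mean increment
before accumulating, which makes the statistic blind to drift: a perfectly
directed track would score like noise. Since this feature is used as a
*directional persistence* readout (ballistic ⇒ near 1, Brownian ⇒ 0.5,
reversing ⇒ below 0.5), the package keeps the drift: per axis and per
window the statistic is the range of the raw cumulative increment sum
divided by the root-mean-square increment. Windows are dyadic, from 8
frames up to half the series.

The raw statistic is strongly biased at small windows (a plain log–log fit
on 72-frame Brownian tracks returns ≈0.64 rather than 0.5). The package
removes this bias analytically: for white-noise increments the expected
range of a $w$-step random walk is, by Spitzer's identity,
$E[R_w] = \sqrt{2/\pi}\sum_{k=1}^{w} k^{-1/2}$, and the estimator is
$H = 0.5 + \mathrm{slope}\left(\log(R/S)_w - \log E[R_w] \sim \log
w\right)$, clipped to $[0, 1]$. On 200 Brownian tracks of 72 frames the
ensemble mean lands near 0.47 (test-asserted within $[0.43, 0.57]$), a
512-frame ballistic track scores above 0.9, and strictly alternating steps
score 0.

### Displacement autocorrelation

"Similarity of the displacement series as a function of lag" admits two
readings: correlation of step *magnitudes* or alignment of step
*directions*. Only the directional reading satisfies the natural limiting
cases (constant velocity ⇒ 1 at every lag; strict reversal ⇒ −1; magnitudes
of those tracks are constant, so their magnitude correlation is undefined).
The reported `autocorr` feature is therefore the mean direction cosine per
lag; the magnitude-series Pearson autocorrelation is computed alongside as
a diagnostic (`autocorr_magnitude` in `displacement_autocorr()`).

## The synthetic generator

`simulate_tracks()` draws from five motion models. Brownian: i.i.d.
Normal(0, σ²) per axis per frame. Directed: constant velocity plus
Gaussian step noise. Lévy: Pareto step lengths with isotropic directions.
Persistent random walk (PRW): Ornstein–Uhlenbeck velocity with relaxation
time $P$ (min) and per-axis stationary velocity SD $S$ (μm/min); position
and velocity are advanced with the *exact* joint Gaussian transition of the
integrated OU process rather than an Euler step, so the ensemble MSD obeys
the Fürth form
$\mathrm{MSD}(t) = 2 d S^2 P\,(t - P(1 - e^{-t/P}))$
at any frame interval — the generator is validated against this closed form
within 5% at lags $P$ and $3P$ over 500 tracks. Mixtures draw a component
per track from configured proportions and return the component labels as
ground truth.

Determinism: each track consumes an RNG substream derived from the seed and
the track index, so the same seed reproduces tracks bit-for-bit and growing
`n_tracks` never reshuffles earlier tracks.

The default two-condition scenario (`default_scenario()`) encodes the study
conditions the package emulates: 2D, 10-min frames, 72 frames per track,
216 tracks per condition, each condition a mixture of a low-motility
Brownian regime (σ = 0.5 μm/step) and a motile persistent-walk regime
(S = 0.35 μm/min per axis, P = 60 min), with motile fractions 1/24
(untreated) versus 11/24 (treated) — the 4.17% and 45.83% printed in the
source study — plus 0.3 μm localisation noise. The regime parameters
themselves are this package's choice of "realistic": they give motile cells
speeds of order 0.5 μm/min and path lengths of a few hundred μm over 12 h,
versus tens of μm for the low-motility regime.

What the generator does *not* emulate: cell division and death, track
fragmentation and re-linking errors, spatially correlated (non-rigid)
tissue deformation, heavy-tailed localisation error, and cell–cell
interactions. Passing the planted-recovery tests therefore shows the
pipeline recovers known structure under idealised tracking, not that real
segmentation artefacts cannot distort the feature battery.

## State space, clustering, and testing

`reduce_and_cluster()` median-imputes missing features (logging the count),
z-scores each feature, and runs PCA. It keeps the smallest number of
components whose cumulative explained variance reaches 95%, capped at 30 —
the cap binds when the spectrum is flat. Ward-linkage agglomerative
clustering (Euclidean distance on the kept PC scores, `ward.D2`) is cut at
k = 2 clusters. Whether the original analysis z-scored before PCA is not
stated; z-scoring is assumed here, as is standard when features mix units.

Cluster labels from hierarchical clustering are arbitrary, so the package
fixes identity by ordering clusters by mean `total_distance`: cluster k is
always the most motile. This makes labels stable across seeds and track
orders, which the suite asserts. The silhouette is computed in the same
kept-PC space the clustering ran in — evaluating a clustering in a
different space than it was fitted in would conflate projection error with
cluster quality.

t-SNE (perplexity 35, seeded) is used for visualisation only; cluster
assignments never depend on the embedding, and the perplexity bound
`perplexity < (n−1)/3` is enforced.

Condition-by-cluster proportions are compared with Pearson's χ² test, no
continuity correction, df = (r−1)(c−1). The worked 2×2 example
[[23, 1], [13, 11]] — 4.17% versus 45.83% motile at 24 cells per condition
— gives χ² = 100/9 ≈ 11.11, p ≈ 8.6×10⁻⁴, verified in the tests against
the Pearson formula computed from first principles.

Group summaries for plotting normalise each feature to [0, 1] by min-max
scaling across all tracks before averaging per group (with SEMs). Min-max
is this package's choice — the original bar-chart normalisation is not
specified. A constant feature scales to 0 with a logged note.

For 3D scenes, where only total distance travelled is extracted,
`cluster_1d()` Ward-clusters the single standardised feature and orders
clusters by mean, mirroring the 2D relabelling rule.

## Drift correction for 3D constructs

A 3D tissue construct drifts rigidly during imaging, adding a shared
translation to every trajectory. Landmarks of the construct itself serve as
fiducials: tracks whose motion is mutually parallel are assumed to carry
only the drift.

Similarity between two fiducials is the cosine between their flattened,
*start-anchored* displacement series ($x_t - x_0$). Anchored displacements
rather than raw positions make the measure origin-independent; anchored
series rather than per-frame steps accumulate a slow drift across frames,
which matters quantitatively: with a 5 μm drift spread over 40 frames and
0.2 μm localisation jitter, per-frame steps give pairwise cosines near 0.56
(the per-step drift signal is comparable to the jitter), while anchored
series give ≈0.98 — only the latter is compatible with the published 0.95
threshold. The per-step variant remains available (`on = "steps"`) for
fast, jerky drift.

Fiducials with pairwise similarity ≥ 0.95 are connected in a graph; the
correlated set is the largest connected component with at least two members
(ties broken by higher mean internal similarity — a deterministic rule).
The drift path is the members' mean start-anchored displacement per frame,
and correction subtracts it from every cell position. On synthetic scenes
the suite asserts: a planted independent random walker is excluded; the
drift-path RMSE stays within $3 \cdot \mathrm{jitter}/\sqrt{n_\mathrm{members}}$;
corrected per-cell total distance is within 5% of the drift-free ground
truth; raising the threshold never grows the member set; and the whole
procedure commutes with a global translation of the scene.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed and is bit-reproducible;
`run_pipeline()` writes byte-identical bundles for identical
configurations, and every output table carries the package version and an
MD5 hash of the full configuration. The validation suite runs at the sizes
quoted above — 200-track Brownian calibrations, 500-track PRW/Fürth
comparison, 20 replicates of the 216-per-condition mixture scenario,
10-fiducial drift scenes — chosen so the whole suite completes in a few
minutes on one core while keeping Monte-Carlo standard errors well inside
the asserted bands.

## Known limitations

* The feature battery's windows and thresholds (sub-track length 20 frames,
  movement thresholds 0.5–5 μm/min, MSD fit lags, Hurst windows) are
  conventions; results at very different frame intervals warrant revisiting
  them.
* Per-axis features (`linearity`, `spearmanrsq`, and the per-axis averages
  `hurst_rs`, `nongauss`) are exactly reproducible but only statistically
  stable under rotation of the field of view.
* The per-track MSD slope of a finite Brownian track is slightly biased
  below 1 (log of a noisy average); ensemble means on 72-frame tracks sit
  near 0.96. The ballistic limit is exact.
* Drift correction is translation-only; rotational or non-rigid tissue
  deformation is out of scope, as is any image-level registration.
* The χ² test assumes independent cells; cells tracked in the same well are
  treated as independent, as in the source analysis.
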