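# cellmotility

Quantitative analysis of single-cell migration from time-lapse tracking
tables: a per-track motility feature battery, unsupervised discovery of
motility phenotypes, condition-proportion testing, and rigid drift
correction for cells migrating on 3D bioengineered tissue constructs. The
package targets the analysis of myogenic progenitor motility assays —
nuclei tracked every 10 minutes for 12 hours in 2D, and every 12 minutes on
3D artificial muscles — but any per-cell tracking table (including the
TrackMate CSV dialect) can be analysed.

## What it computes

For each track with positions $x_0 \dots x_{n-1}$ (μm) and steps
$s_i = x_{i+1} - x_i$, the feature battery includes:

* path metrics: total distance $\sum |s_i|$, net distance
  $|x_{n-1}-x_0|$, progressivity (net/total), min/avg/max speed (μm/min);
* shape metrics: squared Pearson (`linearity`) and Spearman
  (`spearmanrsq`) correlation of the coordinate series;
* dynamics: the log–log slope of the time-averaged mean-squared
  displacement $\mathrm{MSD}(\tau)=\langle|x_{i+\tau}-x_i|^2\rangle$
  (1 ≈ diffusive, 2 = ballistic), a bias-corrected rescaled-range Hurst
  exponent (0.5 = memoryless, →1 persistent), the non-Gaussian parameter
  $\alpha_2 = \langle\Delta x^4\rangle / (3\langle\Delta x^2\rangle^2) - 1$,
  step-direction autocorrelation at lags 1/2/5, and movement-occupancy
  statistics per speed threshold;
* random-walk baselines: observed linearity, net distance, and sub-track
  displacement kurtosis minus their means over matched isotropic random
  walks with resampled step lengths;
* TrackMate-style summaries (total displacement, mean straight-line speed,
  velocity).

Tracks are embedded in this feature space (z-score → PCA keeping ≥95%
variance, ≤30 components), clustered with Ward's method into k = 2
motility phenotypes, scored by silhouette, visualised by seeded t-SNE
(perplexity 35), and condition-by-cluster proportions are compared with
Pearson's χ² test. For 3D scenes, fiducial tracks of the construct with
pairwise motion cosine similarity ≥ 0.95 define a mean trajectory that is
subtracted from every cell track before analysis.

A seeded synthetic generator (Brownian, persistent random walk with exact
Ornstein–Uhlenbeck dynamics, directed, Lévy, and per-condition mixtures)
provides ground truth for every stage; see the methods vignette
(`vignettes/motility-analysis.Rmd`) for the models and estimator choices.

## Worked example

Simulate the default two-condition scenario (a low-motility/motile mixture
with motile fractions 1/24 untreated vs 11/24 treated), extract features,
and test the cluster proportions:

```r
library(cellmotility)

scen  <- default_scenario(n_tracks = 60, seed = 11)
sim_u <- simulate_tracks(scen$untreated, "untreated")
sim_t <- simulate_tracks(scen$treated, "treated")
ts    <- trackset(c(sim_u$tracks$tracks, sim_t$tracks$tracks))
ts
#> <trackset> 120 tracks, 2D, 10 min/frame, lengths 72-72

fm <- feature_table(filter_tracks(ts, min_length = 61))
round(fm[1:3, c("total_distance", "progressivity", "avg_speed",
                "msd_slope", "hurst_rs")], 3)
#>   total_distance progressivity avg_speed msd_slope hurst_rs
#> 1         53.263         0.091     0.075     1.070    0.427
#> 2         58.642         0.115     0.083     0.903    0.473
#> 3         56.550         0.059     0.080     0.600    0.368

ss <- reduce_and_cluster(fm, var_target = 0.95, max_components = 30, k = 2)
ss
#> <statespace_result> 120 tracks, 7 PCs kept (96.5% var), k = 2, silhouette 0.634

test <- condition_cluster_test(ss$cluster_labels, fm$condition)
test$contingency
#>            cluster
#> condition    1  2
#>   treated   30 30
#>   untreated 59  1
sprintf("chi2 = %.3f, df = %d, p = %.3g", test$chi2, test$df, test$p)
#> [1] "chi2 = 36.578, df = 1, p = 1.47e-09"
```

Cluster 2 is, by the package's fixed relabelling rule, the
high-total-distance (motile) cluster: 1.7% of untreated versus 50% of
treated cells land in it here, and the χ² test rejects equal proportions.
The first three rows show low-motility cells: total paths of ~55 μm over
12 h, speeds below 0.1 μm/min, MSD slopes around 1 and Hurst values at or
below 0.5 — diffusive, non-persistent movement.

`run_pipeline()` wraps the whole chain (simulation or table ingestion →
filters → features → state space → χ² → normalised group means) and writes
a reproducible, hash-stamped output bundle; `run_pipeline_3d()` does the
drift-corrected 3D chain. `inst/cli/cellmotility.R` exposes the same stages
as shell subcommands (`simulate`, `features`, `statespace`, `driftcorr`,
`run`).

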