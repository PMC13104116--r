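# recovnet

Quantitative analysis of cortical recovery after craniotomy, for
neuroscientists working with longitudinal mesoscale calcium imaging and
fluorescence morphometry. The package implements the full analysis chain by
which post-operative recovery is measured — stimulus-responsive neuron
detection, population decoding of grating orientation, functional-network
metrics, microglial/neuronal morphology quantification, and cross-modal
lag correlation — together with a synthetic-data module that generates
every input with known ground truth, so each stage is testable without any
raw recording.

## What it computes

**Responsive neurons.** A neuron is responsive to an orientation when its
mean ΔF/F over that orientation's 2-s stimulus windows strictly exceeds its
pooled pre-stimulus baseline mean plus three baseline SDs. Regional counts
and peak-normalized region × day distributions summarize where and when
responsiveness recovers.

**Decoding.** Population discrimination of the four grating orientations
(0°, 45°, 90°, 135°) by a one-vs-rest linear SVM under stratified 4-fold
cross-validation:

    Acc = N_correct_trials / N_total_trials

plus LDA embeddings of trial population vectors.

**Functional networks.** Pairwise Pearson correlation between neuron
traces or region-mean traces:

    Connectivity(x, y) = Σ(xᵢ − x̄)(yᵢ − ȳ) / √[Σ(xᵢ − x̄)² Σ(yᵢ − ȳ)²]

with mean connectivity, the strong-connection ratio (fraction of pairs
with r > 0.8), normalized spectral partitioning (k = 3), modularity

    Q = (1/2m) Σᵢⱼ [Aᵢⱼ − γ kᵢkⱼ/2m] δ(cᵢ, cⱼ)

and weighted degree centrality Σᵤ k(v, u). Negative-weight handling is
explicit configuration (clip to zero by default).

**Morphology.** Sholl profiles on binary cell masks (concentric circles in
2-µm steps; counts are connected foreground runs along each circle), their
maximum and trapezoidal AUC, mean fluorescence intensity, positive-area
fraction, and cell density.

**Longitudinal series.** Day-1 baseline normalization (cross-animal
baseline mean maps to exactly 1), linear interpolation to daily resolution
over days 1–56, sliding-window lag correlation (widths 7–35 days, the
fixed window anchored at day 1) with a tie-ruled best lag, and the
normality-gated test selection for timepoint comparisons (RM-ANOVA + Tukey
when every day passes Shapiro-Wilk, otherwise Friedman + Dunn with
Bonferroni correction).

**Synthetic data.** `session_params()` / `simulate_session()` generate
drifting-grating sessions (20 Hz, 3 sets × 8 repeats × 4 orientations,
8–10 s ISIs) with von Mises orientation tuning, an exponential calcium
kernel, community-structured shared noise, and full ground truth;
`recovery_scenario()` / `simulate_recovery()` generate an entire
longitudinal study across the eight post-operative timepoints (days 1, 4,
7, 10, 14, 21, 28, 56), including per-animal morphology series with an
injected, recoverable cross-modal lag.

## Worked example

```r
library(recovnet)

# one synthetic session at default study conditions
params <- session_params(n_neurons = 150)
atlas  <- make_atlas(K = 19, width = 4000, height = 3000)
sched  <- build_schedule(params, seed = 1)
ds     <- simulate_session(params, sched, atlas, seed = 1)
ds
#> <calcium_dataset> 150 neurons x 21392 frames @ 20 Hz, 96 trials, 19 regions

# stimulus-responsive neurons (baseline mean + 3 SD criterion)
rset <- detect_responsive(ds)
rset
#> <responsive_set> 73 / 150 neurons responsive (union)

# orientation decoding (stratified 4-fold linear SVM)
decoding_accuracy(trial_features(ds), folds = 4, seed = 1)
#> <decoding_result> Acc = 1.000 (96 / 96 trials)

# region-level functional network and its metrics
net <- region_network(ds)
round(c(mean_connectivity = mean_connectivity(net),
        strong_ratio = strong_ratio(net)), 3)
#> mean_connectivity      strong_ratio
#>             0.363             0.275
part <- spectral_partition(net, k = 3, seed = 1)
round(network_modularity(net, part), 3)
#> [1] 0.392
```

With half the neurons truly responsive at high signal-to-noise, detection
lands on 73/150, the four orientations are perfectly decodable, and the
three planted communities give a clearly modular region network
(Q ≈ 0.39 under the spectral partition).

A full longitudinal study with a designed network disruption at day 21 and
a 5-day microglia-to-neuron lag:

```r
scenario <- recovery_scenario(
  session = session_params(n_neurons = 95, n_sets = 1),
  trough_day = 21, lag_days = 5, seed = 3)
study <- simulate_recovery(scenario)

recovery_modularity(study, k = 3, seed = 1)
#>   day   modularity mean_connectivity strong_ratio
#> 1   1  0.362982471         0.3614549    0.2397661
#> 2   4  0.338015254         0.3683514    0.2163743
#> 3   7  0.220229871         0.4597554    0.2679739
#> 4  10  0.132769283         0.5749045    0.2923977
#> 5  14  0.008143100         0.8313186    0.4093567
#> 6  21 -0.020925722         0.9292702    1.0000000
#> 7  28  0.009853333         0.8157953    0.2982456
#> 8  56  0.395737609         0.3330355    0.1929825

best_lag(recovery_lag_analysis(study))
#> $lag
#> [1] 5
#> $r
#> [1] 0.9995953
#> $p
#> [1] 6.325662e-09
#> $width
#> [1] 7
```

Modularity (under the fixed day-1 partition) collapses toward the designed
day-21 trough while global coupling inflates mean connectivity and the
strong-connection ratio, and the injected 5-day lag between the microglial
and neuronal intensity series is recovered exactly.

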