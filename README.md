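# vepfit

Calibration of whole-brain Epileptor network models by cooperative scatter
search.

`vepfit` is for computational neuroscientists who want to estimate the
spatial map of epileptogenicity — which brain regions are epileptogenic
(EZ), which are candidates for seizure propagation (PZ), and which are
healthy (HZ) — by fitting a whole-brain network model to (simulated) SEEG
recordings with a parallel global optimizer, and to quantify how certain
those estimates are.

## The model and the estimation problem

Each region `i` of a structural connectome `C` carries the two-variable
reduction of the Epileptor neural mass model,

```
x_i' = 1 - x_i^3 - 2 x_i^2 - z_i + I
z_i' = (1/tau) * ( 4 (x_i - eta_i) - z_i - K * sum_j C_ij (x_j - x_i) )
```

with input current `I = 3.1`, per-region excitability `eta_i`, time-scale
separation `tau`, and global coupling `K`. An isolated region seizes
autonomously when `eta > eta_c ≈ -2.05`; regions within `delta_eta = 1`
below the threshold can be recruited through the network (PZ), and regions
further below are healthy. SEEG sensors observe
`S_i(t) = sum_j G_ij exp(x_j(t))` through an inverse-square gain matrix
`G`, which is rank-deficient for sparse implantations.

Calibration minimizes the RMSE between an observed series and the model's
forward simulation over `theta = (eta_1..eta_N, K)`, using cooperating
enhanced scatter-search (eSS) workers with dynamic hill-climbing local
search, asynchronous best-solution exchange through a master, and
scoreboard-driven reconfiguration of underperforming workers. The archive
of all evaluated solutions afterwards yields ensemble uncertainty bands
per parameter. Six benchmark problems (deterministic/stochastic, weak/
strong coupling, source/sensor observation) are generated synthetically
with known ground truth.

## Worked example

```r
library(vepfit)

# benchmark 2: deterministic, weak coupling, observed at 8 SEEG sensors
# through a rank-deficient gain; 12 regions with 2 EZ / 3 PZ ground truth
pb <- make_problem(2, n_regions = 12, seed = 7, n_sensors = 8)
pb$problem
#> <vep_problem 2> weak coupling, deterministic, observed at sensor level | 12 regions, 8 channels

fit <- fit_problem(pb$problem, pb$observed, n_workers = 2,
                   max_evals = 2e5, seed = 1)
fit
#> <vep_fit> best cost 3.62053e-05 after 198375 evaluations (2 workers)

score_fit(fit, pb$problem)
#> <vep_confusion> accuracy 100.0%
#>      predicted
#> truth EZ PZ HZ
#>    EZ  2  0  0
#>    PZ  0  3  0
#>    HZ  0  0  7
```

The fitted cost is the root-mean-square error between the observed sensor
series and the series simulated under the recovered parameters: values
near zero mean the deterministic benchmark is solved essentially exactly.
`score_fit()` classifies the recovered excitabilities with the
`eta_c`/`delta_eta` thresholds and tabulates them against the ground
truth; 100% accuracy reproduces the benchmark's headline result. The
archive behind `fit` feeds `filter_archive() |>
subsample_representative() |> percentile_bands()` for per-parameter
uncertainty bands, and `autoplot()` methods plot trajectories, sensor
series, convergence traces, and bands.

A thin command-line wrapper over the same functions lives at
`inst/cli/vep` (subcommands `generate`, `simulate`, `fit`, `uq`,
`evaluate`).

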