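---
title: "Calibrating whole-brain Epileptor network models with cooperative scatter search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating whole-brain Epileptor network models with cooperative scatter search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vepfit)
```

## The model

Each brain region carries the two-variable reduction of the Epileptor neural
mass model: a fast variable $x_i$ and a slow permittivity variable $z_i$,

$$\dot x_i = 1 - x_i^3 - 2x_i^2 - z_i + I, \qquad
  \dot z_i = \frac{1}{\tau}\Big(4(x_i - \eta_i) - z_i -
  K \sum_j C_{ij}(x_j - x_i)\Big),$$

with input current $I = 3.1$, per-region excitability $\eta_i$ (the Hopf
bifurcation parameter), time-scale separation $\tau$, and a diffusive
permittivity coupling of strength $K$ over the structural connectome
$C_{ij}$ (non-negative, symmetric, normalized to maximum entry 1). Time is
dimensionless; only ratios of $\tau$, the integration step, and durations
matter. Integration is forward Euler at `dt = 0.1` from the initial
condition $(x, z) = (-2.5, 3.5)$ in every region; the stochastic variants
use Euler-Maruyama with independent $\sigma\sqrt{dt}\,\xi$ increments in
both equations ($\sigma$ is configurable per model; the noise-free path is
bitwise identical to the ODE integrator). External inputs are identically
zero: the benchmarks define no stimulus. Integration aborts if any state
exceeds $10^6$ in magnitude; the calibration cost maps that to an infinite
cost so the optimizer simply discards the candidate.

An isolated region ($K = 0$) has exactly one fixed point (the nullcline
cubic is strictly monotone), which loses stability through a Hopf
bifurcation as $\eta$ grows. `isolated_fixed_points()` solves the cubic and
classifies the Jacobian; `critical_excitability()` brackets the stability
loss on an $\eta$ grid and bisects to $10^{-3}$. At large time-scale
separation the critical value is $\eta_c \approx -2.05$ ($-2.056$ at
$\tau = 40$, approaching $-2.062$ as $\tau \to \infty$; the value depends
only weakly on $\tau$ through the $1/\tau$ term in the Jacobian trace). A
fixed point exactly at the Hopf margin (trace within $10^{-9}$ of zero) is
labelled unstable, breaking the tie toward seizure onset.

Regions are classified by excitability relative to $\eta_c = -2.05$ with
margin $\Delta\eta = 1$: epileptogenic (EZ) above $\eta_c$, propagation
zone (PZ) within $\Delta\eta$ below it, healthy (HZ) below that. Ties at a
threshold resolve toward the less pathological class, keeping the strict
inequality for the more pathological one.

## The forward problem

SEEG sensors see an exponential mapping of the fast variables,
$S_i(t) = \sum_j G_{ij} e^{x_j(t)}$, through an inverse-square gain
$G_{ij} = \sum_{k \in V_j} c\,A_k / |x^s_i - x^v_k|^2$ summed over the
area-weighted vertices of each region. Orientation-dependent decay is not
modelled. With fewer sensors than regions the gain is rank-deficient,
which is precisely the identifiability challenge of the sensor-level
benchmarks. The envelope operator (`seeg_envelope()`) is a sliding-window
RMS of the locally mean-removed signal — chosen over an analytic-signal
transform for determinism and statelessness; it is a visualization and
optional preprocessing tool, while the default calibration cost uses the
raw series.

## The benchmark generator

Six benchmark estimation problems span the model's regimes:
deterministic/weak-coupling (1, 2), deterministic/strong-coupling (3, 4),
and stochastic/stiff (5, 6), each observed at source level (odd ids,
identity gain) or sensor level (even ids, rank-deficient synthetic gain).
The estimation target is $\theta = (\eta_1, \dots, \eta_{N_n}, K)$ with
bounds $\eta_i \in [-5, -1]$ and $K \in [0, 2]$, and the cost is the RMSE
between the candidate's forward simulation (mapped to the observation
level) and the stored observation over all samples and channels.

Several study conditions are not published and are fixed here once, on
dynamical grounds:

* **Excitability draws.** EZ $\sim U[-1.9, -1.5]$, PZ $\sim U[-2.4, -2.1]$,
  HZ $\sim U[-3.8, -3.2]$ — margins keep every draw away from both
  classification thresholds. Default scenario: 2 EZ, 3 PZ.
* **Coupling.** Weak $K = 0.1$, strong $K = 1.5$. Diffusive coupling is
  homogenizing: in a dense connectome the drag of the many quiescent
  regions quenches the epileptogenic oscillators before any PZ is
  recruited, at every coupling strength. The benchmark connectome
  therefore encodes an explicit seizure-spread network, as in patient
  anatomy where the propagation zone is the tissue most strongly wired to
  the epileptogenic zone: a heavy-tailed log-normal background connectome
  scaled by $1/N_n$ (mean-field scaling keeps total background input per
  region bounded with network size) plus one maximal-weight edge from each
  PZ region to an EZ region. Under these defaults the weak regime shows no
  recruitment (late-time fast-variable range of every non-EZ region below
  0.5) and the strong regime recruits every PZ without recruiting HZ, at
  both 12 and 84 regions.
* **Time scales and window.** $\tau = 10$ for problems 1-4 and $\tau = 90$
  for the stiff problems 5-6, lengthening the seizure roughly ninefold. An
  isolated epileptogenic node at $\tau = 10$ cycles with period
  $\approx 12.5$ time units, so the default windows — 100 units for 1-4,
  900 for 5-6 — contain a handful of seizure events, matching the
  qualitative appearance of whole-brain seizure recordings. Much longer
  windows would accumulate dozens of stereotyped cycles and make the
  deterministic cost pathologically phase-sensitive (the width of the
  global basin around the true excitability of a seizing region shrinks
  roughly inversely with the number of observed cycles; at 60+ cycles it
  is below $10^{-2}$ in $\eta$, which no desk-scale budget can find).
  Observations store every 10th Euler step.
* **Implantation geometry.** Sensor positions, region vertices, and areas
  are synthetic (`synth_geometry()`), emulating a parcellated cortical
  sheet: each region is an extended surface patch on a 60 mm sphere
  (tangential spread 0.35 rad, patch areas of a few thousand mm²,
  area-weighted vertices), and depth-electrode contacts sit inside the
  sphere, each placed along the direction of the region currently least
  covered by the montage, as clinical implantations are planned for
  coverage. Region extent matters: with point-like regions in a volume, a
  few regions are essentially invisible through the inverse-square gain
  and their zone labels are not practically identifiable — label flips
  cost less than $10^{-6}$ RMSE — whereas extended patches keep every
  region's visibility within a factor of ~2 of the median. A conditioning
  safeguard (`plan_montage()`) redraws montages whose gain falls below a
  relative-singular-value floor. Default 8 sensors per 12 regions (scaled
  from roughly 60 per 84), always fewer than regions, so the gain stays
  rank-deficient. The gain scale $c$ defaults to 1.

## The optimizer

`run_ess()` implements enhanced scatter search: a Latin-hypercube
diversification sample (10 x dimension) seeds a reference set (size
$2\lceil\sqrt{d}\,\rceil$ rounded to even) split between best-cost and
max-min-diverse members; members are combined pairwise by uniform draws
from the hyper-rectangle they span, expanded by the pair's displacement
(asymmetrically — the `balance` setting shrinks the expansion on the worse
parent's side); children that improve both parents trigger the go-beyond
rule, which keeps stepping along the improvement direction and halves the
advance factor after each pair of consecutive successes. Dynamic hill
climbing (coordinate moves with step doubling on success, halving on
failure, termination below $10^{-9}$) periodically refines the best
unrefined member. Duplicates (normalized distance below $10^{-8}$) are
rejected and stagnation regenerates the worst half of the reference set.

`run_cooperative()` steps several workers with heterogeneous settings
round-robin in one process, each worker on its own random stream — the
in-process analogue of the island-model master-worker scheme, preserving
its communication contract (workers exchange only `(theta, cost)` records
through the master, never shared state). The master re-broadcasts a
worker's best only when it improves the last broadcast by more than
`improvement_threshold` (10%) relatively — halved after each streak of
more than 20 rejected improvements — and registers accepted improvements
on a scoreboard; a worker that spends `reconfigure_after_evals`
evaluations without an accepted improvement receives a ±20%-jittered copy
of the current best scorer's settings and partially regenerates its
reference set. With a single worker no master intervention is possible and
the run is identical to `run_ess()`. Asynchrony is modelled by the
round-robin interleaving; determinism under fixed seeds is retained, and
with more workers the returned best is always the archive argmin.

For stochastic problems each candidate is scored on a single fresh noise
path whose seed is drawn from the worker's stream and stored in the
archive for replay.

`fit_problem()` adds model-aware layers used by the shipped benchmarks,
all drawing from one shared evaluation budget:

1. *Horizon continuation*: the workers first calibrate against the opening
   fraction of the observation window, where all regions still relax from
   the common initial condition and the cost surface is smooth in every
   excitability; the diverse near-optima of that stage seed the first
   worker's reference set for the full-window optimization (the other
   workers keep an independent inductive bias).
2. *Zone-pair relabeling refinement*: coordinate search on rank-deficient
   sensor problems gets trapped in two characteristic ways — two weakly
   observed quiescent regions trade excitability levels at almost no
   cost, parking one a zone too high, or a healthy region seizes in place
   of the true epileptogenic one (an oscillator identity swap that looks
   similar through the gain). Both are pairwise relabelings, so the
   refinement clamps single regions and region pairs to representative
   zone levels, re-relaxes each candidate with hill climbing (cheap
   candidates fully, one short screening descent per pair otherwise — a
   swap candidate often starts worse than the incumbent but descends far
   below it), and accepts only strict cost improvements.
3. A final hill-climbing polish of the incumbent.

## Uncertainty quantification

The optimizer archives every evaluated parameter vector with its cost.
`filter_archive()` keeps the near-optimal slice (cost below
`rel_threshold` x best for deterministic problems; below best +
`rel_threshold` x the cost spread for stochastic ones, where the cost
itself fluctuates), `subsample_representative()` selects a
farthest-point subsample (default 500) anchored at the best solution, and
`percentile_bands()` reports per-parameter percentiles (default 5/25/50/
75/95) of bounds-normalized values — the parallel-coordinates band plot
around the median. The threshold (10) and subsample size are practical
defaults: dense enough for stable bands, small enough not to dominate
runtime. On matched scaled runs the sensor-level problems show visibly
wider bands than their source-level twins, reflecting the rank-deficient
gain.

## Numerical choices and degenerate inputs

* Forward Euler is first order; halving `dt` halves the trajectory error
  at fixed horizon. The benchmark step 0.1 resolves the fast variable's
  relaxation spikes at $\tau \ge 10$.
* Costs compare like with like: candidate simulations run at the same
  `dt` and downsampling as the stored observation.
* `cost_rmse()` clamps out-of-bounds parameters (with a warning) rather
  than failing, so local-search probes at the boundary stay defined.
* Non-finite costs (diverged simulations) become `Inf`; initialization
  fails only if the whole diversification sample is non-finite.
* Degenerate geometry (a sensor exactly on a vertex) and ragged or
  non-numeric matrix files are rejected with the offending sensor/vertex
  or line named.

## What the synthetic benchmarks do and do not show

The generator emulates the structure of the in-silico study: connectome
normalization, zone placement, rank-deficient sensing, process noise, and
the six problem regimes. It does not emulate patient tractography (fibre
counts, spatial embedding of the Desikan-Killiany parcellation), real
SEEG physics (bipolar referencing, electrode geometry, volume
conduction), or clinical uncertainty in the zone hypothesis. Passing
benchmarks therefore demonstrates that the calibration machinery recovers
known ground truth under the stated observation models — not clinical
validity on empirical recordings.

## Problem sizes in the shipped tests

The test suite and the acceptance script run scaled-down instances — 12
regions, 8 sensors, 2 workers, at most $2 \times 10^5$ cost evaluations —
chosen so the full benchmark suite completes on a single CPU while
preserving every qualitative regime (recruitment, rank deficiency,
stochastic-cost floors, sensor-versus-source uncertainty ordering).
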