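# oscbalance

Event-synchronization effective networks and the oscillation-balance
index for multichannel intracranial EEG.

## What it does, and for whom

Focal seizures reorganise how recording sites interact: activity that is
normally balanced between *segregated* (strong local) and *integrated*
(slow global) modes collapses into hypersynchronous local circuits.
`oscbalance` is for researchers who want to quantify that reorganisation
from multichannel intracranial-EEG-like signals (or from fully synthetic
recordings with known ground truth, which the package generates).

The pipeline has three stages:

1. **Event-based directed network.** Events are sharp local maxima: sample
   `t` is an event when `x[t] > x[t+m]` for all `|m| < M` and
   `x[t] > x[t±M] + h` (defaults `M = 10` samples, `h = 30`). For channels
   `x¹, x²` with event counts `m₁, m₂`, directed counts within the
   pair-adaptive delay `τ` (half the smallest adjacent inter-event
   interval around nearest event pairs) give

       Q = (e(x²|x¹) + e(x¹|x²)) / √(m₁ m₂)   ∈ [0, 1]
       q = (e(x²|x¹) − e(x¹|x²)) / √(m₁ m₂)   ∈ [−1, 1]

   with `q > 0` meaning channel 1 drives channel 2. Windowed growth rates
   of the cumulative counts over `Δn = 5120` samples yield the
   time-resolved weighted directed adjacency
   `a_ij(n) = γ · dq_ij(n) · dQ_ij(n)` for `dq > 0` (else 0), `γ = 1000`,
   zero diagonal.

2. **Complex eigenmode hierarchy.** The asymmetric `a_ij(n)` is
   eigendecomposed; layers are ranked by eigenvalue modulus `|Λ_i|`. The
   undivided leading layer gives the slow-global index
   `H_in = |Λ₁|² / N²`; every further layer is split into weak / balance /
   strong bands of its component moduli (thresholds `AVG + SD`,
   `AVG + 2·SD`) and contributes
   `H_i = |Λ_i|² · M_i · (1 − p_i) / N²` to the strong-local index
   `H_se = Σ_{i≥2} H_i`, where `M_i` counts nonempty bands and
   `p_i = Σ_j |m_j − N/M_i| / N` discounts module-size heterogeneity.

3. **Balance dynamics.** `H_sb = (H_in − H_se)/(H_in + H_se) ∈ [−1, 1]`
   (negative = strong-local dominance). Per seizure phase the package
   reports its Gaussian-kernel density, the density-peak location, mode
   counts, and drop–rebound ("plunge") episodes of the peak track — for
   the global montage and for scoped sub-networks (epileptogenic /
   non-epileptogenic channel subsets).

## Worked example

```r
library(oscbalance)

sim <- simulate_recording(synth_patient_config(seed = 1))
sim$recording
#> <recording> 16 channels x 81920 samples @ 512 Hz (160 s)
#>   phases: interictal, preictal, ictal, postictal

net <- build_network(sim$recording, stride = 2560)
net
#> <effective_network> 16 nodes, 31 snapshots (delta_n = 5120,
#>   stride = 2560, gamma = 1000)

idx <- index_time_course(net)
iv  <- phase_intervals(sim$recording$annotations)
(pk <- interval_peaks(idx, iv))
#> # A tibble: 8 x 6
#>   interval phase          n   peak_x peak_density n_modes
#>      <int> <chr>      <int>    <dbl>        <dbl>   <int>
#> 1        1 interictal     5 -0.00587        0.699       1
#> 2        2 interictal     6  0.00196        2.16        2
#> 3        3 preictal       3 -0.00587        0.662       1
#> 4        4 preictal       3 -0.00587        0.662       1
#> 5        5 ictal          4 -0.444         3.02         2
#> 6        6 ictal          4 -0.530         5.56         3
#> 7        7 postictal      3 -0.00196       1.82         2
#> 8        8 postictal      3  0.00196       2.96         2

peak_track(pk)
#> <plunge_stats> 1 episode(s); peak_x range [-0.53, 0.00196]
#>   (length 0.532), threshold 0.3

glance(kde_hsb(idx$H_sb_norm[idx$phase == "ictal"]))
#> # A tibble: 1 x 5
#>       n bandwidth peak_x peak_density n_modes
#> 1     8    0.0528 -0.542         3.78       1
```

Reading the numbers: outside the seizure the density peak of the balance
index sits at 0 — strong-local and slow-global modes in metastable
balance. During the ictal phase the peak plunges to about −0.5 (the
re-entrant focus circuit dominates the eigenmode hierarchy), then rebounds
post-ictally; the peak tracker counts exactly one drop-and-rebound
episode. `autoplot(idx)`, `autoplot(peak_track(pk))` and
`autoplot(kde_hsb(...))` draw the corresponding time courses, peak tracks
and densities, and `scoped_analysis()` repeats everything on channel
subsets (the focus-only scope plunges deeper than the global montage).

`run_pipeline(pipeline_config(), out_dir)` executes the whole chain and
writes `indices.csv`, `peaks.csv`, `plunge_report.csv`, `densities.csv`,
and a seed/config-hash-stamped log.

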