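---
title: "Event-synchronization networks and the oscillation-balance index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-synchronization networks and the oscillation-balance index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intracranial EEG of focal epilepsy shows abrupt reorganisation of the
interactions between recording sites around seizures. `oscbalance`
quantifies that reorganisation in three stages:

1. **Event-based effective network.** Each channel is reduced to a train of
   sharp transient events (large local maxima). For every channel pair, the
   lag structure of quasi-coincident events yields a synchronization index
   `Q` and a signed directionality index `q`; windowed growth rates of their
   cumulative counts define a time-resolved, weighted, *directed* adjacency
   matrix — the effective network.
2. **Complex eigenmode hierarchy.** Because the adjacency is asymmetric, its
   eigenvalues and eigenvectors are complex. Layers are ranked by eigenvalue
   modulus. The undivided leading layer measures *slow global* integration
   (`H_in`); every further layer is partitioned into weak / balance / strong
   bands by its component moduli and contributes to the *strong local*
   index (`H_se`), discounted for module-size heterogeneity.
3. **Balance dynamics.** The normalized balance
   `H_sb = (H_in - H_se) / (H_in + H_se)` lies in `[-1, 1]`: negative means
   strong-local (segregated) dominance, positive slow-global (integrated)
   dominance. Its kernel-density distribution per seizure phase, the
   location of the density peak, and drop–rebound ("plunge") episodes of
   that peak summarise how seizures disturb the balance.

## Event detection and pairwise indices

A sample `t` is an event when it exceeds all neighbours within `M - 1`
samples on both sides and exceeds the samples exactly `M` away by at least
the margin `h`. Defaults `M = 10` samples and `h = 30` signal units; with
the 512 Hz sampling rate used throughout, `M` corresponds to about 20 ms.
Events are therefore at least `M` samples apart and never occur within `M`
of the series ends.

The pair delay scale `tau` is half the smallest adjacent inter-event
interval around temporally nearest interior event pairs, minimised over
the pair. This guarantees a one-to-one matching within `tau`, which is what
bounds `Q` by 1. Two conventions required a decision:

* **Normalization.** The denominator is `sqrt(m1 * m2)` by default
  (`normalization_mode = "sqrt_mm"`), the classical event-synchronization
  convention, because it is the one under which the stated bounds and
  extremes (`Q = 1` on full coincidence, `q = 1` on a perfect lagged
  pairing) actually hold; the plain product `m1 * m2` is retained as
  `product_mm` for fidelity to the formula as often printed.
* **Direction.** `q > 0` means the *first* channel drives the second, and
  the network weight `a[i, j]` encodes "node `i` acts on node `j`". This
  is fixed and used consistently everywhere (network build, scoped
  analyses, ground-truth recovery tests).
* **Delay scope.** `tau` is computed once per channel pair over the full
  analysed segment, not per window: the delay rule is defined per pair,
  and windowed re-estimation is both noisier and nowhere required. When a
  pair has no interior nearest-neighbour pair (two-event trains), `tau`
  falls back to half the minimum adjacent interval over both trains.
* **Degenerate pairs.** Channels with fewer than two events give
  `Q = q = 0` and zero adjacency entries — the conservative "no evidence"
  value.

Cumulative counts attribute each matched pair to the time of its
effect-side event through the step function, so `Qn(n)` is nondecreasing.
Rates over a trailing window of `delta_n = 5120` samples (10 s at 512 Hz)
divide the count increments by the product of the per-train event counts in
the closed band `[n - delta_n, n]`, and are defined as 0 for empty windows.
The edge weight is `gamma * dq * dQ` when `dq > 0` and 0 otherwise, with
`gamma = 1000`; the diagonal is identically zero. Snapshots are emitted at
stride points (default `stride = delta_n`; the analyses in this package use
1280–2560 samples where a denser sampling of the index time course is
useful).

All sample indices are 1-based with closed windows, the native R
convention; a single convention everywhere prevents off-by-one drift
between stages.

## Eigenmode hierarchy: numerical choices

* `Lambda^2` is read as the squared modulus `|Lambda|^2`: for complex
  eigenvalues only the modulus measures stretch.
* Eigenvectors are scaled to unit 2-norm before their component moduli are
  taken; conjugate pairs then share component moduli exactly, and both
  members of a pair are summed in `H_se` (the sum over layers 2..N is
  taken as written, without conjugate deduplication).
* Band thresholds `AVG + SD` and `AVG + 2 SD` use the eigenvector's own
  components (per layer, not pooled), the sample standard deviation, and
  left-open/right-closed intervals. The weak band is closed at zero so
  exactly-zero components always belong to a module and module sizes sum
  to `N`. Comparisons carry an absolute tolerance of
  `1e-9 * (1 + max modulus)`: an eigenvector with numerically equal
  components must land in a single module deterministically, and `eigen()`
  returns such components with ~1e-16 jitter.
* The heterogeneity correction `p = sum_j |m_j - N / M| / N` is **capped at
  1**. For `N > 12` the raw sum can exceed 1 (three very skewed modules,
  e.g. sizes 14/1/1 at `N = 16` give 1.08), which would make a layer
  "measure" negative and push the normalized balance outside `[-1, 1]`.
  The cap keeps every layer measure nonnegative and the balance bounded,
  at the cost of treating extremely skewed three-band layers as
  contributing nothing.
* **Acyclic snapshots are assigned an exactly zero spectrum.** A directed
  graph without cycles has a nilpotent adjacency, whose true eigenvalues
  are all zero; dense eigensolvers instead return spurious moduli of order
  `norm * eps^(1/N)` (about 1% of the matrix norm at `N = 8`), and the
  *ratio* `H_sb` of such noise is meaningless. The package therefore checks
  the nonzero pattern with a DAG test (exact, cheap) and zeroes the moduli.
  Sparse "no structure" snapshots then give `H_in = H_se = 0` and, by
  convention, `H_sb = 0`.
* `H_sb` normalization: the per-snapshot ratio
  `(H_in - H_se) / (H_in + H_se)` (0 when both are 0) is the default —
  bounded by construction, sign-preserving, and causal (no look-ahead over
  the recording). Dividing the raw difference by its maximum absolute value
  over the time course (`hsb_normalization = "max_abs"`) is available for
  comparison but depends on the whole recording.

A property worth knowing when interpreting results: the band rule
discounts layers whose eigenvectors are *concentrated* on a small fraction
of the nodes (they produce few, very unequal modules, so `M (1 - p)` is
small), while layers spread evenly over the analysed nodes pass at full
weight. Consequently the same localized circuit looks maximally segregated
when analysed within its own channel subset and only partially segregated
at the global scope — which is precisely the behaviour the scoped analyses
exploit. For near-homogeneous eigenvectors the split between "all weak"
and "one strong component" is generic noise, so the discount (and with it
the depth of a plunge) alternates between a small number of attractor
values; phase-pooled densities are used where stability matters.

## Phase dynamics

Kernel densities of `H_sb` use a Gaussian kernel with Silverman's
rule-of-thumb bandwidth on a fixed 512-point grid over `[-1, 1]`, and are
renormalized by their trapezoidal integral on the grid so the reported
curve is a unit-mass density even when the bandwidth would leak mass past
the closed interval. Degenerate samples (all values equal, Silverman
bandwidth 0) fall back to a bandwidth of 0.01 — half a percent of the
range. Modes are local maxima with topographic prominence at least 5% of
the peak density; the bimodal/unimodal labels in phase summaries come from
this count.

Each phase window is split into two equal sub-intervals for peak tracking
(two interictal intervals plus two sub-intervals per seizure phase), and a
plunge episode is a strict drop of the density-peak location by more than
0.3 (normalized units) below the running pre-drop level followed by a
rebound to within 0.15 of it. The threshold is a declared operational
stand-in — "drastically decreased" is not quantified in the underlying
method — chosen so that the canonical synthetic seizure registers a
single drop-and-rebound episode (the ictal plunge) in the large majority
of seeds; occasional spurious positive density peaks in sparse intervals
can raise the pre-drop reference enough to suppress the rebound test, so
a small fraction of seeds report none. The threshold is exposed in the
configuration and reported with results.

Snapshots are attributed to phases by the phase of their window midpoint.

## The synthetic generator

No patient SEEG can ship with the package, so every downstream stage is
exercised on synthetic recordings with known ground truth. The generator
emulates the recording properties that matter to the method: multichannel
signals at 512 Hz, sparse high-amplitude transients (Gaussian bumps,
amplitude 100 against noise SD 5, half-width 5 samples) whose local maxima
the real detector must find; directed propagation with sub-`tau` lags; and
phase-switching coupling regimes. Events on one channel closer than
`2 M = 20` samples are thinned (earliest kept), which both mirrors the
detector's refractory geometry and guarantees `tau >= 10` for every pair,
so planted lags of 8 samples are always detectable.

The canonical **patient scenario** (16 channels, 160 s; interictal 60 s,
preictal 30 s, ictal 40 s, postictal 30 s) drives channels 1–8 — the
epileptogenic focus — with a continuous re-entrant cascade during the
seizure (hop lag 8 samples, one full loop every 64 samples, hop
probability 0.95): re-entry is the classic mechanism of sustained focal
hypersynchrony, and a directed cycle is also exactly the structure whose
eigenmodes express segregation in this framework. Pre-ictally the same
circuit fires in intermittent bursts. During the seizure, channels 9–11
carry a slower, strong re-entrant loop (onset every 320 samples, two
traversals) — a remote propagation circuit whose dominant mode anchors the
global network's integrative layer — and background spiking is elevated
fourfold across the montage, as ictal recordings are globally more active.
Elevated counts also matter numerically: windows with very few events turn
single chance coincidences into large `gamma`-amplified weights, and a
realistic ictal background keeps such artifacts small. The **control
scenario** is the same montage with background events only (0.5 events/s
per channel) and no planted coupling: most snapshots are acyclic, the
balance index sits at 0 and fluctuates around it, the control signature.
The pre-ictal and post-ictal phases run at baseline coupling: the
generator makes no attempt to emulate pre-ictal bimodality, which in real
data arises from partial, intermittent recruitment that this index
resolves only at the two ends of its range.

What the generator does *not* emulate: biophysical waveform shape, line
noise and artifacts, volume conduction, electrode geometry, or non-Poisson
background statistics. Passing regime tests therefore shows that the
*method* responds to coupling structure as described, not that the
thresholds are clinically calibrated.

## Problem sizes used in tests

The shipped test-suite and acceptance analyses run at desk scale, chosen
as the package's own defaults: 16-channel, 160 s recordings; 50 seeds for
the control and patient regime checks and 25 for the scoped comparison;
200-fixture oracle-equivalence sweeps with up to 50 events per train and
8-node matrices; 100 two-channel replicates for direction recovery; and
snapshot strides of 1280–2560 samples. These sizes give the qualitative
signatures comfortable margins while keeping a full run in minutes on one
CPU.

## Known limitations

* The method is event-based: channels whose pathology does not express
  itself in large transients are invisible to it.
* The heterogeneity correction makes the strong-local index insensitive to
  circuits confined to very few channels (concentrated eigenvectors are
  discounted to zero); such circuits surface only through the leading
  layer.
* `tau` adapts per pair over the whole segment; strongly nonstationary
  inter-event statistics could make a single `tau` too tight or too loose
  for part of a recording.
* The per-snapshot ratio normalization of `H_sb` amplifies the sign of
  near-zero indices; the acyclicity rule removes the worst case (pure
  numerical noise) but snapshots with tiny genuine structure still map to
  large |`H_sb`| values.

## A minimal session

```{r example}
library(oscbalance)

sim <- simulate_recording(synth_patient_config(seed = 1))
net <- build_network(sim$recording, stride = 2560)
idx <- index_time_course(net)
autoplot(idx)

iv <- phase_intervals(sim$recording$annotations)
peaks <- interval_peaks(idx, iv)
plunges <- peak_track(peaks)
glance(plunges)
autoplot(plunges)

dens <- kde_hsb(idx$H_sb_norm[idx$phase == "ictal"])
autoplot(dens)
```
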