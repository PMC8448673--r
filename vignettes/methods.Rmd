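---
title: "Models and methods behind vasoionics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vasoionics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasoionics)
```

vasoionics packages the quantitative pipeline used to characterize
vascular smooth-muscle dysfunction: cooperative gating of L-type Ca²⁺
(CaV1.2) channels in cell-attached patches, pharmacological decomposition
of whole-cell K⁺ currents, membrane-potential metrics, pressure-myography
myogenic tone, and molecular quantification. Every analyzer is paired with
a synthetic-data generator with known ground truth, so the whole pipeline
is testable without access to raw recordings. This vignette documents the
models, the tunable parameters, the numerical choices, and what the tests
do and do not establish.

## The partially coupled gating model

A patch containing `N` identical two-state channels is modeled as a
discrete-time Markov chain on the number of simultaneously open channels
`k ∈ {0, …, N}` with three parameters:

* `rho` (ρ) — per-step open→open probability of one channel,
* `sigma_c` (ς) — per-step closed→closed probability,
* `kappa` (κ) — coupling coefficient in [0, 1].

The transition matrix is the mixture `T = (1 − κ)·T_unc + κ·T_cpl`.
`T_unc` is the independent-channel kernel: each of the `k` open channels
survives with probability ρ and each of the `N − k` closed channels stays
closed with probability ς, so the next level is the convolution of two
binomials. `T_cpl` moves all channels in unison, following the
single-channel chain applied to the *majority state* of the patch, with
ties broken toward open; its rows therefore place mass only on `{0, N}`.

The majority-state construction is our design choice: the original
coupled-matrix construction lives in unpublished analysis code, and any
definition must (a) collapse to the independent kernel at κ = 0, (b) give
pure unison gating at κ = 1, and (c) use exactly the three parameters
above. The majority rule is the simplest construction satisfying all
three, and both limits are enforced by tests (exhaustive enumeration of
the 2^N binary configurations at κ = 0; boundary-only paths at κ = 1).
Whether κ should instead act only on the extreme rows is not decidable
from the published description; the majority rule applies it to every row,
which keeps the interior dynamics responsive to κ.

The single-channel stationary open probability is
`p∞ = (1 − ς)/((1 − ς) + (1 − ρ))`, the quantity used to calibrate
simulations against published nPo values.

### Fitting

`fit_params()` maximizes the exact Markov log-likelihood of an observed
(idealized) level sequence — `Σ_t log T(l_t → l_{t+1})`, accumulated from
the transition-count matrix — by gradient ascent with central-difference
numerical gradients (h = 1e−5) on logit-transformed parameters, so the
optimizer works on the whole real line and estimates stay interior.
Backtracking line search guarantees monotone ascent; convergence is
declared when the log-likelihood improves by < 1e−8 or after 5000
iterations. Five fixed interior starting points guard against local
optima; a deterministic start grid (rather than random restarts) makes the
fit a pure function of the data. Forbidden transitions (model probability
zero) contribute a floored log-probability of −700 each and are counted in
a diagnostic. The upstream pipeline idealizes before fitting, so the fit
is a direct observed-chain MLE rather than a hidden-Markov fit on raw
current; this is deterministic and oracle-checkable, at the cost of
ignoring residual classification noise (negligible at the ≥ 99% per-sample
accuracy the idealizer achieves at 0.15 pA noise).

All-constant sequences carry no information about some parameters; they
return a flagged boundary fit (an all-closed record pins ς at its upper
boundary) rather than pretending convergence.

## Idealization and activity statistics

Raw sweeps (2-s test pulse to 0 mV from −80 mV, 10 kHz sampling, 2 kHz
analog low-pass, ~50 sweeps per patch) are quantized by the half-amplitude
rule: a sample belongs to level `k` when its distance from baseline
reaches `(k − 0.5)` unitary currents, i.e. the event threshold sits at
0.5 pA for the 1 pA unitary event.

**Baseline.** The closed-level current is estimated per sweep as the
*lowest local mode* of a kernel density estimate of the sweep's samples
(modes below 1% of the tallest peak are ignored; modes closer than half a
unitary current are merged). A plain histogram mode would fail exactly
where it matters most: in high-activity patches (e.g. N = 3 channels at
p∞ ≈ 0.77) the closed level occupies ~1% of samples and the global mode is
an open level. Taking the lowest surviving mode keeps the estimator
anchored to the closed level whenever it is visited at all; a patch whose
closed level is never visited is inherently ambiguous and no per-sweep
rule can recover it. A genuine bimodal tie (two modes of near-equal
height) warns and picks the lower mode.

**Flicker suppression.** Dwells shorter than 2 samples (0.2 ms at 10 kHz)
are merged into the preceding level, reflecting that the 2 kHz analog
filter makes true sub-0.2-ms resolvable events implausible and that
single-sample excursions are overwhelmingly noise. On noiseless synthetic
paths this merging is disabled in round-trip tests, because there every
one-sample dwell is a real gating event; with merging on, the residual
bias in nPo is about +0.02 at the acceptance operating points — an order
of magnitude below the ±0.15 acceptance band.

**Statistics.** Over an analysis window that excludes the first and last
5 ms of the step (capacitive transients; the published protocol is silent
here), `nPo` is the time-averaged level, `n` is the maximum simultaneous
level seen in the patch, and `Po = nPo/n` — which cannot exceed 1 by
construction (the published SHS figure of 1.2 is treated as an
nPo-related misprint and is not reproduced). A coupled opening is an
upward jump of ≥ 2 levels within one sampling interval; coupled frequency
is reported as events per second of analyzed depolarization, with the
fraction of openings that are coupled exposed as a secondary field.

## Whole-cell K⁺ currents and membrane potential

`extract_iv()` summarizes each voltage-step trace after blanking the first
5 ms (configurable), as either the signed peak of the largest absolute
current or the mean of the final 50 ms, and normalizes by membrane
capacitance to pA/pF. Pulse duration defaults to 600 ms; the published
methods and results disagree (0.6 s vs 200 ms), so it is a parameter. No
leak subtraction is applied (none is described); saturated traces are
excluded with a warning when a clip limit is supplied.

`subtract_ibtx()` computes the iberiotoxin-sensitive BK current as the
pointwise difference of control and IBTx densities on an identical voltage
grid; `I_BK + I_Kv = I_K` holds to machine precision by construction.

`vm_metrics()` estimates the resting potential as the mean of the
most-stable 10-s window (minimum rolling variance) of pre-drug data, and
the drug response as `mean(post) − mean(pre)` with a 1-s settle time after
onset. Drift above 5 mV across pre-drug rolling means raises an
instability flag. Note a statistical consequence of the synthetic noise
model below: with Ornstein–Uhlenbeck noise of sd 1 mV and τ = 0.5 s, the
10-s window mean has an sd of `σ·sqrt(2τ/T)` ≈ 0.32 mV, so single-trace
resting estimates scatter by a few tenths of a millivolt — that scatter is
a property of the stated world, not estimator error.

## Myogenic tone

Tone at a pressure is `100 × (D_pass − D_act)/D_pass`, the active
constriction relative to the maximally dilated (Ca²⁺-free + nifedipine)
diameter at the same pressure. Negative tone is clipped to zero with a
flag. Diameter at a step is the mean of its final 30 s (the published
protocol does not state an averaging window). Viability requires ≥ 30%
constriction to 60 mM K⁺ — "robust" is not quantified in the source, and
30% is conventional myography practice; the threshold is configurable and
its boundary behavior is tested. Stability requires < 5 percentage points
of absolute tone drift across the 1-h hold at 60 mmHg (the discard rule is
stated without a number; 5 points quantifies it).

## Molecular quantification

PLA puncta density is count/area (puncta/µm²). Relative expression uses
2^−ΔΔCt with GAPDH (or any named reference) as internal control and
per-group summaries by geometric mean, so the calibrator group has
geometric-mean fold 1 identically. Densitometry is band/loading with
optional normalization to the control-lane mean; the loading signal may be
a loading-control band or total protein. Image processing (spot calling,
gel densitometry) is out of scope — the module consumes counts and
intensities.

## Synthetic data: what it emulates and what it does not

Generator defaults state the experimental world: 50 sweeps × 2 s at
10 kHz with 1 pA unitary current and 0.15 pA recording noise
(single-channel); −70…+80 mV in 10 mV steps at 20 kHz with Boltzmann
conductances — Kv V½ = 0 mV, k = 15 mV; BK V½ = +20 mV, k = 18 mV; only
the +80 mV densities are contractually exact — and E_K = −84 mV from the
6/140 mM K⁺ solutions at room temperature (whole-cell); OU membrane noise
with τ = 0.5 s (gap-free Vm); a saturating passive diameter curve
(60–130 µm, half-saturation 30 mmHg, matching 90–120 µm arteries) with a
bell-shaped tone profile peaking near 60 mmHg (myography); gamma cell
areas (400 ± 100 µm²) with Poisson counts (PLA); and Ct tables built from
a reference gene near 18 cycles with programmed per-group folds (qPCR).

The generators deliberately omit: modal gating and subconductance states,
series-resistance and perforation dynamics, actual 2 kHz filter kinetics
(the optional smoother is a moving average), servo-controller transients,
and spatial structure in PLA images. A green round-trip test therefore
establishes that the analyzers invert the stated generative model — not
that they are robust to every artifact of real recordings.

## Statistics layer

Two-group comparisons apply a Shapiro–Wilk gate per group at α = 0.05;
both passing routes to Student's t (pooled variance), either failing
routes to Mann–Whitney. Omnibus designs are one-way ANOVA (Tukey or
Bonferroni post-hoc), two-way ANOVA with interaction (empty cells
rejected), and Kruskal–Wallis with a hand-implemented Dunn post-hoc
(rank-based z statistics with tie correction, Bonferroni adjustment). SEM
uses the n − 1 standard deviation. Type-I error of the gated two-group
test and of one-way ANOVA is verified at 2000 null simulations to lie in
[0.04, 0.06].

One test-design note: occupancy goodness-of-fit against the stationary
distribution uses chains thinned by 25 steps before the χ² test, because
raw chain samples are autocorrelated on the dwell-time scale and would
inflate the statistic under a multinomial null.

## Known limitations

* Channel count `n` is the maximum observed simultaneous level, which
  underestimates the true channel count in low-Po patches; this is the
  field's convention and the published definition.
* The fit assumes the idealization is error-free; at high noise
  (> ~0.3 pA per 1 pA unitary) misclassification would bias ρ and ς
  toward faster apparent gating.
* The coupled kernel is one of several three-parameter constructions
  consistent with the published description (see above).
* ABF and HDF5 ingestion are not implemented; inputs are tidy CSV/JSON.
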