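---
title: "Adaptive single-molecule tracking in phase-separated systems: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive single-molecule tracking in phase-separated systems: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptrack)
```

# The problem

Biomolecular condensates concentrate proteins tens to thousands of fold
relative to the surrounding dilute phase. Single-molecule localization
microscopy (dSTORM and relatives) observes both phases at once: each camera
frame yields point detections ("localizations") of sparsely labelled,
photo-switching fluorophores, and consecutive detections of the same
molecule form a trajectory. Two features make this data hard to analyze
with a conventional tracker:

* the localization density differs by one to two orders of magnitude
  between the condensed and dilute phases, and
* molecules inside the condensed phase do not diffuse homogeneously — they
  switch between a nearly motion-frozen *confined* state (bound to the
  percolated molecular network) and a *mobile* state, while dilute-phase
  molecules diffuse freely and much faster.

`adaptrack` implements the full analysis chain for such data — phase
segmentation from localization densities, error-optimal adaptive linking,
a two-state hidden Markov model (HMM) of condensed-phase motion, a
model-free correlation-based step classification, and the kinetic relation
that ties the fitted diffusion parameters to the equilibrium enrichment —
together with the Monte Carlo simulators (two-phase equilibrium diffusion,
ground-truth localization scenes, in-silico FRAP) used to validate each
stage.

# The error model behind the adaptive search range

Frame-to-frame linking accepts a candidate pair only within a search range
(gate) $R$. For a 2D Brownian population with diffusion coefficient $D$
imaged at frame interval $t$, the step magnitude is Rayleigh-distributed
and the fraction of *true* links lost to the gate is
$E_{TN} = e^{-R^2/4Dt}$. Spurious links between unrelated molecules grow
linearly with $R$ at a rate proportional to the molecule density
$\sigma$. Writing $X = R/\sqrt{4Dt}$ (gate in units of the per-frame RMS
displacement), the total error is

$$E(X) = e^{-X^2} + 2\,c\,X, \qquad c \propto \sigma D t,$$

whose minimum satisfies $X e^{-X^2} = c$ on the branch $X > 1/\sqrt{2}$.
Over the experimentally relevant range $c \approx 3\times10^{-4}$ to
$4\times10^{-3}$ the optimum sits between $X^\ast \approx 2.5$ and $3.1$
(`optimal_X()`), which is why a fixed default $X = 2.5$ is used
operationally: the error curve is flat near its minimum, and
`optimal_x_benchmark()` confirms on ground-truth scenes that the empirical
error-minimizing gate is $X \approx 2.5$ across densities and
diffusivities.

The exact prefactor of the spurious-link term depends on the collision
cross-section convention; the package exposes it as the single composite
coefficient `c` (`fp_coefficient()`, default $\pi \sigma D t$) and never
relies on its absolute value.

## Two-pass adaptation

`adaptive_track()` links all localizations with a global default gate
(500 nm), splits the pass-1 displacements by the phase of each step's
start, estimates per-phase diffusion scales, sets per-phase gates
$R_\mathrm{phase} = X\sqrt{4 \hat D_\mathrm{phase} t}$, and relinks.
Cross-phase candidate pairs use the larger of the two gates so genuine
exchange events are not truncated.

Two details matter in a two-state condensed phase:

* **Mixture-aware gating.** The pooled moment estimator
  $\hat D = \sum d^2 / 4nt$ is dominated by the confined majority; gating
  on it would cut most mobile-state steps. The per-phase gating scale is
  therefore taken from the fast component of a mixture fit to the squared
  displacements — two exponential components (squared 2D Brownian steps
  are exponential) plus a fixed-shape component for spurious links, whose
  squared length is uniform up to the squared gate. On a single-state
  phase the mixture collapses and the gate reduces to the moment
  estimator exactly.
* **Spurious-link flux.** Even at the optimal gate, a molecule that blinks
  off can be linked to an unrelated molecule appearing nearby one frame
  later. In a dense condensed phase these rare links carry large
  displacements and add a spurious component to the apparent mobile flux
  $P_m D_m$. `spurious_link_flux()` quantifies it without ground truth by
  relinking frame $f$ against frame $f + \delta$ for offsets $\delta$ far
  beyond the track survival time: every match in this shifted control is
  between unrelated co-occupants, and scaling the control match rate by
  the observed per-localization track-end and track-start frequencies
  predicts the spurious count and flux. On simulated scenes the estimate
  agrees with the ground-truth spurious flux to better than 10%.

# Condensed-phase motion models

## Two-state HMM

`hmm_fit()` is Baum–Welch EM over all condensed-phase tracks jointly,
with 2D Brownian displacement-magnitude emissions
$p(d \mid k) = \frac{d}{2 D_k t} e^{-d^2/4 D_k t}$ for states
$k \in \{c, m\}$ and per-frame switching probabilities $P_{cm}, P_{mc}$.
Each track's forward pass starts from a shared initial-state distribution
that is itself estimated (standard Baum–Welch; tying it to the stationary
law of the transition matrix would void the EM monotonicity guarantee,
which the test suite asserts). Emissions carry no separate static-error
term: a stationary emitter localized with per-axis error $s$ produces the
same displacement law as diffusion with $D = s^2/t$, so detection error is
absorbed into $D_c$ (`loc_error_scale()` converts back,
$s = \sqrt{D_c t}$). The derived quantities are the confinement ratio
$P_c = P_{mc}/(P_{mc}+P_{cm})$, the mobile ratio $P_m = 1 - P_c$, and the
state lifetimes $t/P_{cm}$ and $t/P_{mc}$.

Convergence is declared at a relative log-likelihood change below $10^{-8}$
(cap 10,000 iterations); a BIC comparison against a single Brownian
population flags data with no support for a second state, and fits with
less than 3-fold separation between $D_c$ and $D_m$ are flagged as
unreliable for ratio estimates.

## Model-free classification

The correlation-based route presumes no diffusion model: consecutive step
magnitudes $(d_i, d_{i+1})$ within condensed-phase tracks of at least 10
steps are split by a demarcation $d_b$, and the two conditional
distributions $P(d_{i+1} \mid d_i \lessgtr d_b)$ are compared by the
overlap coefficient $\mathrm{OVL} = \int \min(P, Q)$. For simple Brownian
motion consecutive steps are independent and the conditionals coincide;
two-state switching separates them. Because the empirical OVL of finite
histograms is biased below one by an amount that grows as a condition's
count shrinks, `scan_demarcation()` calibrates each demarcation against a
permutation null (conditioning values shuffled across pairs) and selects
the demarcation maximizing the null-minus-observed separation;
demarcations leaving a condition under 100 pairs are excluded, and a
separation nowhere exceeding four null standard deviations is reported as
"no two-state structure". `classify_steps()` then labels steps L/H by
threshold, giving ratios from label counts and switching frequencies from
transition counts, and `fit_components()` fits the L component with the
detection-error scale $s$ and the H component with a Brownian $D$, by
maximum likelihood with the supports truncated at $d_b$ (a one-sided
heavy-tailed alternative is available as a diagnostic only).

## MSD analytics

`msd()` uses overlapping time-average windows (non-overlapping available);
`fit_msd()` fits $\mathrm{MSD} = 4Dt$ by least squares through the origin
or the subdiffusive $\mathrm{MSD} = 4 D_\alpha t^\alpha$ by log–log
regression, which inverts exact curves to machine precision.

# The kinetic–equilibrium bridge

With no appreciable energy barrier at the phase boundary, the exchange
flux out of the condensed phase is carried by its mobile fraction,
$\sigma_c P_m D_m$, and the influx by the dilute phase, $\sigma_d D_d$.
At steady state,

$$\mathrm{EF} = \frac{\sigma_c}{\sigma_d} \approx \frac{D_d}{P_m D_m},$$

which generalizes to multiple states and phases as equality of
$\sum_i \sigma_i D_i$ across phases (`flux_balance_check()`). This is the
package's headline cross-validation: the enrichment fold measured from
localization densities must agree with the one predicted from the fitted
kinetics (`run_pipeline()` reports both; in the kinetic route the
spurious-link flux is subtracted from the apparent mobile flux before the
relation is applied).

# Monte Carlo engines

## Equilibrium two-phase simulation

`simulate_equilibrium()` advances molecules in a periodic box (default
15 × 30 µm) with stationary disk-shaped condensed regions. Per integration
step `dt` (default $10^{-4}$ s), condensed-phase molecules switch states
with $P_{mc} = dt/t_m$ and $P_{cm} = P_{mc}\,\eta/(1-\eta)$ (detailed
balance at mobile ratio $\eta$); confined molecules are stationary
($D_c = 0$ by default); the diffusion coefficient for a whole step is that
of the region at the step's *start*, even when the step crosses a
boundary — no interface penalty. The enrichment trace
$\mathrm{EF}(t) = (N_c/A_c)/(N_d/A_d)$ is summarized by
`steady_state_ef()` over the final 10 s. Since the full-scale protocol
(50,000 molecules, 100 s) is expensive, scaled runs (5,000 molecules,
`dt` $5\times10^{-4}$ s, 30 s) are used throughout the tests; at that
scale the default initial condition places molecules at the theoretical
enrichment with condensed states at the stationary mobile ratio — the
pre-enriched protocol — so no relaxation transient is paid (a homogeneous
start is available via `init = "uniform"`, and the steady state does not
depend on the choice). The condensed geometry is a synthetic set of eight
well-separated droplets (radii 0.4–0.8 µm, ~2% of the box); experimental
boundaries would be irregular, which is known to depress the steady state
a few percent below theory.

The core stepper is compiled code; normals come from a Marsaglia polar
sampler fed by R's uniform stream, so runs are exactly reproducible from
`set.seed()`.

## Ground-truth localization scenes

`simulate_homogeneous()` generates tracker-evaluation scenes: Poisson
track lifetimes (mean 3.5 frames, minimum 1 — zero-length lifetimes are
resampled up rather than discarded), uniform start frames and positions,
Brownian per-frame steps. Because these scenes have no internal
boundaries, accumulating 0.1 ms sub-steps is distributionally identical to
one Gaussian draw per frame; the default therefore draws once per frame
(`n_substeps` draws the sub-steps explicitly).

`simulate_condensate_scene()` builds the full two-phase scene: condensed
regions hold a two-state population whose per-frame switching follows
$(P_{cm}, P_{mc})$, the dilute background diffuses at $D_d$, and motion is
integrated in 0.1 ms sub-steps with the start-region rule so that boundary
fluxes balance. Confined molecules are anchored, their localizations
scattered with the point-spread scale $\sqrt{D_c t}$ — equivalent in
displacement distribution to diffusing at $D_c$, but anchored molecules
cannot drift across the boundary, which is what the flux-balance relation
assumes. Default parameters are the fitted HMM set
($D_d = 0.47$, $D_m = 0.17$, $D_c = 0.0127$ µm²/s, $P_{cm} = 0.038$,
$P_{mc} = 0.828$ per 30 ms frame, EF $= 62.8$); the dilute per-frame
localization density (0.005 µm⁻²) and 12-droplet, 24 × 24 µm, 4000-frame
field give ~25,000 localizations — the same order as an experimental
acquisition. Localizations falling outside the field of view are not
detected, as for a real camera. What these scenes do *not* emulate:
fluorophore re-blinking (track fragments of one molecule are independent
tracks), localization-precision heterogeneity, drift, and non-circular
boundary shapes — so passing tests bound algorithmic error, not every
experimental systematic.

Track lifetimes average 3.5 frames, so tracks with the ≥10 steps required
by the classification module are rare in scene data; classification is
exercised on dedicated longer-track simulations instead, and
`run_pipeline()` degrades gracefully (flagged, not fatal) when too few
eligible tracks exist.

## FRAP

`simulate_frap()` reuses the equilibrium stepper in the 20 × 8 µm
seven-droplet geometry (radii 0.5/1/1/2/1/1/0.5 µm at
x = 1/3/5/10/15/17/19 µm; the droplet y-coordinates are not specified by
the printed geometry and are set to mid-height). Bleach ROIs default to
0.5 µm radius at the centres of the 2, 1 and 0.5 µm radius droplets.
Molecules inside an ROI at time zero are flagged bleached with respect to
that ROI; since bleaching does not alter dynamics, one trajectory ensemble
evaluates all ROIs. Recovery is the unbleached count in the ROI normalized
to the pre-bleach occupancy. Initialization draws directly from the
stationary law (positions at the configured EF, condensed states at the
mobile ratio), which for the permanently-confined benchmark
($\eta = 0.1$, $D_d/D_m = 10$, EF 100) is exactly stationary.

# Phase segmentation

`local_density()` computes per-localization densities (self-inclusive
neighbour counts within 100 nm over the disk area) and a 50 nm-cell count
grid smoothed with a disk kernel of the same radius; all frames are pooled,
treating the stack as a static molecular distribution. `segment_phases()`
thresholds in three stages: an Otsu split of the per-localization
log-density histogram (the bimodality is the signal) gives a provisional
phase separation; the final threshold is the half-height level
$(\sigma_c + \sigma_d)/2$ of the provisional phase densities, which places
the contour of the kernel-smoothed field on the true density step; and a
significance floor requires the threshold to exceed the largest kernel
count a uniform Poisson field of the same mean would produce, so shot
noise on a single-phase field yields no regions. Morphological closing and
a minimum-area filter (0.05 µm² — just above the 100 nm kernel footprint,
so an isolated blinking localization cannot survive as a region) clean the
mask; per-phase densities come from the raw counts, with the kernel
padding ring excluded from the areas. In `run_pipeline()` the enrichment
fold is cross-validated: the map is segmented on even frames and scored on
odd frames, because a mask selected on the same localizations it is scored
on hugs their shot noise and inflates the enrichment.

# Numerical choices and degenerate inputs

* Boundary points count as condensed (deterministic tie-break of measure
  zero).
* Linking ties resolve lexicographically (distance, then indices), making
  track assignment invariant to input row order; the optimal-bipartite
  strategy is a maximum-weight matching with weights `C - d` and `C`
  larger than any total distance, so link count dominates and summed
  distance breaks ties.
* Frame gaps are not closed by default (`max_gap = 0`); a phase with fewer
  than 50 pass-1 displacements falls back to the default gate (logged in
  the provenance).
* `optimal_X()` refuses composite coefficients outside
  $(0, e^{-1/2}/\sqrt 2)$; roots are polished to residual $<10^{-10}$.
* EM aborts if the log-likelihood decreases beyond numerical tolerance;
  displacements of exactly zero are floored at $10^{-9}$ µm.
* Scaled-down simulation sizes used by the tests and the acceptance
  script: 5,000 molecules / `dt` $5\times10^{-4}$ s / 30 s (equilibrium,
  5 seeds), 10,000 molecules (FRAP), ~10,000 tracks (gate benchmark),
  2,000 tracks (HMM recovery), five default scenes (end-to-end
  cross-validation). These sizes were chosen so that Monte Carlo error is
  comfortably inside each check's tolerance.

# Known limitations

* The spurious-link control assumes track births are spatially independent
  of deaths; fluorophore re-blinking at a fixed molecule violates this
  mildly and would make the correction conservative.
* The enrichment cross-validation inherits the variance of the mobile-flux
  estimate (a few hundred mobile steps per default scene); single-scene
  ratios scatter by ~15%, which is why the acceptance check averages
  replicate scenes.
* The equilibrium engine supports disk geometries only; polygon or raster
  condensed regions are supported throughout the analysis chain but not as
  simulation boundaries.
* All analysis is 2D; three-dimensional data must be projected first.
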