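# adaptrack

Adaptive single-molecule tracking and motion analysis for biomolecular
condensates.

Phase-separated condensates concentrate molecules tens to hundreds of fold
over the surrounding dilute phase, and molecules inside them do not diffuse
homogeneously: they switch between a nearly motion-frozen *confined* state
(bound to the condensed-phase molecular network) and a *mobile* state.
Localization microscopy sees both phases at once, but a tracker with one
global search range cannot serve localization densities and diffusivities
that differ by orders of magnitude between phases. `adaptrack` is for
researchers analyzing single-molecule localization data of condensates (on
supported bilayers or projected from solution) and for anyone simulating
such systems.

The package implements:

* **Phase segmentation** from pooled localization densities: per-point
  densities, Otsu split of the log-density histogram with half-height
  refinement, morphological cleanup, and the enrichment fold
  `EF = sigma_c / sigma_d` with bootstrap uncertainty.
* **Error-optimal adaptive linking.** With `X = R / sqrt(4 D t)` the total
  link error `E = exp(-X^2) + 2 c X` (missed links plus spurious links,
  `c ∝ sigma D t`) is minimized where `X exp(-X^2) = c`, giving
  `X* ≈ 2.5–3.1` over realistic conditions; the tracker links once with a
  500 nm default gate, estimates per-phase diffusion scales, and relinks
  with per-phase gates `R = 2.5 sqrt(4 D t)`.
* **Two-state hidden Markov model** of condensed-phase displacement
  magnitudes (Baum–Welch; emissions `p(d|k) = d/(2 D_k t) e^{-d^2/4 D_k t}`),
  yielding `D_c`, `D_m`, per-frame switching probabilities and the
  confinement ratio `P_c = P_mc / (P_mc + P_cm)`.
* **Model-free step classification** by the correlation of consecutive step
  magnitudes: conditional next-step distributions split at a demarcation
  `d_b`, compared by the overlap coefficient `OVL = ∫ min(P, Q)` with
  permutation-null calibration.
* **The kinetic–equilibrium bridge** `EF ≈ D_d / (P_m D_m)` (flux balance
  across the phase boundary) and its multi-state generalization
  `Σ sigma_i D_i` equal across phases.
* **Monte Carlo simulators**: ground-truth localization scenes for tracker
  benchmarking, the equilibrium two-phase/two-state diffusion engine
  (compiled; periodic box, stationary droplet boundaries, start-region
  step rule), and in-silico FRAP.

## Worked example

Simulate a condensate scene with the default two-state kinetics
(`D_d = 0.47`, `D_m = 0.17`, `D_c = 0.0127` um^2/s, per-frame switching
`P_cm = 0.038`, `P_mc = 0.828`, enrichment 62.8) and run the full
pipeline:

```r
library(adaptrack)
set.seed(42)
scene  <- simulate_condensate_scene()
report <- run_pipeline(scene$table)
report
#> <adaptrack_report>
#>   EF (localization densities): 59.2 +/- 1.1
#>   EF (kinetic, D_d/(P_m D_m)): 59.5
#>   HMM: D_c = 0.01231, D_m = 0.2944, P_m = 4.54%
#>   dilute D (MSD): 0.452 um^2/s
#>   crossings: 151 in / 150 out
#>   warnings: classification: d_b > 0 is not TRUE
```

The two headline numbers are the enrichment fold measured from
localization densities (59.2, against a configured 62.8 — the realized
enrichment of a finite scene) and the one predicted from the fitted
kinetics via `D_d / (P_m D_m)` after subtracting the measured
spurious-link flux (59.5). Their agreement is the method's
cross-validation: a kinetic model of single-molecule motion reproducing a
thermodynamic partition coefficient. Boundary crossings balance (151 in vs
150 out), as they must at equilibrium. The classification warning is
expected here: with 3.5-frame mean track lifetimes almost no track reaches
the 10 steps that the model-free classification requires (use longer-lived
tracks for that module, e.g. `simulate_two_state()`).

The equilibrium engine reproduces its benchmark table:

```r
suite <- run_simulation_suite(n_molecules = 5000, dt = 5e-4, T_total = 30,
                              n_seeds = 2, seed = 1)
suite[, c("D_m", "D_d", "mobile_ratio", "ef_theory", "ef_sim")]
#>    D_m D_d mobile_ratio ef_theory    ef_sim
#> 1 0.20 0.6         0.05        60  58.70218
#> 2 0.10 0.6         0.10        60  59.14738
#> 3 0.01 0.6         1.00        60  57.45395
#> 4 0.10 0.6         0.10        60  58.63909
#> 5 0.10 0.6         0.05       120 117.08770
#> 6 0.20 0.6         0.10        30  28.63851
```

A thin command-line wrapper over these functions is installed at
`inst/cli/adaptrack.R` (subcommands `simulate`, `segment`, `track`, `fit`,
`classify`, `frap`, `pipeline`, `suite`).

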