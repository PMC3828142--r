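---
title: "Modelling cell-cycle synchronisation effects in spheroid radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell-cycle synchronisation effects in spheroid radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`spheroidrt` simulates a three-dimensional tumour micro-region — a spheroid
grown off-lattice from a handful of seeder cells — and its response to
fractionated irradiation. The reason cycle timing matters for radiotherapy is
that clonogenic survival after a dose `D` follows the linear-quadratic (LQ)
law `S = exp(-(alpha * D + beta * D^2))` with strongly phase-dependent
coefficients: cells in G2 and M are several-fold more sensitive than cells in
S. An unperturbed tumour averages over the cycle, but any dose kills
selectively, *resynchronises* the survivors, and so makes the population's
aggregate sensitivity oscillate for days afterwards. The package exists to
quantify those oscillations and to compare dose schedules that exploit or
squander them.

Each cell is an agent with a position, a radius in `[7.94, 10]` um (the ratio
is `2^(1/3)`, so volume doubles over one cycle), a functional phase
(G1, S, G2, M, quiescent G0, necrotic, apoptotic), and its own sampled phase
durations. Durations are drawn per cell and per phase from a normal
distribution with means 8, 6, 4.5 and 1 h (expected cycle 19.5 h), relative
standard deviation 0.3, truncated at 3 standard deviations by resampling. The
truncation bound is a modelling choice (`cycle_params(cutoff = )`): it must
exist for positivity, and 3 s.d. keeps 99.7% of the mass while excluding
near-zero phase lengths.

Two environmental couplings close the loop:

* **Pressure / quiescence.** Cells interact through an adhesive–repulsive
  pair force (extended Hertz repulsion plus a finite adhesive well of range
  2 um) and move by overdamped relaxation. A cell's *integral pressure* is
  the calibrated sum of compressive contact forces over its surface area; a
  cell arriving at the G1/S checkpoint under more than 200 Pa enters G0, and
  re-enters through the restriction point (checked every step) once its
  pressure falls back below threshold. Quiescent cells freeze their
  phase-angle, grow no further, and experience radiation at a reduced
  effective dose.
* **Glucose / necrosis.** Glucose and oxygen are solved on a cubic grid
  (1.4 mm edge; 20 um voxels at full resolution) as quasi-steady
  reaction–diffusion fields with cells as phase-specific sinks. Voxels
  outside the spheroid envelope are held at the medium concentration
  (5 mM glucose, 0.13 mM oxygen, tissue-like values); interstitial gaps and
  the hollow core *inside* the envelope are diffusion-only — treating them
  as perfused reservoirs would visibly flatten the internal gradient. A cell
  whose local glucose is fully depleted commits
  to necrosis (mean duration 24 h) and dissolves, which is what hollows out
  the core of large spheroids. Oxygen is tracked for its uptake observables
  but does not gate death: only the glucose threshold does.

### Radiation response

At each fraction every viable cell survives independently with its
phase-specific LQ probability; quiescent cells use the G1 coefficients at
`dose / QRF` with `QRF = 1.5`. Non-survivors split into an acute path
(probability 0.66; apoptosis with mean duration 12 h) and a slow path: they
keep cycling but arrest at the G2/M checkpoint, where they die with constant
hazard `r_slow` (default 0.05/h, a calibration of the G2 pile-up timescale —
the printed parameter set does not pin this value). Damage repair is not
modelled explicitly; it is considered phenomenologically contained in the
measured LQ coefficients, and fractions are treated as independent
instantaneous events. Cells already committed are not re-rolled by later
fractions (damaged cells re-roll only the acute conversion). A configurable
checkpoint-slip probability (default 0: no value is established for it) lets
damaged cells attempt mitosis once and die there.

### Observables

* `expected_survival(D)`: duration-weighted mean of the phase-specific
  survivals — the baseline for an exponentially growing, quiescence-free
  population.
* `observed_survival(pop, D)`: a *virtual* dose — the population is never
  modified. The default estimator is the expectation (mean LQ survival over
  viable cells); a sampling mode draws one seeded realisation instead. The
  expectation was chosen as default because the two agree in mean while the
  expectation removes estimator noise from trigger decisions.
* `enhancement = expected / observed`: above 1 the population is sensitised
  (cells bunched in radiosensitive phases), below 1 resistant (e.g. a large
  quiescent pool).
* `orderedness`: 1 − H/H_max where H is the Shannon entropy of the
  phase-angle histogram. Default 20 bins; entropy is well behaved in the bin
  count and a functional 4-bin variant is provided. Quiescent cells enter at
  their frozen angle; dead cells are excluded.
* `tumour_burden`: trapezoidal integral of the viable-cell count, in
  cell-days — the treatment-outcome metric.

### Schedules

`build_preset()` encodes the standard fractionation catalogue (conventional
2 Gy weekdays to 60 Gy, hypo- and hyperfractionated variants, accelerated
7-day versions, CHART at 1.5 Gy thrice daily to 54 Gy). The split-course and
concomitant-boost entries are reconstructions — the catalogue lists them
without complete timing parameters — implemented as conventional with a
14-day mid-course gap, and conventional with a doubled final week rescaled to
60 Gy. `build_constant_rate()` produces rate-matched variants (2 Gy/24 h,
2.5 Gy/30 h, ...), `build_triggered_block()` trigger/effector blocks padded
to a fixed dose rate, and `trigger_policy()` + `simulate_treatment(policy=)`
the online enhancement-peak-triggered protocol: a peak is declared when no
increase above 1% occurs across a 12 h trailing window (or, in regression
mode, when the fitted slope turns non-positive), and the accumulated dose
budget `rate * elapsed - delivered` is released if it exceeds `d_min`. The
window length is a design choice: the printed description leaves it open, and
12 h trades detection latency against false triggers on the 2 h sampling
cadence. A non-causal "oracle" mode runs a shadow copy of the simulation
forward to place each dose at the true next enhancement maximum; it exists
only as an upper benchmark for the causal policy, which inherently lags by
the detection window.

## Numerical choices

* **Time stepping.** Operator splitting per step `dt`: death clocks →
  nutrients → mechanics relaxation → cycle events (necrosis, arrest hazard,
  checkpoints, growth) → divisions; scheduled doses land on the first step
  boundary at or past their nominal time. `dt = 0.05 h` (full profile) or
  `0.1 h` (desk profile), both well below the shortest mean phase (1 h).
* **Nutrients.** The diffusion timescale across the grid (~minutes) is far
  below cycle timescales, so the field is relaxed to quasi-steady state
  (warm-started Gauss–Seidel, tolerance 1e-4 mM) and re-solved every few
  steps (`nutrient_every`, default 3–5 ≈ 0.3–0.5 h); between solves cells
  sample the stored field. An explicit Euler mode exists for mass-balance
  audits. Concentrations are clamped at zero and clamped voxels flagged
  starved.
* **Mechanics.** Neighbour search by linked-cell binning with a 3 um skin;
  relaxation in 2 substeps with displacement capped at `0.3 * r_min` per
  substep (repeated capping raises an instability warning). Coincident
  centres (newborn daughters) are separated by a deterministic perturbation.
* **Randomness.** One master seed drives all draws; mechanics consumes no
  randomness, so cycle/radiation draws are unaffected by mechanical
  parameters. Runs are bit-reproducible from `(config, seed)`; the oracle
  scheduler snapshots and restores the RNG state around its shadow runs.

## Calibration

Three constants are calibrations of this implementation, not measured
parameters, and are flagged as such in their documentation:

* `pressure_calib = 25` scales the contact-force pressure before comparison
  with the 200 Pa quiescence threshold. The pair-force parameters (modulus,
  adhesion, drag) are declared defaults in the physiological range — the
  underlying contact model leaves the absolute pressure scale open — and the
  factor was fixed once so that quiescence onsets in the spheroid core during
  growth and the day-14 spheroid carries a majority quiescent population
  inside a proliferating rim.
* `uptake_glucose = 2.8e-16 mol/(cell s)` (with phase multipliers around 1
  and a 0.5 quiescent multiplier) sets the glucose depletion radius
  `sqrt(6 D c_b / S)` to roughly 280 um, so that spheroids develop a necrotic
  core as they approach the ~700 um day-14 scale.
* `r_slow = 0.05/h` places the post-dose G2 pile-up maximum one to two days
  after irradiation.

Whether quiescent cells consume nutrients at a reduced rate is not pinned by
the model description; the package uses a 0.5 multiplier, which matters only
near the necrosis boundary.

## What the simulations do and do not show

The growth protocol (10 seeder cells, 14 days) reproduces the layered
histology — proliferating rim, quiescent interior, starved core — and the
radioresistant-then-hypersensitised enhancement transient after a single
dose, and those are the behaviours the test-suite asserts. Problem sizes in
the tests are deliberately reduced: the shared fixtures use a 14-day run on
the full 1.4 mm / 20 um grid at `dt = 0.1 h` (~3 x 10^4 cells) for the
enhancement and histology checks, and an 8-day coarse-grid spheroid
(~3.5 x 10^3 cells, 40 um voxels) for the sterilisation sweep and
schedule-ordering comparisons; the vignette-level claims hold at these sizes
and the engine scales to larger runs linearly in cell count. At the
sterilisation scale the fractions-to-sterilisation curve resolves optima
only to about one fraction, so the location of its minimum carries a
grid-point of uncertainty even with replicate averaging.

The model is a caricature in known ways: no explicit DNA-repair or
checkpoint-gene dynamics, no oxygen-dependent radiosensitivity or
reoxygenation effect on LQ coefficients, no vasculature, validity restricted
to conventional fraction sizes (the LQ form is not trusted at
radiosurgery-scale doses), and mechanics reduced to spherical cell centres
with pairwise forces rather than a full tessellation — adequate for packing,
pressure gradients and connectivity, which are all the observables consume.
Daughters inherit nothing but their birth neighbourhood; cycle clocks and
durations are resampled, as no heritability is established for them.

## A worked run

```{r}
library(spheroidrt)

cfg <- sim_config(profile = "desk", seed = 1, grow_days = 9)
grown <- simulate_growth(cfg)
glance(grown)

treated <- simulate_treatment(grown, build_constant_rate(2.5, 30),
                              horizon_days = 12)
tumour_burden(treated$series, treated$treatment_start,
              treated$treatment_start + 12 * 24)
autoplot(treated)
plot_section(treated$population)
```
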