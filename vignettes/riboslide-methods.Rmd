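---
title: "Models and methods behind riboslide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riboslide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboslide)
```

# The biological problem

During programmed bypassing, a ribosome translating bacteriophage T4 *gene
60* finishes ORF1 (46 codons), detaches from its take-off codon, slides
across a 50-nt non-coding gap without decoding, and — if it survives the
trip — re-pairs at a landing codon and translates ORF2. Gel densitometry of
the translation products gives band intensities over time for the pausing
intermediates (INT1–INT3), the terminated ORF1 product, and the full
bypassing product (ORF1+2). `riboslide` implements the quantitative layer
that turns such tables into kinetic and thermodynamic statements: a
five-step chain model of ORF1 translation, a per-nucleotide processivity
model of the sliding phase, a two-regime gap-length analysis, a
temperature-shift model, and a free-energy representation.

There is no deposited raw dataset for this kind of experiment, so the
package ships a first-class synthetic-data module that emulates the
densitometry-level tables from the same models plus explicit noise; every
fitting stage is validated end to end against the generator's recorded
truth.

# The translation chain

`chain_model()` holds five irreversible first-order rate constants
`k1..k5` (1/s) for

```
pre-INT1 -> INT1 -> INT2 -> INT3 -> take-off state -> ORF1+2
```

plus a branch fraction `f_byp`: of the ribosomes arriving at the take-off
state, the fraction `f_byp` completes bypassing and ORF2 synthesis with
rate `k5`; the remainder terminates as ORF1 product. The gel cannot
distinguish a ribosome paused at take-off from the terminated product —
both run as the "ORF1" band — so `chain_occupancies()` reports their sum
as the observable ORF1 column by default (`collapse_orf1 = FALSE` splits
them). Occupancies are the closed-form Bateman solution of the linear
chain; they sum to one at every time by construction.

Numerical choices:

* **Near-degenerate rates.** The partial-fraction form divides by rate
  differences. A single near-equal pair (relative gap below `1e-6`) is
  perturbed by `1e-6` relative before evaluation, which keeps the error
  far below the noise level of any fit. Multi-way degeneracies (two or
  more relative gaps below `1e-4`) cancel catastrophically in double
  precision, so those inputs are routed automatically to adaptive ODE
  integration (`deSolve`, `rtol = 1e-10`), which is also available
  explicitly via `method = "ode"`.
* **Global fitting.** `global_fit()` minimises weighted least squares over
  all species simultaneously with Levenberg–Marquardt, rates on the log
  scale and the branch fraction on the logit scale, from 20 multi-starts
  drawn log-uniformly over `[1e-3, 10]` 1/s (default seed 1203). Weights
  are inverse per-species standard deviation when replicates exist,
  uniform otherwise. Fewer than 8 distinct time points raises an
  under-determination warning rather than an error.
* **Uncertainty.** Intervals come from a cluster wild bootstrap: one
  Gaussian multiplier per gel lane (time point × replicate), with HC2
  leverage rescaling of the residuals. The clustering matters because
  band fractions within a lane are renormalised to total lane signal and
  therefore correlated; the leverage correction matters because only a
  few early time points inform the fastest rate, and raw residuals there
  systematically understate the noise. In simulation at the default
  design (12 time points, 3 replicates, 5% multiplicative band noise) the
  nominal 95% intervals are approximately 90% calibrated; the test suite
  asserts a conservative lower bound on aggregate coverage rather than
  nominal coverage.

`local_rates()` converts each step into the mean elongation rate over its
mRNA segment (segment length × rate constant), the quantity used to talk
about local slowdown as the nascent peptide reaches the exit-tunnel
constriction.

# The sliding phase

The headline model treats sliding as a per-nucleotide Bernoulli process:
with forward rate `k_forward` (nt/s) and combined loss
`k_dropoff + k_backward`, the probability of advancing one nucleotide is

```
P = k_forward / (k_forward + k_dropoff + k_backward)
```

and bypassing efficiency over an `L`-nt gap is `A · P^L`, where `A` is the
combined probability of take-off and landing. This model counts a backward
step as a loss. That is a deliberate simplification, kept because it is
the field's standard parameterisation; the package additionally provides
the exact birth–death treatment (`first_passage_exact()`), in which
backward excursions can recover, via tridiagonal linear solves for both
the reach probability and the conditional mean traversal time. The exact
reach probability is never below `A·P^L` and coincides with it when
`k_backward = 0` — a property the test suite checks. `simulate_sliding()`
is the stochastic (Gillespie) counterpart, vectorised across trajectories
and exactly reproducible from its seed.

The boundary at position 0 reflects by default: mRNA refolding behind the
ribosome blocks backward motion at the take-off side. In a continuous-time
chain a backward self-loop at 0 is distributionally identical to removing
the backward hazard there, and both the solver and the simulator implement
it that way; `boundary = "absorb"` treats a backward step at 0 as loss,
for the unsupported-sliding regime. Landing requires completing `L`
forward steps from position 0.

## Two regimes and the breakpoint

Efficiency versus gap length shows a constant-`P` regime on short gaps and
a collapsing regime on long ones. `processivity_model()` encodes this as
constant `P` up to a breakpoint `L*` and a linear per-nucleotide decline
`d` beyond it: nucleotide `j > L*` contributes a factor
`max(P − d·(j − L*), 0)`. The linear form is the package's choice — the
data only say the decline is progressive — and `d` is exposed.

`fit_breakpoint()` scans integer candidate breakpoints, fits `(P, d)` for
each (amplitude fixed at 1 by default, since nearly all ribosomes take off
and land), and keeps the candidate with minimal squared error. A
two-regime claim must beat the single-regime fit in an F-test (default
level 0.05); otherwise a `"single_regime"` result is returned — that is an
outcome, not an error. Fitting is on the linear efficiency scale by
default with a log-scale option (`fit_exponential_gap_model(transform=)`),
since the weighting the original analysis used is not recorded.

## Generator defaults for the gap series

The generator's defaults are the study conditions, not tuning knobs: gaps
38–92 nt in steps of 3 (the deletion/insertion series built from 6-nt
repeats), `A = 1`, `P = 0.99`, breakpoint 56 nt, additive Gaussian noise
`σ = 0.02` on efficiencies (matching the visual replicate scatter of such
assays), two replicates. The decline is derived, not free-floated: it is
the unique linear slope for which the per-gap-length processivity
coefficient `efficiency^(1/L)` at the longest gap (92 nt) equals
`1.2/(1.2 + 0.04)` — i.e. the combined loss rate rises from 0.01 to
0.04 nt/s across the long-gap range, which collapses efficiency to ~5% at
92 nt. An alternative reading — letting the *instantaneous* per-nt
probability, rather than the per-gap average, reach that loss rate at
92 nt — gives a decline roughly five times gentler and leaves efficiency
near 26% at 92 nt, which is hard to reconcile with the sharp long-gap
drop-off these experiments show; it was considered and rejected.

# Temperature dependence

Cooling does two things to the efficiency-versus-length curve: it lowers
the maximum and moves the curve toward shorter gaps. Both are captured by
a single leftward translation: `recurrent_bypassing()` evaluates

```
byp(T, L) = A · P_ref^max(L + Δnt(T), 0)
```

with `Δnt(T) ≥ 0` the shift at temperature `T` relative to the 37 °C
reference (`Δnt(37) = 0`). The sign convention deserves a note: written
with a *minus* sign, the same formula would predict efficiency rising as
temperature falls, which contradicts the observed ordering of the
temperature series; the leftward convention reproduces both the ordering
and the rule of thumb that a ribosome population sliding 80 nt at 37 °C
manages only ~40 nt at 10 °C under a 1.5 nt/°C shift. `fit_temp_shift()`
estimates `P_ref` on the reference sub-series (amplitude fixed at 1 by
default; `fix_A = NULL` refits it), then one `Δnt` per temperature by 1-D
least squares, then the linear slope of `Δnt` against cooling, reported in
nt/°C. Shifts are constrained non-negative below the reference
temperature.

Whether the amplitude should be refit per temperature is genuinely open;
the default keeps it fixed, because the shift itself already absorbs the
drop in maximal efficiency under the leftward convention, and a
per-temperature amplitude would be confounded with the shift on grids that
lack very short gaps.

## Free energy

`delta_g()` maps an efficiency to
`ΔG° = −kT·ln(byp/(1 − byp))` — zero at 50% efficiency, negative when
bypassing is favourable. Units default to multiples of `kT`
(`thermo_config(temp_k=)` converts to kJ/mol). `delta_g_profile()`
evaluates a model across gap lengths, clamping efficiencies to
`[1e-6, 1 − 1e-6]` with a truncation warning before taking logs, and
interpolates the zero crossing — the gap length beyond which bypassing
stops being favourable (≈69 nt for a single-regime `P = 0.99` model, per
`log 0.5 / log 0.99`).

# Gel quantification helpers

* `bypassing_efficiency()`: ORF1+2 density over (ORF1 + ORF1+2); both
  bands zero is an error, never a silent 0/0.
* `calibrate_band_length()`: interpolates each band border against a
  peptide ladder — piecewise-linear in log length versus mobility, the
  conventional gel calibration (a plain linear option exists) — and
  reports the border midpoint, rounded to whole amino acids with the raw
  value retained. Extrapolation beyond the ladder refuses rather than
  guesses.
* `completion_time()`: how "synthesis time" is extracted from a plateau
  curve is a convention, so it is an exposed policy: fit a delayed single
  exponential `amp·(1 − e^{−(t−t0)/τ})` and report `t0 + m·τ`, default
  `m = 2` (~86% of plateau). A trajectory whose final 20% of samples vary
  by more than 5% of the maximum has not plateaued and is rejected.
* `bypassing_time()`, `sliding_velocity()`, `average_elongation_rate()`:
  the timing decomposition — total time on the gapped mRNA minus the
  gap-less construct isolates take-off + sliding + landing; gap length
  over that time gives the sliding velocity; ORF2 length over its
  translation time gives the post-landing elongation rate.
* `rank_correlation()`: Spearman's rho for the velocity–efficiency
  association, refusing constant series.

# The synthetic-data module

`generate_timecourse()`, `generate_gap_series()`,
`generate_temperature_grid()` and `generate_ladder()` produce exactly the
CSV dialects the analysis functions read, each with a truth record
(parameters, noise, seed) so that σ = 0 output must be recovered exactly —
the package's end-to-end smoke test, run in the suite and by
`run_pipeline()`.

Defaults and what they emulate:

* **Time courses**: chain rates `(0.5, 0.25, 0.25, 0.2, 0.015)` 1/s with
  `f_byp = 0.49`. These give ORF1 completion within ~15 s, successive
  intermediate peaks, and an ORF1+2 plateau of 49% on an ~80 s time
  scale — the qualitative shape of fast (low-Mg²⁺, polyamine) in vitro
  translation. They are scenario defaults, not claims about unpublished
  fitted values. Noise is multiplicative log-normal (σ = 0.05) on band
  densities followed by per-lane renormalisation; two replicates.
* **Gap series and temperature grids**: as described above; the
  temperature grid uses the twelve temperatures 37–10 °C and slope
  1.5 nt/°C.
* **Ladder**: marker lengths 11–41 aa with log-linear mobility and band
  fixtures at 21 ± 3, 31 ± 2 and 38.5 ± 2.5 aa, matching the measured
  pause-intermediate lengths.

What the generator does *not* emulate: gel image artefacts (smearing,
background, saturation), inter-gel calibration drift, codon-resolution
elongation, or any sequence dependence of sliding. Passing tests therefore
demonstrate correctness of the estimators under the stated noise models,
not robustness to densitometry pathologies.

# Problem sizes and determinism

The test suite and the acceptance script size their simulations to run
comfortably on a laptop: parameter-recovery studies use 12–25 seeded
repetitions, bootstrap intervals 100–200 resamples, Monte Carlo ensembles
2×10⁴–10⁵ trajectories (where the Monte Carlo standard error is already an
order of magnitude below the tolerances being checked). Every stochastic
path takes an explicit integer seed, records it in its output, and
restores the caller's RNG state; identical seeds give bit-identical
results.

# Known limitations

* The chain model is the five-step coarse-graining only; mutant constructs
  are just different datasets to it.
* Drop-off and permanent stalling are indistinguishable here, as in the
  underlying experiments; `SlidingRates` lumps them.
* The long-gap decline's linear form, and whether it reflects drop-off or
  backward sliding, are conventions — both mechanisms are expressible in
  the rate parameterisation and neither is asserted.
* Bootstrap intervals are approximate (see above); for publication-grade
  uncertainty on a specific design, run a purpose-built simulation study
  at that design.
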