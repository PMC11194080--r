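# riboslide

Kinetic analysis of programmed and spontaneous ribosome sliding along
mRNA, built around the bypassing of the 50-nt non-coding gap in
bacteriophage T4 *gene 60*.

During bypassing, a ribosome that has finished ORF1 detaches from its
take-off codon, slides across the non-coding gap without forming
codon–anticodon contacts, and resumes translation at a landing codon.
`riboslide` is for researchers who quantify such experiments from gel
densitometry: it turns band-intensity tables into rate constants,
processivities, breakpoints, temperature shifts and free energies.

## What it computes

* **Translation chain** — the minimal kinetic model of ORF1 translation is
  five consecutive irreversible steps through the pausing intermediates
  INT1–INT3 to the take-off state, whose outflow branches with fraction
  *f*<sub>byp</sub> into the bypassing product ORF1+2. Closed-form
  (Bateman) occupancies, global nonlinear least-squares fitting with
  bootstrap intervals, and per-segment local elongation rates.
* **Sliding processivity** — the per-nucleotide model

  *Bypassing efficiency* = *A* · *P*<sup>nt</sup>,
  *P* = *k*<sub>forward</sub> / (*k*<sub>forward</sub> +
  *k*<sub>drop-off</sub> + *k*<sub>backward</sub>),

  where *A* is the combined take-off/landing probability; exponential
  fitting of gap-length series, per-gap processivity coefficients, and
  two-regime breakpoint detection with an F-test against a single regime.
* **Exact and stochastic sliding** — the sliding random walk solved
  exactly (tridiagonal first-passage systems for reach probability and
  conditional traversal time) and simulated (seeded Gillespie ensembles).
* **Temperature dependence** — the recurrent shift model
  byp(*T*, nt) = *A* · *P*<sub>37</sub><sup>max(nt + Δnt(*T*), 0)</sup>
  with a linear Δnt(*T*) law (nt/°C), and the free-energy transform
  ΔG° = −kT · ln(byp / (1 − byp)).
* **Gel quantification** — bypassing efficiency from band densities,
  band-length calibration against peptide ladders, completion-time
  extraction, timing decomposition, sliding velocity, rank correlations.
* **Synthetic data** — seeded generators for every table the analyses
  consume, each with a machine-readable truth record, so the whole
  pipeline is testable end to end without laboratory data.

## Worked example

```r
library(riboslide)

# Processivity from the fitted sliding rates (nt/s)
processivity_from_rates(sliding_rates(k_forward = 1.2, k_dropoff = 0.01))
#> [1] 0.9917355

# Two-regime analysis of a seeded synthetic gap-length series
gs <- generate_gap_series(sigma = 0.02, seed = 7)
bp <- fit_breakpoint(gs$data)
bp$regime; bp$breakpoint; round(bp$P, 4)
#> [1] "two_regime"
#> [1] 57
#> [1] 0.9901

# Stochastic sliding over the natural 50-nt gap
simulate_sliding(sliding_rates(1.2, 0, 0.0121), L = 50, n = 20000, seed = 1)
#> Sliding ensemble: n = 20000 over 50 nt (seed 1)
#>   reach probability: 0.6071
#>   traversal time of successful trajectories: 41.28 +/- 5.83 s

# Where does bypassing stop being thermodynamically favourable?
pr <- delta_g_profile(processivity_model(1, 0.99), L = 30:110)
attr(pr, "zero_crossing_nt")
#> [1] 68.96772
```

Reading the numbers: a forward rate of 1.2 nt/s against a 0.01 nt/s
combined loss gives a 99% chance of advancing at each nucleotide; on a
seeded synthetic series the piecewise fit locates the regime change near
56 nt with sub-breakpoint processivity ≈ 0.99; about 61% of simulated
ribosomes traverse the natural 50-nt gap, taking ≈ 41 s (≈ 1.2 nt/s); and
with *P* = 0.99 the free energy of bypassing crosses zero near a 69-nt
gap, beyond which bypassing is unfavourable.

`run_pipeline(out_dir, seed)` chains the generators and fits into one
reproducible bundle (CSV tables plus a JSON run report).

## Package layout

* `R/` — implementation: `chain_kinetics` (Bateman chain + global fit),
  `sliding_model` (processivity, breakpoint, first passage, Gillespie),
  `thermo_model` (temperature shift, ΔG°), `gel_quant` (densitometry
  observables), `synthetic_data` (generators), `io` (schemas, pipeline).
* `tests/testthat/` — unit, property and end-to-end suites.
* `vignettes/riboslide-methods.Rmd` — the models, their assumptions,
  numerical choices and limitations.
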