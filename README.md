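# chromodyn

Chromatin mobility, polymer dynamics and Hi-C contact statistics for
interphase chromosome organization studies.

Fluorescently tagged loci in live nuclei move subdiffusively: their mean
squared displacement grows as MSD ∝ τ^α with α < 1, and α is a
fingerprint of the polymer state of the chromatin fibre — 0.5 for an
ideal Rouse chain, 2ν/(1+2ν) ≈ 0.54 for a chain with excluded volume in
good solvent, 3/4 for a semi-flexible chain. chromodyn implements the
full analysis chain that connects raw particle-tracking tables and
binned Hi-C contact matrices to those numbers, for researchers
quantifying how structural factors (condensins, cohesins, damage)
change chromatin behaviour:

* **Mobility** — per-track MSD curves; the exact weighted ensemble mean
  `⟨m(τ)⟩ = Σ N_i m_i / Σ N_i` with its exact standard error; two-stage
  power-law fits `a τ^α` (Nelder–Mead, then Levenberg–Marquardt with
  parameter covariance); `1/δα²`-weighted histograms and kernel density
  estimates of the exponent distribution; one- and two-Gaussian
  descriptions with principled model selection; the length of
  constraint L_c (sd of position about the time-averaged position).
* **Polymer simulation** — a coarse-grained bead–spring chromosome arm
  (overdamped Langevin, Euler integration, compiled core): harmonic
  bonds, constant-force excluded volume, weak spherical confinement,
  plus random-plane 2D projection mimicking single-plane imaging.
* **Scaling theory** — the analytic monomer-MSD exponent map
  `rouse_exponent(nu) = 2 nu / (1 + 2 nu)` and the reference exponent
  table.
* **Hi-C statistics** — triplet-text contact matrices; KR and vc_sqrt
  balancing; intra-arm/inter-arm/trans classification; distance decay;
  per-band z-score maps with sparse-band exclusion and strict z > 2
  interaction calling; common/specific comparison of two conditions;
  aggregate peak matrices; insulation vectors at 10–100 kb offsets with
  border profiles; loess-smoothed virtual 4C with confidence bands;
  per-bin median interaction distances.
* **Synthetic data** — fractional-Gaussian-motion track generators with
  mixture populations, Ornstein–Uhlenbeck confined tracks, and contact
  maps with power-law decay, block domains and planted loops, all with
  ground truth, so every stage is testable without external data.

## Worked example

Simulate a two-population locus ensemble — 90% of tracks with exponent
0.61 and 10% with 0.78, as seen when a confining factor is lost in a
fraction of cells — and run the mobility report:

```r
library(chromodyn)

rec <- trajectory_recipe(
  n_tracks = 1000, n_frames = 500, dt = 0.02,
  components = data.frame(weight = c(0.9, 0.1),
                          alpha = c(0.61, 0.78),
                          mobility = c(0.02, 0.02)),
  seed = 31)
ts <- generate_tracks(rec)
mobility_report(ts)
```

```
mobility report [synthetic] (1000 tracks)
  ensemble (weighted-mean-MSD slope) alpha: 0.625
  mean per-track alpha (1/dalpha^2-weighted): 0.636
  exponent distribution model: double
    components: w = 0.91 at alpha = 0.616; 0.09 at 0.823
  L_c quartiles (um): 0.116 / 0.134 / 0.157
```

The two-Gaussian description recovers the planted mixture: 91% of the
density at α ≈ 0.62 and 9% at α ≈ 0.82 (the upward offsets reflect
finite-window fit bias), and the pooled slope α ≈ 0.62 matches the main
population. The analytic anchors for interpreting such numbers:

```r
reference_exponents()
#>                          label    nu     alpha              source
#> 1                  ideal Rouse 0.500 0.5000000            computed
#> 2 excluded volume (mean-field) 0.600 0.5454545            computed
#> 3    excluded volume (refined) 0.588 0.5404412            computed
#> 4                semi-flexible    NA 0.7500000 literature constant
```

The same fitting code consumes simulated bead tracks:

```r
cfg   <- sim_config(n_beads = 500, seed = 1)        # excluded volume on
beads <- run_simulation(cfg)
fits  <- fit_exponents(beads, tau_min = 1, tau_max = 10)
mean(fits$alpha)   # ~0.58; phantom chain (excluded_volume = FALSE) ~0.51
```

A command-line wrapper over the same functions ships in
`inst/cli/chromodyn` (subcommands `synth-tracks`, `msd`, `exponents`,
`simulate`, `hic-zscore`, `virtual4c`, ..., each writing a JSON run
manifest).

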