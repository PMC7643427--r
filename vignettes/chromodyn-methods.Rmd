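---
title: "Chromatin mobility and contact statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin mobility and contact statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromodyn)
```

chromodyn quantifies how a chromatin locus moves inside the interphase
nucleus and how the chromatin fibre folds genome-wide, the two views a
single-particle-tracking plus Hi-C study of chromosome organization
produces. This vignette explains the models behind each stage, the
parameters that matter, and the design choices made where the underlying
procedures are conventionally left informal.

## 1. Mean squared displacement of a tracked locus

A trajectory is a sequence of positions $r_t$ (micrometres) at uniform
frame interval $\delta t$ (default 0.02 s, matching 20-ms-interval
imaging). For a delay $\tau = k\,\delta t$ the per-track MSD is the
average of $|r(t+\tau)-r(t)|^2$ over all $n-k$ overlapping frame pairs,
giving the displacement count $N_i(\tau) = n - k \approx
(T_i-\tau)/\delta t$. Overlapping displacements are statistically
dependent; the estimator is nevertheless defined over all of them, as is
standard, and the dependence is accounted for by the exact ensemble
standard error below rather than ignored.

The ensemble mean weights each track by $N_i(\tau)$,

$$\langle m(\tau)\rangle = \frac{\sum_i N_i m_i}{\sum_i N_i},$$

which is identical to pooling every individual squared displacement into
one sample and averaging. Its variance is computed exactly from the
per-track first and second moments,

$$\sigma^2_{\langle m\rangle}(\tau) = \frac{1}{N}\left(\frac{1}{N}
\sum_i N_i\,(m_i^2+\sigma_i^2) - \langle m\rangle^2\right),$$

where $\sigma_i^2(\tau)$ is the *population* variance of the squared
displacements within track $i$. That reading of $\sigma_i^2$ is the
unique one under which the bracket equals the pooled population variance
of all squared displacements, so the standard error reduces to
pooled-variance/$N$ — both identities are asserted to $10^{-12}$
relative in the test suite. With a single track the formula collapses to
$\sigma_i^2/N_i$ exactly.

Missing frames split a track into fragments instead of interpolating;
interpolation would manufacture artificially smooth displacements and
bias the MSD downward. A minimum-length filter (default 26 frames, so
that $\tau = 0.5$ s retains at least one displacement at
$\delta t = 0.02$ s) is exposed because published recordings rarely
state how incomplete tracks were handled.

## 2. Anomalous-diffusion exponents and their distribution

Subdiffusive loci follow $m(\tau) \approx a\tau^\alpha$ with
$\alpha < 1$. Each track's curve is fitted for
$0 < \tau \le \tau_{\max}$ (default 0.5 s — beyond that, nuclear and
stage drift dominate single-locus recordings) by unweighted least
squares in two stages: a Nelder–Mead simplex search, whose optimum seeds
a Levenberg–Marquardt refinement that supplies the exponent uncertainty
$\delta\alpha_i$ from the parameter covariance. The $\tau = 0$ point is
never part of the objective. For numerically perfect fits
$\delta\alpha$ is floored at $10^{-6}$ so the downstream
$1/\delta\alpha^2$ weights stay finite.

The population of exponents is summarized by a weighted histogram and a
weighted Gaussian-kernel density estimate, both weighted by
$1/\delta\alpha_i^2$ so precisely measured tracks dominate. The
bandwidth defaults to Silverman's rule evaluated on the weighted sample
(effective sample size $(\sum w)^2/\sum w^2$) and can be overridden.

One- and two-component Gaussian densities are then fitted to the *KDE
curve* by least squares (fitting the smoothed curve, not the raw sample,
is the convention this analysis follows; an EM fit to the raw exponents
via mclust is available with `method = "em"`). Components are reported
with $\bar\alpha_1 \le \bar\alpha_2$ and the mixing weight $w$
constrained to $[0,1]$.

Two numerical choices guard the curve fit. First, a fitted component's
sd is constrained to at least the kernel bandwidth: the KDE is the true
density convolved with the kernel, so any genuine component must be at
least kernel-wide, and without the constraint the optimizer chases
smoothing wiggles with near-zero-width spikes. Second, model selection
(`select_model()`) prefers "double" only when the two-component fit
reduces the residual sum of squares by the factor $\rho$ (default 0.5),
the component means are separated by more than $\sigma_{\alpha 1}$, and
*both* weights are at least `w_floor` (default 0.05) — a component
carrying under 5% of the density is indistinguishable from a fitting
artefact at realistic sample sizes. $\rho$ and `w_floor` are exposed.

A limitation worth knowing: with ~1000 tracks and component separation
around $0.17$ in $\alpha$, the verdict is close to the decision
boundary and flips for some generator seeds; larger samples or longer
tracks (smaller $\delta\alpha_i$) stabilize it.

## 3. Length of constraint

$L_c = \sqrt{\frac1n\sum_t |r_t-\bar r|^2}$ — the standard deviation of
the position about the time-averaged position, all coordinates summed.
It estimates the radius of the region the locus explored and is
invariant under translations and rotations. For a stationary
mean-reverting (Ornstein–Uhlenbeck) locus with per-axis sd $s$ in $d$
dimensions, $L_c \to s\sqrt d$ for long tracks; the OU generator in the
package reproduces this closed form to within 5% and anchors the test.

## 4. Polymer scaling theory

A monomer of a connected chain drags its neighbours, so its MSD is
subdiffusive. The scaling argument gives
$\alpha = \frac{2\nu}{1+2\nu}$, with $\nu$ the Flory exponent
($R_g \sim N^\nu$): the ideal (phantom) Rouse chain has $\nu = 1/2$,
$\alpha = 1/2$; excluded volume in good solvent swells the chain
($\nu = 3/5$ mean-field, $\nu \approx 0.588$ refined), raising $\alpha$
to $6/11 \approx 0.545$ and $0.5404$ respectively — both round to
"about 0.54". The semi-flexible polymer value $\alpha = 3/4$, relevant
for stiffened (e.g. damaged) chromatin, involves bending rigidity
outside this argument and is stored as a cited literature constant,
never derived.

## 5. The bead–spring simulator

`run_simulation()` evolves a chain of beads by Euler integration of the
overdamped Langevin equation: harmonic bonds between consecutive beads,
an optional constant-magnitude repulsion between any two beads closer
than one bead diameter (beads represent ten-nucleosome stretches and may
partially interpenetrate — the repulsion is finite, not a hard core),
an optional confinement sphere implemented as a constant inward radial
force outside the boundary (radial reflection available), and thermal
kicks with variance $2k_BT\,\Delta t/\zeta$ per coordinate. The full
chain defaults to 2436 beads of 25 nm radius in a 4.5 µm sphere — a
3.6 Mb chromosome arm at 10 nucleosomes per bead, confined so weakly
the sphere is effectively irrelevant.

Parameters not fixed by that geometry are the package's own defaults,
in simulation units with $k_BT = 0.0025$, $\zeta = 1$ (free-bead
$D = 0.0025\ \mu m^2$ per time unit):

* bond rest length = one bead diameter (50 nm); stiffness 100, putting
  the bond-length sd near 10% of the rest length at the default
  thermal scale (verified stationary in the tests);
* repulsion force 1, giving a mean steady-state overlap depth near 10%
  of the bead radius — deep enough to matter, shallow enough for the
  default time step;
* time step 0.002, keeping the RMS Euler step (~5.5 nm in 3D) well
  under the bead radius; a step ever exceeding the bead radius aborts
  with advice to reduce $\Delta t$;
* sampling every 25 steps; 10 000 equilibration then 50 000 sampled
  steps; the middle 50% of the chain exported as tracks (chain ends are
  anomalously mobile).

Exponents, not time scales, are the quantity of interest, and they are
insensitive to these defaults within broad ranges (the excluded-volume
ON/OFF ordering is itself asserted across seeds in the tests). The time
axis is left in simulation units; no mapping to seconds is implied.

The *intermediate-time window* for exponent fitting must sit above the
bond relaxation time ($\zeta/k = 0.01$ units) and below the chain's
Rouse time ($\sim 8\times10^3$ units for 500 beads). Calibration showed
the free-diffusion-to-Rouse crossover still contaminating delays below
~1 time unit, so the default window is the decade $[1, 10]$ units
(20–200 sampling strides); both bounds are parameters. On this window a
500-bead phantom chain fits $\bar\alpha \approx 0.51$ and the same
chain with excluded volume $\bar\alpha \approx 0.57$–0.58, bracketing
the analytic 0.5 and 0.545 as expected (constant-force repulsion is a
soft excluded volume; the simulated exponent sits slightly above the
asymptotic scaling prediction, consistent with pre-asymptotic swelling
at the length scales the window probes).

Desk-scale runs use ~500 beads; the full 2436-bead chain is available
by setting `n_beads` and completes in tens of minutes on one core.

`project_to_plane()` mimics single-focal-plane imaging: orthogonal
projection onto a plane with uniformly random normal. It preserves the
mean exponent (each in-plane coordinate is a linear combination of
independent axes with the same temporal correlations) while broadening
the fitted-exponent distribution (each 2D fit sees fewer coordinates),
and projected MSDs are 2/3 of 3D MSDs for isotropic motion — all three
properties are asserted in the tests.

## 6. Hi-C statistics

Contact maps are symmetric binned matrices with masked-bin propagation
(masked bins leave all statistics, never zero-filled).

* **Balancing**: `kr_balance()` equalizes row sums (rtol $10^{-6}$) by
  the symmetric scaling fixed-point iteration, which converges to the
  Knight–Ruiz balancing vector; `vc_sqrt_balance()` divides each entry
  by $\sqrt{c_ic_j}$ of the bin coverages.
* **Classification**: value-weighted proportions of intra-arm,
  inter-arm and trans contacts; arm membership by bin midpoint relative
  to the centromere.
* **Distance decay**: mean contact value of intra-arm pairs in
  log-spaced separation bands.
* **z-scores**: intra-arm pairs at separation $\ge 2$ bins (self and
  nearest-neighbour pairs are dominated by digestion/religation signal)
  are standardized within their genomic-separation band; bands with
  fewer than 15 pairs, or zero spread, are masked entirely. Band
  statistics are per-arm by default (genome-wide pooling optional).
  Interactions are pairs with $z$ *strictly* greater than 2.
* **Aggregate matrices**: windows of ±8 kb genomic distance around each
  called pair (9×9 at 2 kb bins — an odd, centred window; the
  half-window is a parameter), each divided by its own mean, then
  averaged; windows truncated by arm edges are dropped.
* **Insulation**: 10 kb vectors of mean contact values at offsets
  10–100 kb in 10 kb steps, each pair assigned to the coarse bin of its
  genomic midpoint; edge bins lacking the full complement of midpoints
  are masked rather than partially averaged. Border profiles normalize
  a ±100 kb window by its mean, take log2, and average across borders
  (border lists come from external domain callers as BED).
* **Virtual 4C**: one matrix row, loess-smoothed (tricube weights,
  degree 2, span 0.3 by default) with a normal-approximation pointwise
  95% band from the local fit's standard errors; the smoother
  reproduces linear profiles exactly away from edges, which the tests
  assert. Span and level are parameters; neither has a canonical value.
* **Median interaction distance**: per bin, the contact-value-weighted
  median separation to its intra-chromosomal partners.

All genomic intervals are 0-based half-open; BEDPE output satisfies
`start1 <= start2`.

## 7. Synthetic data: what it does and does not emulate

`generate_tracks()` draws stationary-increment fractional Gaussian
motion with Hurst exponent $H = \alpha^*/2$ from the exact Toeplitz
covariance of fractional Gaussian noise (Cholesky factorization, one
per component, reused across tracks and axes), so the ensemble MSD is
exactly $\Gamma\tau^{\alpha^*}$ — the stationary-increment subdiffusion
the analysis layer assumes. Mixture recipes assign tracks to components
by weight; localization noise (default 0) adds white Gaussian error per
frame. `generate_confined_tracks()` is an exact discrete OU process.
`generate_contact_map()` builds expected counts
$\mu_{ij} = \text{depth}\cdot|i-j|^{\gamma}$ times block-domain and
planted-loop enrichments, then draws symmetric Poisson counts, emitting
the ground-truth loop/border lists alongside;
`generate_condition_pair()` shares planted loops between two maps for
the common/specific partition analysis.

These generators validate the estimators, not the biology: real tracking
data adds localization error, drift, photobleaching-limited track
lengths and cell-to-cell variability; real Hi-C adds fragment-level
biases, unmappable regions and distance-dependent noise that Poisson
sampling on a smooth decay does not reproduce. Passing tests show the
pipeline recovers known truth under its own model assumptions — they do
not certify performance on data violating those assumptions.

Problem sizes used in the checks — 500-bead chains, 200–1000 tracks of
100–500 frames, 200-bin contact maps — were chosen so the full suite
runs in a few minutes while keeping estimator noise far below the
tolerances asserted. The two-population recovery experiment uses
500-frame tracks deliberately: at 100 frames the per-track fit noise
(sd ≈ 0.2) provably swamps a 0.17 component separation, and no
estimator could recover the mixture.

## 8. Reproducibility

Every stochastic stage takes an explicit integer seed and is
bit-reproducible under it; the CLI writes a JSON manifest (resolved
parameters, seed, package version) next to each output.
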