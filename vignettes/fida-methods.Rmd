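---
title: "Models and methods behind fidascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fidascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fidascreen)
```

# The measurement model

A FIDA measurement mobilizes a thin plug of fluorescent indicator through
a capillary by pressure-driven laminar flow. Three relations carry the
whole analysis.

**Poiseuille transit.** The mean flow velocity under a pressure drop
$\Delta P$ (applied across the full capillary of length $L$, radius $r$,
buffer viscosity $\eta$) is $\bar v = \Delta P\, r^2 / (8 \eta L)$.
With the default geometry (75 μm inner diameter, $L$ = 1 m, detection at
$L_d$ = 0.84 m) and 400 mbar mobilization, the transit to the detector is
about 106 s — the "reaction time" available for in-capillary mixing.
Pressures are mbar in every interface and converted to Pa internally.

**Taylor–Aris dispersion.** Radial diffusion averages the solute across
the parabolic profile, so the plug spreads axially with an effective
dispersion $K = \bar v^2 r^2/(48 D) + D$, giving a Gaussian temporal peak
of variance $\sigma_t^2 = r^2 t_R/(24 D)$ at retention time $t_R$. We use
the cross-section-averaged (24-denominator) temporal form; the 48-based
dispersion-coefficient bookkeeping is the same algebra one step earlier.
The regime is valid when the residence number $\tau = D t_R / r^2$
exceeds ~1.4 (exposed as a configurable constant; violations set the
`TAYLOR_INVALID` flag).

**Stokes–Einstein.** $R_h = k_B T / (6\pi\eta D)$ converts the fitted
diffusivity to a hydrodynamic radius. The instrument temperature and
buffer viscosity are not themselves measured by the assay; defaults are
298.15 K and 8.9·10⁻⁴ Pa·s (water at 25 °C), both configurable in
`fida_method()` (a high-salt buffer correction belongs there too).

**Injection-plug broadening.** The indicator plug is loaded for 10 s at
50 mbar, i.e. a ~1 cm slug, which adds a top-hat of temporal width
$w$ ≈ 1.25 s at the detector; its variance $w^2/12$ (σ₀ ≈ 0.36 s) is
added in quadrature by the simulator and subtracted in quadrature by the
fitter (toggle `subtract_plug` to mimic idealized analysis). Fits whose
peak is narrower than the plug fail explicitly rather than return a
radius.

# Peak fitting

The fitter restricts the Gaussian least-squares to the points whose
baseline-corrected signal exceeds $(1-\text{fraction})$ of the peak
height; the default fraction 0.75 keeps the top 75 % of the peak. An
alternative reading of "75 % of the Taylorgram" (central 75 % of the
area) was considered and rejected for simplicity; the fraction is an
option, so either convention can be emulated.

Numerical choices worth knowing:

* **Baseline is estimated, not co-fitted, by default.** The robust
  baseline is the median of the first and last 10 % of samples; the
  mismatch score $|\text{pre} - \text{post}|/\text{peak height}$ flags a
  buffer/baseline mismatch above 0.05. Inside the top-75 % window the
  baseline, amplitude and width of a truncated Gaussian are nearly
  collinear, which makes a free-baseline fit ill-posed (we observed
  rank-deficient Jacobians on clean data). The default therefore fixes
  the baseline at the flank estimate; `fit_baseline = TRUE` restores the
  free-baseline fit.
* **Starts are deterministic**: $t_R$ from the argmax, σ from
  FWHM/2.355, amplitude from the peak height. Optimization uses
  Levenberg–Marquardt (minpack.lm) with positivity bounds.
* **Noise** is 1.4826 × the median absolute deviation of the flanks;
  S/N below 50 (the assay's working floor) sets `LOW_SNR`.
* **Two-species fits** (free label correction) share one retention time;
  the locked species' width is computed from its locked radius (0.6 nm
  for the labelled-protein workflow) at the shared $t_R$, and the main
  mole fraction is the amplitude fraction, matching the simulator's
  convention that peak amplitude is proportional to mole fraction. A
  main radius within 25 % of the locked one sets `DEGENERATE_LOCKED`.
* **Viscosity normalization** estimates the sample/buffer viscosity
  ratio as $f = t_R/t_R^{\text{buffer}}$ and divides the apparent radius
  by $f$ — exact under the model, because elevated viscosity slows flow
  and diffusion by the same factor. $f < 0.8$ warns (faster than buffer
  is physically suspicious).

# The synthetic-data generator

The generator emulates the statistical structure of a lysate screening
campaign so that every downstream stage is testable without an
instrument:

* single- or two-species Gaussian peaks with plug broadening and i.i.d.
  Gaussian noise (shot noise is deliberately out of scope);
* lysate autofluorescence (flat offset ∝ 1/dilution), a smoothed
  baseline-mismatch step (amplitude ∝ 1/dilution) centred on the peak,
  viscosity interpolating as $1 + (f_0 - 1)/\text{dilution}$ (ideal
  mixing — no functional form is measured, this is the simplest
  consistent choice), and a nonspecific radius shift ∝ 1/dilution;
* campaign structure: binder × dilution × replicate traces plus
  preculture and buffer-only references, with analyte concentration
  equal to expression level divided by dilution, and a truth record for
  scoring.

Two calibration choices deserve emphasis, both made once from the
qualitative behaviour they must reproduce (elevated apparent radii and
baseline artifacts in concentrated lysates; clean separation of heat
lysates at 1:30; persistent false positives for detergent lysates):

* the nonspecific shift at stock is 0.9 nm for heat lysis and 16 nm for
  chemical lysis, with fixed per-binder multipliers 0.7–1.4 emulating
  composition differences. The chemical value is deliberately large: for
  a shift decaying as 1/dilution to still exceed the 10 % threshold at a
  1:100 dilution of a 1.15 nm indicator, the stock value must exceed
  ~11.5 nm. It abstracts detergent-solubilized aggregates rather than a
  literal species size;
* the preculture receives 10 % of the shift (host background only),
  because false positives are defined *relative to the preculture* and
  arise from the over-expressed protein present only in binder lysates.

What passing tests on these simulations do **not** show: real lysates
have correlated, non-Gaussian noise, adsorption and tailing peaks,
day-to-day drift (the study compares some samples only within a day),
and expression levels unknown in advance. The generator's defaults are
calibrated to qualitative patterns, not to quantitative lysate data.

# The finite-difference oracle

`pde_taylorgram()` is an independent brute-force check of the Gaussian
pipeline: it solves $\partial_t c = K \partial_x^2 c - \bar v
\partial_x c$ with the effective dispersion above, a resolved top-hat
plug, operator splitting (advection advances exactly one cell per step
at Courant number 1, so it introduces no numerical dispersion) and
sub-cycled FTCS diffusion under the $dt \le dx^2/2K$ bound; unstable or
under-resolved grids are refused.

Detection matters. The *physical* time series at a fixed detector is
slightly skewed because dispersion keeps growing while the peak crosses;
a symmetric Gaussian fit of that profile under-reads the radius by about
$9(\sigma_t/t_R)^2$ — ~2.5 % for a 1.15 nm species and ~10 % at 5 nm
under the default program. This is a limitation of the Gaussian
approximation itself (simulator *and* fitter share it), not of either
implementation. The oracle therefore offers two modes: `"snapshot"`
records the spatial profile at the moment of passage (the
frozen-dispersion assumption the closed form makes), which is the
apples-to-apples equivalence check and agrees with the pipeline within
0.5 %; `"window"` records the fixed-position series and is used to
*quantify* the skew bias as documented physics.

# Binding analysis

`fraction_bound()` evaluates the exact 1:1 mass-action solution with
indicator depletion in the cancellation-free conjugate form
$f_b = 2B/(S + \sqrt{S^2 - 4IB})$; the textbook $(S - \sqrt{\cdot})/2I$
form loses ~8 significant digits in the trace regime. The trace limit
$B/(B + K_D)$ is used when $I$ is negligible.

The apparent radius under fast exchange is the mole-fraction-weighted
arithmetic mean of the radii (the convention of the instrument
software's binding model); the diffusivity-weighted alternative
(harmonic in $R_h$) is available as `mode = "d"` and is always the
smaller of the two. $K_D$ is fitted on a log scale within 10⁻¹²–10⁻²
M (bound hits are flagged), weighted by 1/SD² when replicate SDs exist;
the free radius is fixed to the separately measured indicator-alone
value by default (fitting it changes a clean $K_D$ by < 0.5 %). The
indicator concentration in the depletion quadratic is the loaded
concentration — no intra-capillary dilution correction is attempted.
Kinetic under-equilibration in capillary-mixing mode is modelled in the
generator by the factor $1 - e^{-(k_{on}[B] + k_{off})t_{contact}}$ with
the contact time taken from the mobilization transit; slow associators
therefore under-read, as in the real assay.

# Hit calling

Two rules are implemented, matching the two screening regimes:

* **threshold**: hit iff mean $R_h \ge (1+\theta)\,R_h^{\text{ref}}$,
  default $\theta$ = 0.10; the reference (indicator alone for purified
  screens, preculture for lysate screens) is always caller-supplied,
  never inferred;
* **Dunnett**: one-way ANOVA followed by one-sided (greater)
  many-to-one comparisons against the control — one-sided because
  binding can only increase the radius (the sidedness is this package's
  choice; sources rarely state it). The many-to-one correlation has
  product structure, so $P(\max_j T_j \le t)$ is computed by the classic
  deterministic double quadrature over the common normal factor and the
  pooled-variance chi factor (64-node Gauss–Legendre; agrees with
  reference multivariate-t implementations to < 10⁻³ and is two orders
  of magnitude faster, which is what makes 1000-replicate null
  calibrations practical). Technical replicates are treated as the
  test's n — with the documented caveat that small-variance technical
  replicates make tiny shifts significant, so be skeptical of
  significant hits with a small radius change.

Where a dilution ladder is screened, tests run per dilution (a one-way
many-to-one design per level) rather than as a two-way layout — a
simplification, noted here, that keeps the control comparison local to
its own dilution. The threshold rule is scale-invariant; Dunnett
adjusted p-values are never smaller than the raw one-sided p-values.

When the *predicted* complex change is below twice the threshold,
`predicted_complex_change()` recommends the statistical rule: with an
8 % true change, triplicates and 0.5 % replicate noise, the 10 %
threshold misses a 44 nM binder that the Dunnett rule calls — the
motivating trade-off between the two rules.

# Radius prediction

Two routes, used to sanity-check measured complex sizes within the ~9 %
error the structure-correlator approach carries:

* sequence power laws $R_h(\text{Å}) = 4.75\,N^{0.29}$ (folded) and
  $2.49\,N^{0.509}$ (disordered);
* a Kirkwood bead sum over the structure,
  $1/R_h = N^{-2}\big(\sum_i 1/a_i + \sum_{i\ne j} g(r_{ij})\big)$ with
  $a_i$ = element van der Waals radius + hydration shell and
  $g(r) = 1/r$ for separated beads. For overlapping beads the plain
  $1/r$ kernel is replaced by the Rotne–Prager–Yamakawa regularized
  pair mobility $(1/\bar a)(1 - r/4\bar a)$, which joins $1/r$
  continuously at contact. This matters: with the plain kernel the pair
  term alone caps a 13-residue helix at 7.1 Å regardless of hydration,
  so no shell could reconcile the structure route with the ~10 Å
  sequence prediction; with the RPY kernel, heavily hydrated beads
  overlap and the estimate grows with the hydrated envelope, as it
  should. Closed-form results for one bead ($R_h = a$), two separated
  beads ($2ad/(a+d)$) and the contact dumbbell (+33 %) are unchanged.

The Cα-mode hydration shell (5.8 Å, i.e. an effective residue bead of
7.5 Å — comparable to the 6.1 Å beads used by standard Cα-level
hydrodynamic calculators) is calibrated once so the ideal 13-residue
helix matches the folded power law; the heavy-atom mode uses a
conventional 1.1 Å water shell. The fluorophore label is ignored
throughout, and no claim is made beyond the ~9 % band: dynamics, shape
anisotropy and label effects are all outside the model.

# Problem sizes and determinism

All randomness flows from explicit integer seeds; identical seeds give
bit-identical traces, campaigns and tables. The shipped test suite
works at desk scale, chosen to finish in well under an hour on one
core: 200-trace accuracy sweeps, 100-seed recovery runs at the S/N 50
floor, 50-replicate K_D recovery per affinity, full 10-binder campaigns
over the 1:2–1:100 ladder in triplicate, and 1000-replicate null
calibrations of the Dunnett rule at the summary level.

# Known limitations

* The Gaussian model ignores the finite-residence skew quantified by
  the oracle's window mode; for species beyond ~5 nm under the default
  program (τ approaching 1.4) both the approximation and the regime
  degrade together.
* Lysate effects are modelled additively and independently; real
  matrices couple them.
* Only 1:1 stoichiometry is fitted; multimerization is only *detected*
  (via predicted-vs-measured size), never modelled.
* The structure-based predictor is a smooth-bead approximation with a
  calibrated shell, not a boundary-element hydrodynamics solver.
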