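# fidascreen

Simulation and analysis of flow-induced dispersion analysis (FIDA)
experiments for screening designed protein binders.

## The problem

Computational protein design produces far more binder candidates than can
be characterized carefully, so screening throughput is the bottleneck.
FIDA offers a route around purification: a fluorescently labelled
*indicator* (the target, e.g. a 1.15 nm FITC-labelled helical peptide tag
or a 2.96 nm labelled SH3-GK domain) is injected into a 75 μm capillary
and mobilized by pressure-driven laminar flow. Taylor dispersion spreads
the plug into a bell-shaped peak (a *Taylorgram*) whose width encodes the
indicator's diffusion coefficient, hence its hydrodynamic radius via
Stokes–Einstein:

    sigma_t^2 = r^2 t_R / (24 D),        R_h = k_B T / (6 pi eta D)

When an unlabelled binder in the sample (even a crude bacterial lysate)
binds the indicator, the apparent R_h grows. A single capillary-mixing
measurement therefore reports binding; a dilution series of the binder
gives the dissociation constant through the exact depletion-corrected
1:1 isotherm

    f_b = 2B / (S + sqrt(S^2 - 4 I B)),   S = I + B + K_D,
    R_h(app) = R_h(free) + f_b (R_h(complex) - R_h(free))

The package implements this whole workflow for simulated campaigns: the
capillary physics and a finite-difference advection–dispersion oracle, a
forward simulator of raw Taylorgrams and lysate screening campaigns
(autofluorescence, viscosity, baseline mismatch, nonspecific binding),
Gaussian dispersion fitting with quality control and viscosity
normalization, two-species fits with a locked free-label radius, K_D
fitting, hit calling by a fixed 10 % R_h threshold or by one-sided
Dunnett many-to-one testing against a preculture control, and
structure/sequence-based R_h prediction for sanity-checking measured
complex sizes.

## Worked example

Simulate one noisy measurement of the free indicator at the assay's
signal-to-noise floor, and fit it:

```r
library(fidascreen)
m  <- fida_method()                               # 75 um x 1 m capillary, 400 mbar mobilization
tg <- simulate_taylorgram(m, species_state(1.15), indicator_conc = 50e-9,
                          noise_sd = 1, seed = 7) # S/N ~ 50
fit_taylorgram(tg, m)
#> Taylorgram dispersion fit: rh = 1.162 nm
#>   t_R = 106.35 s, sigma_t = 5.444 s, amplitude = 49.8, baseline = -0.0185
#>   D = 2.112e-10 m^2/s, S/N = 51.3, tau = 15.98
```

The peak arrives at the 84 cm detection window after ~106 s; its 5.4 s
width corresponds to a 1.16 nm radius (truth 1.15 nm; `tau` ≈ 16 ≫ 1.4
confirms the Taylor regime). Titrate a micromolar binder and fit the
1:1 isotherm:

```r
tt <- simulate_titration(kd = 2.76e-6, rh_free = 1.15, rh_complex = 2.40,
                         indicator_conc = 50e-9,
                         analyte_ladder = 0.1e-6 * 2^(0:11),
                         replicates = 3, noise_sd_nm = 0.02, seed = 7)
fit_kd(tt, indicator_conc = 50e-9, fix_rh_free = 1.15)
#> 1:1 binding isotherm fit: KD = 2.67 uM (SE 0.082)
#>   rh_free = 1.150 nm (fixed), rh_complex = 2.396 nm (SE 0.0055)
#>   indicator 50 nM, 12 points, RSS 14.13
```

The 2.76 μM truth is recovered within 4 % from a 12-point two-fold
ladder in triplicate. A whole lysate campaign runs as:

```r
truth <- campaign_preset("alfa")                  # 10 candidates, 4 true binders
camp  <- simulate_campaign(truth, lysate_model("heat"), m, seed = 1)
rep   <- dilution_series_report(fit_campaign(camp, m), truth)
subset(rep$by_dilution, rule == "threshold", c(dilution_factor, fp, fn))
```

which shows false positives at low lysate dilutions vanishing by 1:30
while every true binder is retained — the rationale for screening
heat-treated lysates at a 30-fold dilution.

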