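#' Species state
#'
#' One fluorescent species in a mixture: hydrodynamic radius, mole
#' fraction, and relative brightness per molecule. Mole fractions of a
#' mixture must sum to 1.
#'
#' @param rh_nm Hydrodynamic radius in nm.
#' @param mole_fraction Mole fraction in `[0, 1]`.
#' @param brightness Relative fluorescence per molecule (default 1).
#' @return Object of class `species_state`.
#' @export
species_state <- function(rh_nm, mole_fraction = 1, brightness = 1) {
  stopifnot(rh_nm > 0, mole_fraction >= 0, mole_fraction <= 1,
            brightness >= 0)
  structure(list(rh_nm = rh_nm, mole_fraction = mole_fraction,
                 brightness = brightness), class = "species_state")
}

#' Lysate background model
#'
#' Statistical model of a bacterial lysate's effect on a measurement:
#' autofluorescence, elevated viscosity, nonspecific interactions that
#' inflate the apparent indicator radius, and a buffer/baseline mismatch
#' step. All dilution-dependent quantities decay from their stock value as
#' `1/dilution` (ideal mixing). Chemical (detergent) lysis keeps all host
#' proteins in solution and defaults to a much larger nonspecific shift
#' than heat lysis, which precipitates heat-labile host proteins.
#'
#' @param lysis_mode `"heat"` or `"chemical"`.
#' @param autofluorescence_level Background fluorescence (a.u.) at
#'   dilution 1.
#' @param viscosity_factor_at_stock Sample/buffer viscosity ratio at
#'   dilution 1 (>= 1).
#' @param nonspecific_rh_shift Apparent-radius inflation (nm) at
#'   dilution 1 for samples containing the over-expressed protein.
#' @param baseline_mismatch_amplitude Amplitude (a.u.) of the smoothed
#'   baseline step at dilution 1.
#' @param preculture_shift_frac Fraction of the nonspecific shift present
#'   in the preculture (host background only; default 0.1).
#' @return Object of class `lysate_model`.
#' @export
lysate_model <- function(lysis_mode = c("heat", "chemical"),
                         autofluorescence_level = NULL,
                         viscosity_factor_at_stock = NULL,
                         nonspecific_rh_shift = NULL,
                         baseline_mismatch_amplitude = NULL,
                         preculture_shift_frac = 0.1) {
  lysis_mode <- match.arg(lysis_mode)
  def <- if (lysis_mode == "heat")
    list(auto = 30, visc = 1.6, shift = 0.9, mismatch = 15)
  else
    list(auto = 60, visc = 1.3, shift = 16, mismatch = 40)
  autofluorescence_level <- autofluorescence_level %||% def$auto
  viscosity_factor_at_stock <- viscosity_factor_at_stock %||% def$visc
  nonspecific_rh_shift <- nonspecific_rh_shift %||% def$shift
  baseline_mismatch_amplitude <- baseline_mismatch_amplitude %||% def$mismatch
  stopifnot(autofluorescence_level >= 0, viscosity_factor_at_stock >= 1,
            nonspecific_rh_shift >= 0, baseline_mismatch_amplitude >= 0,
            preculture_shift_frac >= 0, preculture_shift_frac <= 1)
  structure(list(lysis_mode = lysis_mode,
                 autofluorescence_level = autofluorescence_level,
                 viscosity_factor_at_stock = viscosity_factor_at_stock,
                 nonspecific_rh_shift = nonspecific_rh_shift,
                 baseline_mismatch_amplitude = baseline_mismatch_amplitude,
                 preculture_shift_frac = preculture_shift_frac),
            class = "lysate_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## sample/buffer viscosity ratio at a given dilution (ideal mixing)
.viscosity_at_dilution <- function(lysate, dilution) {
  if (is.null(lysate)) return(1)
  1 + (lysate$viscosity_factor_at_stock - 1) / dilution
}

#' Simulate a raw Taylorgram
#'
#' Forward model of one measurement: each species contributes a Gaussian
#' sharing the viscosity-scaled retention time, with Taylor-Aris width
#' (plug broadening added in quadrature) and peak amplitude proportional
#' to `mole_fraction * brightness * indicator_conc` (1 a.u. per nM at
#' brightness 1). Elevated sample viscosity `f` slows the flow
#' (`t_R -> f t_R`) and slows diffusion (`D -> D/f`), so the apparent
#' radius read off an uncorrected fit is inflated by `f`. Optional lysate
#' background adds autofluorescence, a smoothed baseline-mismatch step and
#' a nonspecific radius shift; i.i.d. Gaussian noise is added last.
#'
#' @param method A [fida_method()].
#' @param species A `species_state` or list of them (mole fractions
#'   summing to 1).
#' @param lysate Optional [lysate_model()].
#' @param dilution Lysate dilution factor (>= 1).
#' @param indicator_conc Indicator concentration in M.
#' @param noise_sd SD of additive Gaussian noise (a.u.).
#' @param seed Optional integer seed (local to this call).
#' @param dt Sampling interval in s (default 0.2).
#' @param duration Recording length in s; defaults to the mobilization
#'   step duration, extended if needed to cover the peak.
#' @param nonspecific_scale Per-sample multiplier on the lysate's
#'   nonspecific shift (models variable expression/composition).
#' @return A [taylorgram()].
#' @export
simulate_taylorgram <- function(method, species, lysate = NULL,
                                dilution = 1, indicator_conc = 50e-9,
                                noise_sd = 0, seed = NULL, dt = 0.2,
                                duration = NULL, nonspecific_scale = 1) {
  if (inherits(species, "species_state")) species <- list(species)
  if (!length(species)) stop("at least one species is required")
  fr <- vapply(species, `[[`, numeric(1), "mole_fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("species mole fractions must sum to 1")
  if (dilution < 1) stop("dilution must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  mob <- method$steps[method$steps$label == "mobilize", ]
  f <- .viscosity_at_dilution(lysate, dilution)
  tr <- transit_time(method, mob$pressure_mbar, method$detect_length,
                     viscosity_factor = f)
  s0 <- plug_sigma0(method)

  shift_nm <- if (is.null(lysate)) 0 else
    lysate$nonspecific_rh_shift * nonspecific_scale / dilution

  comp <- lapply(species, function(sp) {
    rh <- (sp$rh_nm + shift_nm) * 1e-9
    D_sample <- stokes_einstein_d(rh, method$temperature,
                                  method$buffer_viscosity) / f
    sig <- sqrt(method$capillary_radius^2 * tr / (24 * D_sample) + s0^2)
    amp <- sp$mole_fraction * sp$brightness * indicator_conc / 1e-9
    list(amp = amp, sig = sig)
  })
  sig_max <- max(vapply(comp, `[[`, numeric(1), "sig"))
  need <- tr + 6 * sig_max
  duration <- duration %||% max(mob$duration_s, need)
  time <- seq(0, duration, by = dt)

  signal <- numeric(length(time))
  for (cp in comp)
    signal <- signal + gaussian_model(time, cp$amp, tr, cp$sig)

  if (!is.null(lysate)) {
    signal <- signal + lysate$autofluorescence_level / dilution
    ## lysate plug behind the indicator: smoothed step rising through t_R
    amp_mm <- lysate$baseline_mismatch_amplitude / dilution
    signal <- signal + amp_mm / (1 + exp(-(time - tr) / (1.5 * sig_max)))
  }
  if (noise_sd > 0)
    signal <- signal + stats::rnorm(length(time), 0, noise_sd)

  taylorgram(time, signal,
             meta = list(indicator_conc = indicator_conc,
                         dilution_factor = dilution,
                         viscosity_factor_true = f,
                         retention_time_true = tr))
}

## expected apparent rh (nm) for a binder sample in the fast-exchange model
.expected_rh <- function(kd, analyte_conc, indicator_conc, rh_free,
                         rh_complex, shift_nm = 0) {
  if (is.na(kd) || analyte_conc <= 0) return(rh_free + shift_nm)
  fb <- fraction_bound(kd, indicator_conc, analyte_conc)
  apparent_rh(fb, rh_free, rh_complex) + shift_nm
}

#' Simulate a titration series
#'
#' Generates apparent radii for a two-fold (or arbitrary) analyte ladder
#' under the exact depletion-corrected 1:1 equilibrium. With `kinetics`
#' given, the equilibrium fraction bound is multiplied by the capillary
#' mixing equilibration factor `1 - exp(-(kon*[B] + koff) * contact_time)`
#' (slow associators under-read, as in capmix assays).
#'
#' @param kd True dissociation constant in M.
#' @param rh_free,rh_complex Free and complex radii in nm.
#' @param indicator_conc Indicator concentration in M.
#' @param analyte_ladder Ascending analyte concentrations in M.
#' @param replicates Replicates per point (default 3).
#' @param noise_sd_nm SD of Gaussian noise on each replicate radius (nm).
#' @param kinetics Optional list `(kon (1/M/s), koff (1/s),
#'   contact_time (s))`; `contact_time` defaults to the mobilization
#'   transit time to the detector.
#' @param method A [fida_method()] (used for the default contact time).
#' @param seed Optional integer seed.
#' @return data.frame with columns `analyte_conc_M, rh_nm, rh_sd_nm, n`.
#' @export
simulate_titration <- function(kd, rh_free, rh_complex, indicator_conc,
                               analyte_ladder, replicates = 3,
                               noise_sd_nm = 0, kinetics = NULL,
                               method = fida_method(), seed = NULL) {
  if (any(analyte_ladder < 0)) stop("analyte concentrations must be >= 0")
  if (is.unsorted(analyte_ladder)) stop("analyte_ladder must be ascending")
  if (!is.null(seed)) set.seed(seed)
  eqf <- rep(1, length(analyte_ladder))
  if (!is.null(kinetics)) {
    ct <- kinetics$contact_time
    if (is.null(ct)) {
      mob <- method$steps[method$steps$label == "mobilize", ]
      ct <- transit_time(method, mob$pressure_mbar, method$detect_length)
    }
    eqf <- 1 - exp(-(kinetics$kon * analyte_ladder + kinetics$koff) * ct)
  }
  out <- lapply(seq_along(analyte_ladder), function(i) {
    B <- analyte_ladder[i]
    fb <- if (B > 0) fraction_bound(kd, indicator_conc, B) * eqf[i] else 0
    mu <- apparent_rh(fb, rh_free, rh_complex)
    reps <- mu + if (noise_sd_nm > 0)
      stats::rnorm(replicates, 0, noise_sd_nm) else numeric(replicates)
    data.frame(analyte_conc_M = B, rh_nm = mean(reps),
               rh_sd_nm = if (replicates > 1) stats::sd(reps) else NA_real_,
               n = replicates)
  })
  do.call(rbind, out)
}

#' Campaign ground truth
#'
#' Describes a simulated screening campaign: one row per binder candidate
#' with its true dissociation constant (`NA` for a non-binder), expression
#' concentration at lysate stock, complex radius, and a per-binder
#' multiplier on the lysate's nonspecific shift; plus the indicator and
#' the experimental design (dilution ladder, replicates).
#'
#' @param binders data.frame with columns `binder_id, true_kd_M,
#'   expression_conc_M, complex_rh_nm, nonspecific_scale`.
#' @param indicator_rh_free_nm Indicator radius in nm.
#' @param indicator_conc_M Indicator concentration in M.
#' @param dilution_ladder Lysate dilution factors (>= 1).
#' @param replicates Technical replicates per condition (>= 1).
#' @return Object of class `campaign_truth`.
#' @export
campaign_truth <- function(binders, indicator_rh_free_nm, indicator_conc_M,
                           dilution_ladder = c(2, 3, 5, 10, 30, 100),
                           replicates = 3) {
  need <- c("binder_id", "true_kd_M", "expression_conc_M",
            "complex_rh_nm", "nonspecific_scale")
  stopifnot(is.data.frame(binders), all(need %in% names(binders)),
            replicates >= 1, all(dilution_ladder >= 1))
  structure(list(binders = binders,
                 indicator_rh_free_nm = indicator_rh_free_nm,
                 indicator_conc_M = indicator_conc_M,
                 dilution_ladder = dilution_ladder,
                 replicates = replicates),
            class = "campaign_truth")
}

#' Built-in campaign presets
#'
#' `"alfa"`: a 10-candidate screen against a small peptide indicator
#' (1.15 nm) where binding roughly doubles the radius; 4 true binders
#' with micromolar affinities (2.76-10 uM), 200 nM indicator.
#' `"gk"`: a 12-candidate screen against a 2.96 nm globular indicator
#' where the complex is only 8-22 percent larger; 3 true binders with
#' 44-727 nM affinities, 200 nM indicator.
#'
#' @param name `"alfa"` or `"gk"`.
#' @return A [campaign_truth()].
#' @export
campaign_preset <- function(name = c("alfa", "gk")) {
  name <- match.arg(name)
  if (name == "alfa") {
    b <- data.frame(
      binder_id = sprintf("A%02d", 1:10),
      true_kd_M = c(10.0e-6, 2.76e-6, 5.71e-6, 8.0e-6, rep(NA_real_, 6)),
      expression_conc_M = c(150e-6, 90e-6, 120e-6, 140e-6,
                            110e-6, 70e-6, 95e-6, 130e-6, 85e-6, 100e-6),
      complex_rh_nm = c(2.30, 2.40, 2.35, 2.25, rep(NA_real_, 6)),
      nonspecific_scale = c(1.0, 0.9, 1.1, 1.0, 0.8, 1.4, 1.0, 0.7, 1.2, 1.1))
    campaign_truth(b, indicator_rh_free_nm = 1.15, indicator_conc_M = 200e-9)
  } else {
    b <- data.frame(
      binder_id = sprintf("G%02d", 1:12),
      true_kd_M = c(646e-9, 44.1e-9, 727e-9, rep(NA_real_, 9)),
      expression_conc_M = c(110e-6, 100e-6, 120e-6,
                            90e-6, 105e-6, 80e-6, 130e-6, 95e-6, 100e-6,
                            115e-6, 85e-6, 125e-6),
      complex_rh_nm = c(3.40, 3.196, 3.55, rep(NA_real_, 9)),
      nonspecific_scale = c(1.0, 1.0, 0.9, 1.1, 0.8, 1.2, 1.0, 0.9,
                            1.3, 1.0, 1.1, 0.7))
    campaign_truth(b, indicator_rh_free_nm = 2.96, indicator_conc_M = 200e-9)
  }
}

#' Simulate a whole screening campaign
#'
#' Emits a Taylorgram for each binder x dilution x replicate, plus
#' preculture (no binder) and buffer-only references, with a sample sheet
#' and the truth record for downstream false-positive/negative scoring.
#' Binder analyte concentration at a given dilution is
#' `expression_conc / dilution`. All randomness flows from `seed`.
#'
#' @param truth A [campaign_truth()].
#' @param lysate A [lysate_model()].
#' @param method A [fida_method()].
#' @param noise_sd Trace noise SD in a.u. (default 2).
#' @param seed Integer seed.
#' @param dt Trace sampling interval in s.
#' @return List with `sheet` (data.frame: sample_id, role, binder_id,
#'   dilution_factor, replicate), `traces` (named list of [taylorgram()]),
#'   and `truth` (the input truth).
#' @export
simulate_campaign <- function(truth, lysate, method = fida_method(),
                              noise_sd = 2, seed = 1, dt = 0.2) {
  stopifnot(inherits(truth, "campaign_truth"), inherits(lysate, "lysate_model"))
  set.seed(seed)
  rows <- list(); traces <- list()
  add <- function(id, role, binder, dil, rep_, trace) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = id, role = role, binder_id = binder,
      dilution_factor = dil, replicate = rep_, stringsAsFactors = FALSE)
    traces[[id]] <<- trace
  }
  I <- truth$indicator_conc_M
  rf <- truth$indicator_rh_free_nm
  ind <- function(rh) species_state(rh)

  ## buffer-only references (viscosity reference retention time)
  for (r in seq_len(truth$replicates)) {
    id <- sprintf("buffer_r%d", r)
    add(id, "buffer", NA_character_, 1, r,
        simulate_taylorgram(method, ind(rf), lysate = NULL,
                            indicator_conc = I, noise_sd = noise_sd, dt = dt))
  }
  for (dil in truth$dilution_ladder) {
    pc_shift <- lysate$nonspecific_rh_shift * lysate$preculture_shift_frac / dil
    for (r in seq_len(truth$replicates)) {
      id <- sprintf("PC_d%g_r%d", dil, r)
      add(id, "preculture", NA_character_, dil, r,
          simulate_taylorgram(method, ind(rf + pc_shift), lysate = lysate,
                              dilution = dil, indicator_conc = I,
                              noise_sd = noise_sd, dt = dt,
                              nonspecific_scale = 0))
    }
    for (i in seq_len(nrow(truth$binders))) {
      bi <- truth$binders[i, ]
      B <- bi$expression_conc_M / dil
      mu <- .expected_rh(bi$true_kd_M, B, I, rf, bi$complex_rh_nm)
      for (r in seq_len(truth$replicates)) {
        id <- sprintf("%s_d%g_r%d", bi$binder_id, dil, r)
        add(id, "binder", bi$binder_id, dil, r,
            simulate_taylorgram(method, ind(mu), lysate = lysate,
                                dilution = dil, indicator_conc = I,
                                noise_sd = noise_sd, dt = dt,
                                nonspecific_scale = bi$nonspecific_scale))
      }
    }
  }
  list(sheet = do.call(rbind, rows), traces = traces, truth = truth,
       seed = seed)
}

#' Simulate replicate radii at the summary level
#'
#' Fast path for statistical studies of the hit-calling rules: skips the
#' raw traces and draws replicate fitted radii directly around their
#' expected values (same equilibrium and nonspecific-shift model as
#' [simulate_campaign()]), with relative Gaussian noise emulating the
#' radius repeatability of the dispersion fit.
#'
#' @param truth A [campaign_truth()].
#' @param lysate Optional [lysate_model()] (NULL for clean samples).
#' @param dilution Single dilution factor.
#' @param noise_frac Relative SD of replicate radii (default 0.005).
#' @param seed Integer seed.
#' @return data.frame with columns `binder_id` (control rows labelled
#'   `"PC"`), `replicate`, `rh_nm`.
#' @export
simulate_screen_rh <- function(truth, lysate = NULL, dilution = 30,
                               noise_frac = 0.005, seed = 1) {
  stopifnot(inherits(truth, "campaign_truth"))
  set.seed(seed)
  I <- truth$indicator_conc_M; rf <- truth$indicator_rh_free_nm
  n <- truth$replicates
  base_shift <- if (is.null(lysate)) 0 else
    lysate$nonspecific_rh_shift / dilution
  pc_frac <- if (is.null(lysate)) 0 else lysate$preculture_shift_frac
  mus <- c(PC = rf + base_shift * pc_frac,
           stats::setNames(vapply(seq_len(nrow(truth$binders)), function(i) {
             bi <- truth$binders[i, ]
             .expected_rh(bi$true_kd_M, bi$expression_conc_M / dilution, I,
                          rf, bi$complex_rh_nm,
                          base_shift * bi$nonspecific_scale)
           }, numeric(1)), truth$binders$binder_id))
  out <- lapply(names(mus), function(g)
    data.frame(binder_id = g, replicate = seq_len(n),
               rh_nm = mus[[g]] * (1 + stats::rnorm(n, 0, noise_frac)),
               stringsAsFactors = FALSE))
  do.call(rbind, out)
}
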