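#' @keywords internal
"_PACKAGE"

## Boltzmann constant, J/K (2019 SI exact value)
.kB <- 1.380649e-23

## Taylor-regime heuristic: dimensionless residence tau = D * t_R / r^2
## must exceed this for the Taylor-Aris description to hold.
.TAU_MIN <- 1.4

#' Capillary instrument method
#'
#' Describes the capillary geometry, temperature, running-buffer viscosity
#' and the pressure/duration program of a single FIDA measurement. Defaults
#' reproduce the standard coated-capillary assay sequence: 75 um inner
#' diameter, 1 m total length, 84 cm to the detection window, and a
#' four-step program ending in a 180 s mobilization at 400 mbar during
#' which the Taylorgram is recorded.
#'
#' @param capillary_radius Capillary inner radius in m (default 37.5e-6).
#' @param total_length Total capillary length in m (default 1.0).
#' @param detect_length Length from inlet to detection window in m
#'   (default 0.84). Must be smaller than `total_length`.
#' @param temperature Temperature in K (default 298.15).
#' @param buffer_viscosity Running-buffer dynamic viscosity in Pa s
#'   (default 8.9e-4, water at 25 C).
#' @param steps data.frame with columns `label`, `pressure_mbar`,
#'   `duration_s`: the pressure program. The last step must be the
#'   mobilization step (data are recorded during it).
#'
#' @return An object of class `fida_method`.
#' @examples
#' m <- fida_method()
#' transit_time(m, pressure_mbar = 400, length_m = m$detect_length)
#' @export
fida_method <- function(capillary_radius = 37.5e-6,
                        total_length = 1.0,
                        detect_length = 0.84,
                        temperature = 298.15,
                        buffer_viscosity = 8.9e-4,
                        steps = default_steps()) {
  stopifnot(is.data.frame(steps),
            all(c("label", "pressure_mbar", "duration_s") %in% names(steps)))
  if (!all(c(capillary_radius, total_length, detect_length,
             temperature, buffer_viscosity) > 0))
    stop("all lengths, temperature and viscosity must be strictly positive")
  if (detect_length >= total_length)
    stop("detect_length must be smaller than total_length")
  if (!all(steps$pressure_mbar > 0) || !all(steps$duration_s > 0))
    stop("all step pressures and durations must be strictly positive")
  if (steps$label[nrow(steps)] != "mobilize")
    stop("the last program step must be the 'mobilize' step")
  structure(list(capillary_radius = capillary_radius,
                 total_length = total_length,
                 detect_length = detect_length,
                 temperature = temperature,
                 buffer_viscosity = buffer_viscosity,
                 steps = steps),
            class = "fida_method")
}

#' @rdname fida_method
#' @export
default_steps <- function() {
  data.frame(label = c("equilibrate", "analyte_load", "indicator_inject", "mobilize"),
             pressure_mbar = c(3500, 3500, 50, 400),
             duration_s = c(75, 20, 10, 180),
             stringsAsFactors = FALSE)
}

#' @export
print.fida_method <- function(x, ...) {
  cat("FIDA instrument method\n")
  cat(sprintf("  capillary: r = %.1f um, L = %.2f m (detect at %.2f m)\n",
              x$capillary_radius * 1e6, x$total_length, x$detect_length))
  cat(sprintf("  T = %.2f K, buffer viscosity = %.3g Pa s\n",
              x$temperature, x$buffer_viscosity))
  cat("  program:\n")
  for (i in seq_len(nrow(x$steps)))
    cat(sprintf("    %-17s %6g mbar  %5g s\n", x$steps$label[i],
                x$steps$pressure_mbar[i], x$steps$duration_s[i]))
  invisible(x)
}

## mean Poiseuille velocity in m/s for a pressure drop over the full capillary
.mean_velocity <- function(method, pressure_mbar, viscosity_factor = 1) {
  dp <- pressure_mbar * 100  # mbar -> Pa
  dp * method$capillary_radius^2 /
    (8 * method$buffer_viscosity * viscosity_factor * method$total_length)
}

#' Poiseuille transit time
#'
#' Time for the mean laminar flow to carry a plug over `length_m` of
#' capillary under a pressure drop applied across the whole capillary:
#' `t = length / vbar` with `vbar = dP r^2 / (8 eta L_total)`. A
#' `viscosity_factor` > 1 models a sample more viscous than buffer.
#'
#' @param method A [fida_method()].
#' @param pressure_mbar Applied pressure in mbar.
#' @param length_m Distance travelled in m (at most the total length).
#' @param viscosity_factor Sample viscosity relative to buffer (>= 1 for
#'   physically ordinary samples; default 1).
#' @return Transit time in seconds.
#' @examples
#' transit_time(fida_method(), 400, 0.84)  # about 106 s
#' @export
transit_time <- function(method, pressure_mbar, length_m,
                         viscosity_factor = 1) {
  stopifnot(inherits(method, "fida_method"))
  if (pressure_mbar <= 0) stop("pressure must be strictly positive")
  if (length_m <= 0) stop("length must be strictly positive")
  if (length_m > method$total_length)
    stop("length exceeds the total capillary length")
  if (viscosity_factor <= 0) stop("viscosity_factor must be positive")
  length_m / .mean_velocity(method, pressure_mbar, viscosity_factor)
}

#' Stokes-Einstein conversions
#'
#' `stokes_einstein_rh()` converts a translational diffusion coefficient to
#' the hydrodynamic (Stokes) radius, `rh = kB T / (6 pi eta D)`;
#' `stokes_einstein_d()` is the exact inverse.
#'
#' @param diffusivity Diffusion coefficient in m^2/s.
#' @param rh Hydrodynamic radius in m.
#' @param temperature Temperature in K.
#' @param viscosity Dynamic viscosity in Pa s.
#' @return Radius in m, or diffusivity in m^2/s.
#' @examples
#' stokes_einstein_rh(2.134e-10, 298.15, 8.9e-4) * 1e9  # ~1.15 nm
#' @export
stokes_einstein_rh <- function(diffusivity, temperature, viscosity) {
  if (any(diffusivity <= 0) || any(temperature <= 0) || any(viscosity <= 0))
    stop("all arguments must be strictly positive")
  .kB * temperature / (6 * pi * viscosity * diffusivity)
}

#' @rdname stokes_einstein_rh
#' @export
stokes_einstein_d <- function(rh, temperature, viscosity) {
  if (any(rh <= 0) || any(temperature <= 0) || any(viscosity <= 0))
    stop("all arguments must be strictly positive")
  .kB * temperature / (6 * pi * viscosity * rh)
}

#' Taylor-Aris peak width
#'
#' Temporal standard deviation of the Taylorgram for a species of
#' hydrodynamic radius `rh_m` detected at retention time `retention_time`:
#' `sigma_t^2 = r^2 t_R / (24 D)` with `D` from the Stokes-Einstein
#' relation at the method's temperature and buffer viscosity.
#'
#' @param rh_m Hydrodynamic radius in m.
#' @param retention_time Retention time in s.
#' @param method A [fida_method()].
#' @return Gaussian SD in seconds.
#' @export
taylor_sigma <- function(rh_m, retention_time, method) {
  if (any(rh_m <= 0) || any(retention_time <= 0))
    stop("rh and retention time must be strictly positive")
  D <- stokes_einstein_d(rh_m, method$temperature, method$buffer_viscosity)
  sqrt(method$capillary_radius^2 * retention_time / (24 * D))
}

#' Taylor-regime validity
#'
#' Dimensionless residence number `tau = D t_R / r^2`. The Taylor-Aris
#' description requires radial diffusion to average the solute over the
#' parabolic profile; the usual heuristic is `tau >= 1.4`.
#'
#' @inheritParams taylor_sigma
#' @param tau_min Validity threshold (default 1.4).
#' @return List with `tau` and logical `valid`.
#' @export
taylor_validity <- function(rh_m, retention_time, method, tau_min = .TAU_MIN) {
  if (any(rh_m <= 0) || any(retention_time <= 0))
    stop("rh and retention time must be strictly positive")
  D <- stokes_einstein_d(rh_m, method$temperature, method$buffer_viscosity)
  tau <- D * retention_time / method$capillary_radius^2
  list(tau = tau, valid = tau >= tau_min)
}

#' Gaussian Taylorgram model
#'
#' `s(t) = baseline + amplitude * exp(-(t - t_R)^2 / (2 sigma_t^2))`,
#' vectorized over `time`.
#'
#' @param time Time points in s.
#' @param amplitude Peak amplitude above baseline (fluorescence units).
#' @param retention_time Peak center in s.
#' @param sigma_t Gaussian SD in s (> 0).
#' @param baseline Constant baseline (fluorescence units).
#' @return Signal values.
#' @export
gaussian_model <- function(time, amplitude, retention_time, sigma_t,
                           baseline = 0) {
  if (sigma_t <= 0) stop("sigma_t must be strictly positive")
  baseline + amplitude * exp(-(time - retention_time)^2 / (2 * sigma_t^2))
}

#' Injection-plug broadening
#'
#' Temporal SD contributed by the finite indicator plug: the plug is
#' loaded for `duration_s` at `pressure_mbar`, giving a slug of length
#' `v_inject * duration`; at the detector the corresponding top-hat of
#' temporal width `w = slug / v_mobilize` contributes `w / sqrt(12)`,
#' added to the Taylor width in quadrature.
#'
#' @param method A [fida_method()]. The injection and mobilization steps
#'   are read from the method's program (labels `indicator_inject` and
#'   `mobilize`).
#' @return Plug SD `sigma0` in seconds.
#' @export
plug_sigma0 <- function(method) {
  st <- method$steps
  inj <- st[st$label == "indicator_inject", ]
  mob <- st[st$label == "mobilize", ]
  if (nrow(inj) != 1 || nrow(mob) != 1)
    stop("method program must contain one 'indicator_inject' and one 'mobilize' step")
  slug <- .mean_velocity(method, inj$pressure_mbar) * inj$duration_s
  w <- slug / .mean_velocity(method, mob$pressure_mbar)
  w / sqrt(12)
}
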