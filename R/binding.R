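#' Equilibrium fraction bound (1:1 model with depletion)
#'
#' Exact solution of the 1:1 mass-action equilibrium including indicator
#' depletion: with total indicator `I`, total analyte `B` and
#' `S = I + B + kd`, the fraction of indicator in complex is
#' `f_b = (S - sqrt(S^2 - 4 I B)) / (2 I)`. For `I << kd` this reduces
#' to the simple hyperbola `B / (B + kd)`, which is used as the exact
#' trace limit when `I` is zero or negligibly small.
#'
#' @param kd Dissociation constant in M (> 0).
#' @param indicator_conc Total indicator concentration `I` in M (>= 0).
#' @param analyte_conc Total analyte concentration `B` in M (>= 0);
#'   vectorized.
#' @return Fraction bound in `[0, 1]`.
#' @examples
#' fraction_bound(2.76e-6, 50e-9, 10e-6)  # ~0.78
#' @export
fraction_bound <- function(kd, indicator_conc, analyte_conc) {
  if (any(kd <= 0)) stop("kd must be strictly positive")
  if (any(indicator_conc < 0) || any(analyte_conc < 0))
    stop("concentrations must be non-negative")
  I <- indicator_conc; B <- analyte_conc
  if (I < 1e-15 * kd)                      # trace limit, avoids 0/0
    return(B / (B + kd))
  S <- I + B + kd
  disc <- pmax(S^2 - 4 * I * B, 0)
  ## conjugate form of (S - sqrt(disc)) / (2 I): no cancellation when
  ## 4 I B << S^2 (the trace regime)
  fb <- 2 * B / (S + sqrt(disc))
  pmin(pmax(fb, 0), 1)
}

#' Apparent hydrodynamic radius under fast exchange
#'
#' Population-weighted average of the free and complexed indicator. The
#' default (`mode = "rh"`) averages the radii arithmetically,
#' `rh = rh_free + f_b (rh_complex - rh_free)`; `mode = "d"` averages
#' the diffusivities instead (harmonic in radius), the alternative
#' convention discussed in the binding-model literature.
#'
#' @param fraction_bound Fraction bound in `[0, 1]`; vectorized.
#' @param rh_free,rh_complex Radii in nm with `rh_complex >= rh_free`.
#' @param mode `"rh"` (default) or `"d"`.
#' @return Apparent radius in nm.
#' @export
apparent_rh <- function(fraction_bound, rh_free, rh_complex, mode = c("rh", "d")) {
  mode <- match.arg(mode)
  if (any(fraction_bound < -1e-12) || any(fraction_bound > 1 + 1e-12))
    stop("fraction_bound must be in [0, 1]")
  if (rh_complex < rh_free) stop("rh_complex must be >= rh_free")
  fb <- pmin(pmax(fraction_bound, 0), 1)
  if (mode == "rh")
    rh_free + fb * (rh_complex - rh_free)
  else
    1 / (fb / rh_complex + (1 - fb) / rh_free)
}

## log-scale KD search bounds (M)
.KD_LO <- 1e-12
.KD_HI <- 1e-2

#' Fit a 1:1 binding isotherm
#'
#' Weighted nonlinear least squares of the depletion-corrected 1:1 model
#' `rh(B) = apparent_rh(fraction_bound(kd, I, B), rh_free, rh_complex)`
#' over a titration table. `kd` is searched on a log scale within
#' `[1e-12, 1e-2]` M; weights are `1 / sd^2` when replicate SDs are
#' present. `rh_free` can be fixed to the separately measured
#' indicator-alone radius (recommended) or co-fitted.
#'
#' @param points data.frame with columns `analyte_conc_M`, `rh_nm`, and
#'   optionally `rh_sd_nm`, `n` (as produced by [simulate_titration()]).
#' @param indicator_conc Indicator concentration `I` in M.
#' @param fix_rh_free Radius (nm) to fix `rh_free` at, or `NULL` to fit it.
#' @param mode Apparent-radius averaging mode, see [apparent_rh()].
#' @return Object of class `fida_kd`: `kd` (M), `kd_se`, `rh_free`,
#'   `rh_complex` (nm) with SEs, `residuals`, `converged`, `flags`.
#' @examples
#' tt <- simulate_titration(2.76e-6, 1.15, 2.40, 50e-9,
#'                          0.1e-6 * 2^(0:11))
#' fit_kd(tt, indicator_conc = 50e-9, fix_rh_free = 1.15)
#' @export
fit_kd <- function(points, indicator_conc, fix_rh_free = NULL,
                   mode = c("rh", "d")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(points),
            all(c("analyte_conc_M", "rh_nm") %in% names(points)))
  B <- points$analyte_conc_M; y <- points$rh_nm
  if (any(B < 0)) stop("analyte concentrations must be >= 0")
  nz <- B[B > 0]
  if (length(unique(B)) < 4 ||
      (length(nz) && max(nz) / min(nz) < 10))
    warning("fewer than 4 distinct concentrations or ladder spans less ",
            "than one order of magnitude; kd may be poorly constrained")
  w <- rep(1, length(y))
  if (!is.null(points$rh_sd_nm) && all(is.finite(points$rh_sd_nm)) &&
      all(points$rh_sd_nm > 0))
    w <- 1 / points$rh_sd_nm^2

  flags <- character(0)
  rng <- max(y) - min(y)
  if (rng <= max(1e-9, 2 * stats::median(
        if (all(w == 1)) 0 else points$rh_sd_nm))) {
    return(structure(list(converged = FALSE, flags = "NO_SIGNAL",
                          message = "no concentration dependence of rh",
                          kd = NA_real_, points = points),
                     class = "fida_kd"))
  }

  ## deterministic starts: end members and half-rise concentration
  rf0 <- if (is.null(fix_rh_free)) y[which.min(B)] else fix_rh_free
  rc0 <- max(y)
  half <- rf0 + 0.5 * (rc0 - rf0)
  kd0 <- B[which.min(abs(y - half))]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(nz)
  start <- list(lkd = log10(kd0), rc = rc0)
  lower <- c(lkd = log10(.KD_LO), rc = rf0)
  upper <- c(lkd = log10(.KD_HI), rc = Inf)
  if (is.null(fix_rh_free)) {
    start$rf <- rf0
    lower <- c(lower, rf = 0); upper <- c(upper, rf = Inf)
  }

  model <- function(lkd, rc, rf) {
    fb <- fraction_bound(10^lkd, indicator_conc, B)
    apparent_rh(fb, rf, max(rc, rf), mode = mode)
  }
  fit <- tryCatch({
    if (is.null(fix_rh_free))
      minpack.lm::nlsLM(y ~ model(lkd, rc, rf), start = start,
                        weights = w, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ model(lkd, rc, fix_rh_free), start = start,
                        weights = w, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(converged = FALSE, flags = "FIT_FAILED",
                          message = conditionMessage(fit), kd = NA_real_,
                          points = points), class = "fida_kd"))

  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  kd <- 10^cf[["lkd"]]
  if (cf[["lkd"]] <= log10(.KD_LO) + 1e-6 ||
      cf[["lkd"]] >= log10(.KD_HI) - 1e-6)
    flags <- c(flags, "KD_AT_BOUND")
  rf <- if (is.null(fix_rh_free)) cf[["rf"]] else fix_rh_free

  structure(list(converged = TRUE, kd = kd,
                 kd_se = kd * log(10) * unname(se["lkd"]),
                 rh_free = rf,
                 rh_free_se = if (is.null(fix_rh_free))
                   unname(se["rf"]) else NA_real_,
                 rh_free_fixed = !is.null(fix_rh_free),
                 rh_complex = cf[["rc"]],
                 rh_complex_se = unname(se["rc"]),
                 indicator_conc = indicator_conc, mode = mode,
                 residuals = stats::resid(fit),
                 rss = stats::deviance(fit),   # weighted when weights given
                 flags = flags, fit = fit, points = points),
            class = "fida_kd")
}

#' @export
print.fida_kd <- function(x, ...) {
  if (!x$converged) {
    cat("1:1 binding fit FAILED:", x$message,
        sprintf("[%s]\n", paste(x$flags, collapse = ",")))
    return(invisible(x))
  }
  unit <- if (x$kd < 1e-6) c(1e9, "nM") else c(1e6, "uM")
  cat(sprintf("1:1 binding isotherm fit: KD = %.3g %s (SE %.2g)\n",
              x$kd * as.numeric(unit[1]), unit[2],
              x$kd_se * as.numeric(unit[1])))
  cat(sprintf("  rh_free = %.3f nm%s, rh_complex = %.3f nm (SE %.2g)\n",
              x$rh_free, if (x$rh_free_fixed) " (fixed)" else "",
              x$rh_complex, x$rh_complex_se))
  cat(sprintf("  indicator %.3g nM, %d points, RSS %.4g\n",
              x$indicator_conc * 1e9, nrow(x$points), x$rss))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.fida_kd <- function(object, ...) {
  c(kd_M = object$kd, rh_free_nm = object$rh_free,
    rh_complex_nm = object$rh_complex)
}

#' @export
summary.fida_kd <- function(object, ...) {
  print(object)
  if (object$converged && !is.null(object$fit)) print(summary(object$fit))
  invisible(object)
}

#' Predicted binding curve
#'
#' Evaluates the fitted 1:1 isotherm on an analyte grid (for plotting or
#' reporting). With `analyte_conc = NULL` a log-spaced grid spanning the
#' fitted points is used.
#'
#' @param object A converged [fit_kd()] result.
#' @param analyte_conc Analyte concentrations in M, or `NULL`.
#' @param ... Unused.
#' @return data.frame with `analyte_conc_M` and `rh_nm`.
#' @export
predict.fida_kd <- function(object, analyte_conc = NULL, ...) {
  if (!object$converged) stop("cannot predict from a failed fit")
  if (is.null(analyte_conc)) {
    nz <- object$points$analyte_conc_M[object$points$analyte_conc_M > 0]
    analyte_conc <- 10^seq(log10(min(nz)) - 0.5, log10(max(nz)) + 0.5,
                           length.out = 100)
  }
  fb <- fraction_bound(object$kd, object$indicator_conc, analyte_conc)
  data.frame(analyte_conc_M = analyte_conc,
             rh_nm = apparent_rh(fb, object$rh_free, object$rh_complex,
                                 mode = object$mode))
}

#' @export
residuals.fida_kd <- function(object, ...) {
  if (!object$converged) stop("no residuals: fit failed")
  object$residuals
}

#' @export
plot.fida_kd <- function(x, ...) {
  p <- x$points
  graphics::plot(p$analyte_conc_M * 1e6, p$rh_nm, log = "x",
                 xlab = "analyte (uM)", ylab = "apparent rh (nm)", ...)
  if (!is.null(p$rh_sd_nm))
    graphics::arrows(p$analyte_conc_M * 1e6, p$rh_nm - p$rh_sd_nm,
                     p$analyte_conc_M * 1e6, p$rh_nm + p$rh_sd_nm,
                     angle = 90, code = 3, length = 0.02)
  if (x$converged) {
    cv <- predict(x)
    graphics::lines(cv$analyte_conc_M * 1e6, cv$rh_nm, col = 2)
  }
  invisible(x)
}
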