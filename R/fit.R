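#' Dispersion-fit options
#'
#' @param taylorgram_fraction Fraction of the peak used for fitting, in
#'   `(0, 1]`. The default 0.75 keeps the points whose baseline-corrected
#'   signal exceeds 25 percent of the peak height (the top 75 percent of
#'   the peak).
#' @param locked_rh_second_species Radius (nm) of a second species whose
#'   width is locked rather than fitted (e.g. 0.6 nm for free label), or
#'   `NULL` (default) for a single-species fit.
#' @param subtract_plug Subtract the injection-plug variance `sigma0^2`
#'   in quadrature before inverting to a diffusivity (default TRUE).
#' @param fit_baseline Re-fit a residual baseline inside the peak window
#'   (default FALSE). The window only covers the top of the peak, where
#'   baseline, amplitude and width are nearly collinear; the default
#'   instead fixes the baseline at the robust flank estimate, which is
#'   both better-posed and how the flanks are actually informative.
#' @param max_iterations,convergence_tol Optimizer controls.
#' @param snr_min Signal-to-noise floor below which `LOW_SNR` is flagged
#'   (default 50).
#' @param mismatch_threshold Baseline mismatch score above which
#'   `BASELINE_MISMATCH` is flagged (default 0.05).
#' @return Object of class `fit_options`.
#' @export
fit_options <- function(taylorgram_fraction = 0.75,
                        locked_rh_second_species = NULL,
                        subtract_plug = TRUE,
                        fit_baseline = FALSE,
                        max_iterations = 200,
                        convergence_tol = 1e-8,
                        snr_min = 50,
                        mismatch_threshold = 0.05) {
  stopifnot(taylorgram_fraction > 0, taylorgram_fraction <= 1,
            convergence_tol > 0, max_iterations >= 1)
  structure(list(taylorgram_fraction = taylorgram_fraction,
                 locked_rh_second_species = locked_rh_second_species,
                 subtract_plug = subtract_plug,
                 fit_baseline = fit_baseline,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 snr_min = snr_min,
                 mismatch_threshold = mismatch_threshold),
            class = "fit_options")
}

#' Baseline level and mismatch score
#'
#' Robust baseline from the pre- and post-peak flanks (median of the
#' first and last 10 percent of samples). The mismatch score
#' `|pre - post| / peak height` detects a buffer/baseline mismatch (the
#' double-peak or step artifact seen in concentrated lysates).
#'
#' @param trace A [taylorgram()].
#' @param flank_frac Fraction of samples in each flank (default 0.1).
#' @return List with `baseline`, `mismatch_score`, `pre`, `post`,
#'   `noise_sd` (1.4826 x MAD of the flanks).
#' @export
estimate_baseline <- function(trace, flank_frac = 0.1) {
  stopifnot(inherits(trace, "taylorgram"))
  n <- length(trace$signal)
  k <- floor(n * flank_frac)
  if (k < 3) stop("trace too short for flank windows")
  pre <- trace$signal[seq_len(k)]
  post <- trace$signal[seq.int(n - k + 1L, n)]
  baseline <- stats::median(c(pre, post))
  peak <- max(trace$signal) - baseline
  score <- if (peak > 0)
    abs(stats::median(pre) - stats::median(post)) / peak else 0
  noise <- stats::median(c(abs(pre - stats::median(pre)),
                           abs(post - stats::median(post)))) * 1.4826
  list(baseline = baseline, mismatch_score = score,
       pre = stats::median(pre), post = stats::median(post),
       noise_sd = noise)
}

## failed-fit result carrying diagnostics instead of silent numbers
.fit_failure <- function(message, trace, options) {
  structure(list(converged = FALSE, message = message, rh = NA_real_,
                 flags = "FIT_FAILED", trace = trace, options = options),
            class = "fida_fit")
}

#' Fit a Taylorgram
#'
#' Extracts the hydrodynamic radius from a Taylorgram by nonlinear
#' least-squares of a Gaussian restricted to the top
#' `taylorgram_fraction` of the peak, then inverts the Taylor-Aris
#' relation `D = r^2 t_R / (24 (sigma_t^2 - sigma0^2))` and applies
#' Stokes-Einstein at the method's temperature and buffer viscosity.
#' With `locked_rh_second_species` set in `options`, a sum of two
#' Gaussians sharing the retention time is fitted, the second species'
#' width computed from the locked radius (free label correction); the
#' main species' radius and amplitude fraction are returned.
#'
#' Quality flags: `LOW_SNR` (S/N below the floor), `BASELINE_MISMATCH`
#' (flank step above threshold), `TAYLOR_INVALID` (residence number
#' below 1.4), `DEGENERATE_LOCKED` (main radius within 25 percent of the
#' locked radius).
#'
#' @param trace A [taylorgram()].
#' @param method A [fida_method()].
#' @param options A [fit_options()].
#' @return Object of class `fida_fit` with components `rh` (nm),
#'   `retention_time`, `sigma_t`, `amplitude`, `baseline`, `diffusivity`
#'   (m^2/s), `snr`, `flags`, `mole_fraction_main` (two-species fits),
#'   `converged`, and the underlying `nls` fit.
#' @examples
#' tg <- simulate_taylorgram(fida_method(), species_state(1.15))
#' fit_taylorgram(tg, fida_method())
#' @export
fit_taylorgram <- function(trace, method = fida_method(),
                           options = fit_options()) {
  stopifnot(inherits(trace, "taylorgram"), inherits(method, "fida_method"),
            inherits(options, "fit_options"))
  bl <- estimate_baseline(trace)
  t <- trace$time; y <- trace$signal
  height <- max(y) - bl$baseline
  if (height <= 0) return(.fit_failure("no peak above baseline", trace, options))

  ## fit window: top `fraction` of the baseline-corrected peak
  thresh <- bl$baseline + (1 - options$taylorgram_fraction) * height
  ipk <- which.max(y)
  lo <- ipk; while (lo > 1 && y[lo - 1] >= thresh) lo <- lo - 1
  hi <- ipk; while (hi < length(y) && y[hi + 1] >= thresh) hi <- hi + 1
  win <- lo:hi
  if (length(win) < 8)
    return(.fit_failure(sprintf("only %d points above the fit threshold",
                                length(win)), trace, options))
  tw <- t[win]; yw <- y[win]

  ## deterministic starts: argmax, FWHM/2.355, peak height
  half <- bl$baseline + height / 2
  l2 <- ipk; while (l2 > 1 && y[l2 - 1] >= half) l2 <- l2 - 1
  h2 <- ipk; while (h2 < length(y) && y[h2 + 1] >= half) h2 <- h2 + 1
  sig0_guess <- max((t[h2] - t[l2]) / 2.355, diff(range(tw)) / 10)

  ## baseline-corrected signal; the residual in-window baseline is only
  ## co-fitted on request (see fit_options)
  yc <- yw - bl$baseline
  ctrl <- minpack.lm::nls.lm.control(maxiter = options$max_iterations,
                                     ftol = options$convergence_tol)
  locked <- options$locked_rh_second_species
  s0 <- if (options$subtract_plug) plug_sigma0(method) else 0
  fb <- isTRUE(options$fit_baseline)
  fit <- tryCatch({
    if (is.null(locked)) {
      if (fb)
        minpack.lm::nlsLM(yc ~ b + A * exp(-(tw - tr)^2 / (2 * sg^2)),
                          start = list(A = height, tr = t[ipk],
                                       sg = sig0_guess, b = 0),
                          control = ctrl,
                          lower = c(A = 0, tr = min(tw), sg = 1e-6, b = -Inf))
      else
        minpack.lm::nlsLM(yc ~ A * exp(-(tw - tr)^2 / (2 * sg^2)),
                          start = list(A = height, tr = t[ipk],
                                       sg = sig0_guess),
                          control = ctrl,
                          lower = c(A = 0, tr = min(tw), sg = 1e-6))
    } else {
      sigL <- function(tr)
        sqrt(taylor_sigma(locked * 1e-9, tr, method)^2 + s0^2)
      minpack.lm::nlsLM(
        yc ~ A * exp(-(tw - tr)^2 / (2 * sg^2)) +
          A2 * exp(-(tw - tr)^2 / (2 * sigL(tr)^2)),
        start = list(A = 0.8 * height, A2 = 0.2 * height,
                     tr = t[ipk], sg = sig0_guess),
        control = ctrl,
        lower = c(A = 0, A2 = 0, tr = min(tw), sg = 1e-6))
    }
  }, error = function(e) e)
  if (inherits(fit, "error"))
    return(.fit_failure(conditionMessage(fit), trace, options))

  cf <- stats::coef(fit)
  base_out <- bl$baseline + if (fb) cf[["b"]] else 0
  var_taylor <- cf[["sg"]]^2 - s0^2
  if (var_taylor <= 0)
    return(.fit_failure(
      "fitted peak narrower than the injection plug (sigma_t^2 <= sigma0^2)",
      trace, options))
  D <- method$capillary_radius^2 * cf[["tr"]] / (24 * var_taylor)
  rh_m <- stokes_einstein_rh(D, method$temperature, method$buffer_viscosity)

  snr <- if (bl$noise_sd > 0) cf[["A"]] / bl$noise_sd else Inf
  flags <- character(0)
  if (snr < options$snr_min) flags <- c(flags, "LOW_SNR")
  if (bl$mismatch_score > options$mismatch_threshold)
    flags <- c(flags, "BASELINE_MISMATCH")
  tv <- taylor_validity(rh_m, cf[["tr"]], method)
  if (!tv$valid) flags <- c(flags, "TAYLOR_INVALID")

  out <- list(converged = TRUE, rh = rh_m * 1e9, rh_sd = NA_real_,
              retention_time = cf[["tr"]], sigma_t = cf[["sg"]],
              amplitude = cf[["A"]], baseline = base_out,
              diffusivity = D, snr = snr, tau = tv$tau,
              mismatch_score = bl$mismatch_score,
              viscosity_factor = NA_real_, flags = flags,
              fit = fit, trace = trace, method = method, options = options)
  if (!is.null(locked)) {
    out$locked_rh <- locked
    out$locked_amplitude <- cf[["A2"]]
    out$mole_fraction_main <- cf[["A"]] / (cf[["A"]] + cf[["A2"]])
    if (abs(out$rh - locked) / locked < 0.25)
      out$flags <- c(out$flags, "DEGENERATE_LOCKED")
  }
  structure(out, class = "fida_fit")
}

#' @export
print.fida_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Taylorgram fit FAILED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("Taylorgram dispersion fit: rh = %.4g nm", x$rh))
  if (!is.na(x$viscosity_factor))
    cat(sprintf(" (viscosity-corrected, f = %.3f)", x$viscosity_factor))
  cat("\n")
  cat(sprintf("  t_R = %.2f s, sigma_t = %.3f s, amplitude = %.3g, baseline = %.3g\n",
              x$retention_time, x$sigma_t, x$amplitude, x$baseline))
  cat(sprintf("  D = %.4g m^2/s, S/N = %.1f, tau = %.2f\n",
              x$diffusivity, x$snr, x$tau))
  if (!is.null(x$mole_fraction_main))
    cat(sprintf("  two-species fit: locked %.2f nm, main fraction %.3f\n",
                x$locked_rh, x$mole_fraction_main))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.fida_fit <- function(object, ...) {
  c(rh_nm = object$rh, retention_time_s = object$retention_time,
    sigma_t_s = object$sigma_t, amplitude = object$amplitude,
    baseline = object$baseline)
}

#' @export
predict.fida_fit <- function(object, time = NULL, ...) {
  if (!object$converged) stop("cannot predict from a failed fit")
  time <- time %||% object$trace$time
  y <- gaussian_model(time, object$amplitude, object$retention_time,
                      object$sigma_t, object$baseline)
  if (!is.null(object$locked_rh)) {
    s0 <- if (object$options$subtract_plug) plug_sigma0(object$method) else 0
    sL <- sqrt(taylor_sigma(object$locked_rh * 1e-9, object$retention_time,
                            object$method)^2 + s0^2)
    y <- y + gaussian_model(time, object$locked_amplitude,
                            object$retention_time, sL, 0)
  }
  y
}

#' @export
residuals.fida_fit <- function(object, ...) {
  if (!object$converged) stop("no residuals: fit failed")
  object$trace$signal - predict(object)
}

#' @export
plot.fida_fit <- function(x, ...) {
  plot(x$trace, ...)
  if (x$converged)
    graphics::lines(x$trace$time, predict(x), col = 2, lwd = 2)
  invisible(x)
}

#' Viscosity normalization from retention time
#'
#' Elevated sample viscosity slows both the flow and the diffusion, so
#' an uncorrected fit reports a radius inflated by the sample/buffer
#' viscosity ratio. That ratio is estimated as `f = t_R / reference_tr`
#' from the retention time of the same indicator in clean buffer, and
#' the corrected radius is `rh / f`.
#'
#' @param fit A converged [fit_taylorgram()] result.
#' @param reference_tr Buffer retention time of the indicator in s.
#' @return The fit with corrected `rh`, recorded `viscosity_factor`, and
#'   the `VISCOSITY_CORRECTED` flag.
#' @export
viscosity_normalize <- function(fit, reference_tr) {
  stopifnot(inherits(fit, "fida_fit"))
  if (!fit$converged) stop("cannot normalize a failed fit")
  if (reference_tr <= 0) stop("reference_tr must be positive")
  f <- fit$retention_time / reference_tr
  if (f < 0.8)
    warning("sample retention ", signif(f, 3),
            "x buffer: faster than buffer is physically suspicious")
  fit$rh <- fit$rh / f
  fit$diffusivity <- fit$diffusivity * f
  fit$viscosity_factor <- f
  fit$flags <- union(fit$flags, "VISCOSITY_CORRECTED")
  fit
}

#' Replicate summary
#'
#' Arithmetic mean and sample SD (denominator n-1) of the (corrected)
#' radii of replicate fits; flags are propagated as the union. With a
#' single replicate the SD is reported as `NA`, not 0.
#'
#' @param fits List of converged `fida_fit` objects.
#' @return List with `rh_mean`, `rh_sd`, `n`, `flags`.
#' @export
replicate_summary <- function(fits) {
  if (!length(fits)) stop("empty fit list")
  if (inherits(fits, "fida_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(ok)) stop(sum(!ok), " of ", length(fits), " fits failed")
  rh <- vapply(fits, `[[`, numeric(1), "rh")
  list(rh_mean = mean(rh),
       rh_sd = if (length(rh) > 1) stats::sd(rh) else NA_real_,
       n = length(rh),
       flags = Reduce(union, lapply(fits, `[[`, "flags")))
}

#' Fit every trace of a simulated campaign
#'
#' Convenience batch driver: fits all traces of a [simulate_campaign()]
#' result, estimates the buffer reference retention time from the
#' buffer-only replicates, viscosity-normalizes every lysate fit, and
#' summarizes replicates per sample group.
#'
#' @param campaign Result of [simulate_campaign()].
#' @param method A [fida_method()].
#' @param options A [fit_options()].
#' @return List with `fits` (per-trace table: sample_id, role, binder_id,
#'   dilution_factor, replicate, rh_nm, tr_s, snr, viscosity_factor,
#'   flags), `summaries` (per group: role, binder_id, dilution_factor,
#'   rh_mean, rh_sd, n), `reference_tr`, and `replicate_rh` (long table
#'   of corrected replicate radii for statistical hit calling).
#' @export
fit_campaign <- function(campaign, method = fida_method(),
                         options = fit_options()) {
  sheet <- campaign$sheet
  fits <- vector("list", nrow(sheet))
  for (i in seq_len(nrow(sheet)))
    fits[[i]] <- fit_taylorgram(campaign$traces[[sheet$sample_id[i]]],
                                method, options)
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!all(conv))
    stop("fit failed for sample(s): ",
         paste(sheet$sample_id[!conv], collapse = ", "))

  ref_tr <- mean(vapply(fits[sheet$role == "buffer"], `[[`,
                        numeric(1), "retention_time"))
  for (i in which(sheet$role != "buffer"))
    fits[[i]] <- viscosity_normalize(fits[[i]], ref_tr)

  tab <- cbind(sheet, data.frame(
    rh_nm = vapply(fits, `[[`, numeric(1), "rh"),
    tr_s = vapply(fits, `[[`, numeric(1), "retention_time"),
    snr = vapply(fits, `[[`, numeric(1), "snr"),
    viscosity_factor = vapply(fits, `[[`, numeric(1), "viscosity_factor"),
    flags = vapply(fits, function(f)
      paste(f$flags, collapse = ";"), character(1))))

  key <- paste(sheet$role, ifelse(is.na(sheet$binder_id), "-", sheet$binder_id),
               sheet$dilution_factor)
  summaries <- do.call(rbind, lapply(split(seq_len(nrow(tab)), key),
    function(ix) {
      s <- replicate_summary(fits[ix])
      data.frame(role = sheet$role[ix[1]], binder_id = sheet$binder_id[ix[1]],
                 dilution_factor = sheet$dilution_factor[ix[1]],
                 rh_mean = s$rh_mean, rh_sd = s$rh_sd, n = s$n,
                 flags = paste(s$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  rownames(summaries) <- NULL
  list(fits = tab, summaries = summaries, reference_tr = ref_tr,
       replicate_rh = tab[tab$role != "buffer",
                          c("role", "binder_id", "dilution_factor",
                            "replicate", "rh_nm")])
}
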