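#' Threshold hit calling
#'
#' A sample is a hit when its mean radius exceeds the reference by at
#' least `theta` (default 10 percent): `rh_mean >= (1 + theta) *
#' reference_rh`. The reference is the indicator-alone radius for
#' purified screens and the preculture radius for lysate screens; the
#' caller supplies it explicitly.
#'
#' @param summaries data.frame with at least `binder_id` and `rh_mean`
#'   (nm); `rh_sd`, `n`, `dilution_factor`, `flags` are carried through
#'   when present.
#' @param reference_rh Reference radius in nm (> 0).
#' @param theta Relative cutoff (default 0.10).
#' @return The input with `reference_rh`, `pct_change`
#'   (`100 (rh_mean/reference - 1)`), and logical `hit_threshold` added.
#' @export
call_hits_threshold <- function(summaries, reference_rh, theta = 0.10) {
  stopifnot(is.data.frame(summaries), "rh_mean" %in% names(summaries))
  if (reference_rh <= 0) stop("reference_rh must be positive")
  out <- summaries
  out$reference_rh <- reference_rh
  out$pct_change <- 100 * (out$rh_mean / reference_rh - 1)
  out$hit_threshold <- out$rh_mean >= (1 + theta) * reference_rh
  out
}

## P(max_j T_j <= t) for the many-to-one comparison: (T_1..T_m) is
## multivariate t with the product correlation structure
## rho_ij = lam_i lam_j, lam_i = sqrt(n_i/(n_i+n0)). Writing
## T_i = (lam_i Z0 + sqrt(1-lam_i^2) Z_i) / U with U = chi_df/sqrt(df)
## reduces the m-dimensional probability to a fast deterministic double
## quadrature over (Z0, U) - the classic Dunnett computation.
.dunnett_maxt_cdf <- function(t, lam, df, n_nodes = 64) {
  zg <- pracma::gaussLegendre(n_nodes, -8, 8)
  ug <- pracma::gaussLegendre(n_nodes, 1e-4, 4)
  wz <- zg$w * stats::dnorm(zg$x)
  wu <- ug$w * 2 * ug$x * df * stats::dchisq(ug$x^2 * df, df)
  s <- sqrt(1 - lam^2)
  tu <- outer(rep(1, n_nodes), ug$x)           # u over columns
  z0 <- outer(zg$x, rep(1, n_nodes))           # z0 over rows
  vapply(t, function(ti) {
    lp <- 0
    for (i in seq_along(lam))
      lp <- lp + stats::pnorm((ti * tu - lam[i] * z0) / s[i], log.p = TRUE)
    sum(wz * (exp(lp) %*% wu))
  }, numeric(1))
}

## One-sided (greater) Dunnett many-to-one adjusted p-values from a
## one-way layout: t_i = (ybar_i - ybar_0)/sqrt(s2 (1/n_i + 1/n_0)) with
## the pooled ANOVA variance (df = N - k); p_adj(i) = 1 - P(max T <= t_i).
.dunnett_p <- function(values, groups, control) {
  groups <- as.character(groups)
  ids <- setdiff(unique(groups), control)
  ybar <- tapply(values, groups, mean)
  nn <- tapply(values, groups, length)
  ss <- tapply(values, groups, function(v) sum((v - mean(v))^2))
  df <- sum(nn) - length(nn)
  s2 <- sum(ss) / df
  n0 <- nn[[control]]
  ni <- nn[ids]
  tstat <- (ybar[ids] - ybar[[control]]) / sqrt(s2 * (1 / ni + 1 / n0))
  lam <- sqrt(ni / (ni + n0))
  p <- 1 - .dunnett_maxt_cdf(tstat, lam, df)
  stats::setNames(pmin(pmax(p, 0), 1), ids)
}

#' Dunnett many-to-one hit calling
#'
#' One-way ANOVA followed by Dunnett's many-to-one comparison of every
#' binder group against the control group, one-sided (greater), because
#' binding can only increase the radius. A group is a hit when its
#' adjusted p-value falls below `alpha`.
#'
#' @param replicate_rh data.frame with columns `binder_id` and `rh_nm`
#'   (one row per replicate), including the control group's replicates.
#' @param control Label of the control group (default `"PC"`).
#' @param alpha Family-wise significance level (default 0.05).
#' @return data.frame with one row per non-control group: `binder_id`,
#'   `rh_mean`, `rh_sd`, `n`, `p_adjusted`, `hit_statistical`.
#' @export
call_hits_dunnett <- function(replicate_rh, control = "PC", alpha = 0.05) {
  stopifnot(is.data.frame(replicate_rh),
            all(c("binder_id", "rh_nm") %in% names(replicate_rh)))
  if (!control %in% replicate_rh$binder_id)
    stop("control group '", control, "' not present in the data")
  cnt <- table(replicate_rh$binder_id)
  small <- names(cnt)[cnt < 2]
  if (length(small))
    stop("group(s) with fewer than 2 replicates: ",
         paste(small, collapse = ", "))
  p <- .dunnett_p(replicate_rh$rh_nm, replicate_rh$binder_id, control)
  ids <- names(p)
  agg <- function(id, f) f(replicate_rh$rh_nm[replicate_rh$binder_id == id])
  data.frame(binder_id = ids,
             rh_mean = vapply(ids, agg, numeric(1), f = mean),
             rh_sd = vapply(ids, agg, numeric(1), f = stats::sd),
             n = as.integer(cnt[ids]),
             p_adjusted = unname(p),
             hit_statistical = unname(p) < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dilution-series false positive / negative report
#'
#' Scores a fitted campaign against its ground truth, per dilution and
#' per rule: the fixed-threshold rule (relative to the preculture at the
#' same dilution) and the one-sided Dunnett rule (against the preculture
#' replicates). FP = non-binders called hits, FN = true binders missed.
#'
#' @param fitted Result of [fit_campaign()].
#' @param truth The [campaign_truth()] used to simulate the campaign.
#' @param theta Threshold for the fixed rule (default 0.10).
#' @param alpha Level for the Dunnett rule (default 0.05).
#' @return List with `by_dilution` (data.frame: dilution_factor, rule,
#'   fp, fn, n_binders, n_true, fp_rate, fn_rate) and `calls` (per
#'   binder x dilution hit calls under both rules).
#' @export
dilution_series_report <- function(fitted, truth, theta = 0.10,
                                   alpha = 0.05) {
  stopifnot(inherits(truth, "campaign_truth"))
  sm <- fitted$summaries
  rep_rh <- fitted$replicate_rh
  is_true <- stats::setNames(!is.na(truth$binders$true_kd_M),
                             truth$binders$binder_id)
  if (!all(sm$binder_id[sm$role == "binder"] %in% names(is_true)))
    stop("campaign summaries contain binder ids absent from the truth record")

  rows <- list(); calls <- list()
  for (dil in sort(unique(sm$dilution_factor[sm$role == "binder"]))) {
    pc <- sm[sm$role == "preculture" & sm$dilution_factor == dil, ]
    if (nrow(pc) != 1) stop("missing preculture at dilution ", dil)
    bs <- sm[sm$role == "binder" & sm$dilution_factor == dil, ]
    thr <- call_hits_threshold(bs, reference_rh = pc$rh_mean, theta = theta)

    rr <- rep_rh[rep_rh$dilution_factor == dil, ]
    rr$binder_id[rr$role == "preculture"] <- "PC"
    dn <- call_hits_dunnett(rr[, c("binder_id", "rh_nm")],
                            control = "PC", alpha = alpha)
    dn <- dn[match(thr$binder_id, dn$binder_id), ]

    truthv <- is_true[thr$binder_id]
    for (rule in c("threshold", "dunnett")) {
      hit <- if (rule == "threshold") thr$hit_threshold else dn$hit_statistical
      rows[[length(rows) + 1]] <- data.frame(
        dilution_factor = dil, rule = rule,
        fp = sum(hit & !truthv), fn = sum(!hit & truthv),
        n_binders = sum(!truthv), n_true = sum(truthv),
        fp_rate = sum(hit & !truthv) / max(sum(!truthv), 1),
        fn_rate = sum(!hit & truthv) / max(sum(truthv), 1))
    }
    calls[[length(calls) + 1]] <- data.frame(
      dilution_factor = dil, binder_id = thr$binder_id,
      is_true_binder = unname(truthv),
      rh_mean = thr$rh_mean, pct_change = thr$pct_change,
      hit_threshold = thr$hit_threshold,
      p_adjusted = dn$p_adjusted, hit_statistical = dn$hit_statistical,
      stringsAsFactors = FALSE)
  }
  list(by_dilution = do.call(rbind, rows), calls = do.call(rbind, calls))
}

#' Thermostability comparison
#'
#' Compares a binder's hit status before and after heat treatment under
#' the threshold rule: `retained` if both pass, `lost` if only the
#' pre-heat measurement passes, `inconclusive` otherwise (nothing to
#' retain when the binder never passed).
#'
#' @param rh_before,rh_after Mean radii (nm) before/after heating.
#' @param reference_rh Reference radius in nm.
#' @param theta Relative cutoff (default 0.10).
#' @return `"retained"`, `"lost"`, or `"inconclusive"`.
#' @export
thermostability_compare <- function(rh_before, rh_after, reference_rh,
                                    theta = 0.10) {
  cut <- (1 + theta) * reference_rh
  before <- rh_before >= cut
  after <- rh_after >= cut
  ifelse(before & after, "retained",
         ifelse(before & !after, "lost", "inconclusive"))
}
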