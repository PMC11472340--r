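# Enzyme kinetics: initial rates from absorbance traces, relative activity
# with significance, Michaelis-Menten and four-parameter logistic fits, and
# inhibition-mode classification by global fitting with small-sample
# information criteria.

#' Initial rate from an absorbance trace
#'
#' Converts the linear slope of an absorbance time course (ferrocenium
#' reduction followed at 300 nm) into a rate in uM/s via Beer-Lambert:
#' `rate = |slope| / (epsilon * path * stoichiometry) * 1000` with the slope
#' in absorbance per second and `epsilon` in mM^-1 cm^-1.
#'
#' @param time_s Times (s).
#' @param absorbance Absorbance values.
#' @param epsilon Molar absorptivity (mM^-1 cm^-1).
#' @param path_cm Optical path length (cm).
#' @param stoichiometry_factor Electrons transferred per substrate turnover
#'   (ferrocenium consumed per catalytic event).
#' @param r2_min Linearity threshold; a linear fit with `R^2` below it marks
#'   the rate low-confidence.
#' @return Rate (uM/s) with attributes `r_squared` and `low_confidence`.
#' @export
#' @examples
#' initial_rate(seq(0, 300, 10), 1 - 1e-4 * seq(0, 300, 10), epsilon = 1)
initial_rate <- function(time_s, absorbance, epsilon, path_cm = 1,
                         stoichiometry_factor = 1, r2_min = 0.95) {
  if (epsilon <= 0) stop_pct("epsilon must be positive")
  stopifnot(length(time_s) == length(absorbance), length(time_s) >= 3L)
  fit <- stats::lm(absorbance ~ time_s)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # flat traces fit "perfectly"
  rate <- abs(slope) / (epsilon * path_cm * stoichiometry_factor) * 1000
  low <- slope != 0 && r2 < r2_min
  structure(rate, r_squared = r2, low_confidence = low)
}

#' Relative enzymatic activity vs a vehicle control
#'
#' `100 * mean(sample) / mean(control)` with the SD propagated from both
#' groups. Significance of a deviation from 100% is assessed by a one-sample
#' t-test of the relative activity against 100 using the propagated SD, with
#' an optional Bonferroni correction across a compound panel. (This is a
#' conservative stand-in for a one-way ANOVA with a Dunnett post-test.)
#'
#' @param sample_rates,control_rates Replicate rates (>= 2 each).
#' @param alpha Significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor; 1 (default) disables correction.
#' @return An `activity_result` list: `relative_activity` (%), `sd`,
#'   `n_replicates`, `t`, `p`, `p_adjusted`, `significant`.
#' @export
relative_activity <- function(sample_rates, control_rates, alpha = 0.05,
                              n_comparisons = 1L) {
  if (length(sample_rates) < 2L || length(control_rates) < 2L) {
    stop_pct("need at least 2 replicates per group")
  }
  mc <- mean(control_rates)
  if (mc <= 0) stop_pct("control mean must be positive")
  ms <- mean(sample_rates)
  rel <- 100 * ms / mc
  # first-order error propagation of the ratio
  rel_sd <- rel * sqrt((stats::sd(sample_rates) / ms)^2 +
                       (stats::sd(control_rates) / mc)^2)
  n <- length(sample_rates)
  sig <- activity_significance(rel, rel_sd, n, alpha, n_comparisons)
  structure(c(list(relative_activity = rel, sd = rel_sd, n_replicates = n),
              sig),
            class = "activity_result")
}

#' One-sample t-test of a relative activity against 100%
#'
#' Used both by [relative_activity()] and directly on summary panels that
#' report only mean +/- SD.
#'
#' @param mean_pct,sd_pct Relative activity mean and SD (% of control).
#' @param n Number of replicates.
#' @param alpha Significance level.
#' @param n_comparisons Bonferroni divisor.
#' @return List with `t`, `p`, `p_adjusted`, `significant`.
#' @export
activity_significance <- function(mean_pct, sd_pct, n = 3L, alpha = 0.05,
                                  n_comparisons = 1L) {
  se <- sd_pct / sqrt(n)
  t <- ifelse(se == 0, ifelse(mean_pct == 100, 0, Inf), (mean_pct - 100) / se)
  p <- 2 * stats::pt(-abs(t), df = n - 1L)
  p_adj <- pmin(1, p * n_comparisons)
  list(t = t, p = p, p_adjusted = p_adj, significant = p_adj < alpha)
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("Relative activity: %.1f +/- %.1f %% of control (n = %d)\n",
              x$relative_activity, x$sd, x$n_replicates))
  cat(sprintf("  t = %.2f, adjusted p = %.3g (%s)\n", x$t, x$p_adjusted,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

mm_starts <- function(s, v) {
  pos <- s > 0 & v > 0
  vmax0 <- max(v)
  # Lineweaver-Burk seed, guarded
  km0 <- tryCatch({
    cf <- stats::coef(stats::lm(I(1 / v[pos]) ~ I(1 / s[pos])))
    k <- cf[2L] / cf[1L]
    if (!is.finite(k) || k <= 0) NA_real_ else unname(k)
  }, error = function(e) NA_real_)
  kms <- unique(c(km0, stats::median(s[pos]), min(s[pos]),
                  min(s[pos]) / 100, max(s)))
  kms <- kms[is.finite(kms) & kms > 0]
  list(vmax0 = vmax0, kms = kms)
}

#' Fit the Michaelis-Menten equation
#'
#' Least-squares fit of `v = Vmax * S / (Km + S)` by Levenberg-Marquardt
#' with multiple starting values for `Km` (Lineweaver-Burk seed plus spread
#' over the substrate range), keeping the best solution.
#'
#' @param series A `rate_series` (columns `substrate_uM`, `rate`) or data
#'   frame; at least 5 substrate levels.
#' @return An `mm_fit` with `km` (uM), `vmax` (uM/s), standard errors,
#'   `fit_rmse`, and `km_lower_bound_only` flagged when the data show no
#'   curvature over the tested range (fitted `Km` beyond the substrate
#'   range).
#' @export
fit_mm <- function(series) {
  s <- series$substrate_uM
  v <- series$rate
  if (length(unique(s)) < 5L) stop_pct("need at least 5 substrate levels")
  st <- mm_starts(s, v)
  best <- NULL
  for (km0 in st$kms) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ vmax * s / (km + s),
                        start = list(vmax = st$vmax0, km = km0),
                        lower = c(vmax = 0, km = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12 * sum(v^2)) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) stop_pct("Michaelis-Menten fit failed to converge")
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, 2L],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  structure(list(km = unname(cf["km"]), vmax = unname(cf["vmax"]),
                 km_se = unname(se["km"]), vmax_se = unname(se["vmax"]),
                 fit_rmse = sqrt(best$rss / length(v)),
                 km_lower_bound_only = unname(cf["km"]) > max(s),
                 fit = fit, data = data.frame(substrate_uM = s, rate = v)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Km = %.4g uM, Vmax = %.4g uM/s\n",
              x$km, x$vmax))
  if (x$km_lower_bound_only) {
    cat("  note: no curvature over tested range; Km only bounded from below\n")
  }
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(km = object$km, vmax = object$vmax)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$substrate_uM else newdata$substrate_uM
  object$vmax * s / (object$km + s)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$data$rate - predict(object)
}

#' Fit a four-parameter logistic dose-response and report the IC50
#'
#' @param dose A [titration_series()] of percent activity vs compound
#'   concentration (uM); at least 5 concentrations.
#' @param flat_tol Response range (percent) below which the series is called
#'   flat ("no inhibition") and no IC50 is fitted.
#' @return An `ic50_fit` with `ic50` (uM, `NA` when no inhibition), `top`,
#'   `bottom`, `hill`, `fit_rmse`, `no_inhibition`, `low_confidence`
#'   (non-monotone response beyond noise).
#' @export
fit_ic50 <- function(dose, flat_tol = 5) {
  conc <- dose$conc_uM
  resp <- dose$response
  if (length(conc) < 5L) stop_pct("need at least 5 concentrations")
  out <- list(ic50 = NA_real_, top = NA_real_, bottom = NA_real_,
              hill = NA_real_, fit_rmse = NA_real_, no_inhibition = FALSE,
              low_confidence = FALSE,
              data = data.frame(conc_uM = conc, response = resp))
  if (diff(range(resp)) < flat_tol) {
    out$no_inhibition <- TRUE
    return(structure(out, class = "ic50_fit"))
  }
  pos <- conc > 0
  ic50_0 <- exp(mean(log(range(conc[pos]))))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ bottom + (top - bottom) / (1 + (conc / ic50)^hill),
      start = list(top = max(resp), bottom = min(resp), ic50 = ic50_0,
                   hill = 1),
      lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-9, hill = 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out$low_confidence <- TRUE
    return(structure(out, class = "ic50_fit"))
  }
  cf <- stats::coef(fit)
  out$ic50 <- unname(cf["ic50"])
  out$top <- unname(cf["top"])
  out$bottom <- unname(cf["bottom"])
  out$hill <- unname(cf["hill"])
  out$fit_rmse <- sqrt(mean(stats::residuals(fit)^2))
  # non-monotone beyond noise: ordered response rises where it should fall
  ord <- order(conc)
  dr <- diff(resp[ord])
  expected_sign <- -sign(out$top - out$bottom) * sign(out$hill)
  out$low_confidence <- any(sign(dr) == -expected_sign & abs(dr) >
                              4 * max(out$fit_rmse, 1e-8))
  out$fit <- fit
  structure(out, class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (x$no_inhibition) {
    cat("Dose-response: flat (no inhibition), IC50 undefined\n")
  } else {
    cat(sprintf("4PL fit: IC50 = %.4g uM (top %.1f, bottom %.1f, hill %.2f)\n",
                x$ic50, x$top, x$bottom, x$hill))
    if (x$low_confidence) cat("  [low confidence]\n")
  }
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50 = object$ic50, top = object$top, bottom = object$bottom,
    hill = object$hill)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc_uM else newdata$conc_uM
  fourpl(conc, object$ic50, object$top, object$bottom, object$hill)
}

# internal: fit one inhibition model globally (log-parameterised
# Levenberg-Marquardt on the residual function, so perfect starting points
# on noiseless data are not an error), return parameters + AICc
fit_one_mode <- function(s, i, v, mode, km0, vmax0, ki0) {
  predict_mode <- function(par) {
    mm_rate(s, i, exp(par[["log_km"]]), exp(par[["log_vmax"]]),
            ki = if ("log_ki" %in% names(par)) exp(par[["log_ki"]]) else Inf,
            ki_prime = if ("log_ki_prime" %in% names(par))
              exp(par[["log_ki_prime"]]) else Inf,
            model = mode)
  }
  par0 <- c(log_km = log(km0), log_vmax = log(vmax0))
  if (mode %in% c("competitive", "noncompetitive", "uncompetitive")) {
    par0 <- c(par0, log_ki = log(ki0))
  } else if (mode == "mixed") {
    par0 <- c(par0, log_ki = log(ki0), log_ki_prime = log(ki0))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = function(p) v - predict_mode(p),
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$par))) return(NULL)
  k <- length(par0) + 1L                  # + residual variance
  n <- length(v)
  rss <- max(fit$deviance, 1e-12 * sum(v^2), 1e-300)
  aicc <- n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  list(par = fit$par, aicc = aicc, rss = rss, k = k)
}

#' Global inhibition-model fit and mode selection
#'
#' Fits the four classical inhibition models (plus the no-inhibition model)
#' globally across all inhibitor concentrations with shared `Km` and `Vmax`,
#' and selects the mode by the small-sample corrected Akaike criterion
#' (AICc). When the best models are within `delta_aicc` of each other the
#' one with fewer parameters wins (parsimony tie rule).
#'
#' @param series A `rate_series` with columns `substrate_uM`, `inhibitor_uM`
#'   and `rate`, containing at least two inhibitor concentrations including
#'   zero.
#' @param delta_aicc Tie window (default 2).
#' @return A `kinetic_fit` with `km`, `vmax`, `ki`, `ki_prime` (mixed only),
#'   `mode`, and `aicc_table` (one row per candidate model).
#' @export
fit_inhibition_global <- function(series, delta_aicc = 2) {
  s <- series$substrate_uM
  i <- series$inhibitor_uM
  v <- series$rate
  if (length(unique(i)) < 2L) {
    stop_pct("need at least 2 inhibitor concentrations (mode unidentifiable)")
  }
  if (!any(i == 0)) stop_pct("series must include the uninhibited control (I = 0)")
  base <- fit_mm(data.frame(substrate_uM = s[i == 0], rate = v[i == 0]))
  km0 <- max(base$km, 1e-6)
  vmax0 <- base$vmax
  ki0 <- stats::median(i[i > 0])
  modes <- c("none", "competitive", "noncompetitive", "uncompetitive", "mixed")
  fits <- lapply(modes, function(m) fit_one_mode(s, i, v, m, km0, vmax0, ki0))
  names(fits) <- modes
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop_pct("no inhibition model converged")
  tab <- data.frame(model = modes[ok],
                    k = vapply(fits[ok], `[[`, numeric(1), "k"),
                    rss = vapply(fits[ok], `[[`, numeric(1), "rss"),
                    aicc = vapply(fits[ok], `[[`, numeric(1), "aicc"))
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  # parsimony tie rule: among models within the window, fewest parameters,
  # then the window's best AICc
  cand <- tab[tab$delta_aicc < delta_aicc, ]
  cand <- cand[order(cand$k, cand$aicc), ]
  mode <- cand$model[1L]
  chosen <- fits[[mode]]
  cf <- exp(unlist(chosen$par))
  names(cf) <- sub("^log_", "", names(cf))
  structure(list(km = unname(cf["km"]), vmax = unname(cf["vmax"]),
                 ki = if ("ki" %in% names(cf)) unname(cf["ki"]) else NA_real_,
                 ki_prime = if ("ki_prime" %in% names(cf))
                   unname(cf["ki_prime"]) else NA_real_,
                 mode = mode, aicc_table = tab[order(tab$aicc), ],
                 data = data.frame(substrate_uM = s, inhibitor_uM = i,
                                   rate = v)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Global inhibition fit\n")
  cat(sprintf("  mode = %s   Km = %.4g uM  Vmax = %.4g uM/s", x$mode,
              x$km, x$vmax))
  if (!is.na(x$ki)) cat(sprintf("  Ki = %.4g uM", x$ki))
  if (!is.na(x$ki_prime)) cat(sprintf("  Ki' = %.4g uM", x$ki_prime))
  cat("\n")
  print(x$aicc_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  c(km = object$km, vmax = object$vmax, ki = object$ki,
    ki_prime = object$ki_prime)
}

#' Rule-based inhibition-mode label from apparent parameters
#'
#' Compares apparent `Km` and `Vmax` from per-concentration Michaelis-Menten
#' fits against the uninhibited fit: a rising apparent `Km` at constant
#' `Vmax` is competitive-like, a falling `Vmax` at constant `Km` is
#' noncompetitive-like, and both moving is mixed. Parameters are "changed"
#' beyond a 25% fold threshold; when both change, the dominant axis (in log
#' fold) wins and a `mixed_flag` records the secondary movement. If a
#' [fit_inhibition_global()] result is supplied, disagreement is reported
#' and the global fit's mode wins.
#'
#' @param fit_no_inh `mm_fit` at zero inhibitor.
#' @param fits_with_inh List of `mm_fit`s at increasing inhibitor
#'   concentrations.
#' @param global Optional `kinetic_fit` cross-check.
#' @param fold_tol Fold change regarded as "changed" (default 1.25).
#' @param z_tol Significance threshold for the pooled parameter trend
#'   (default 2.5, conservative against testing two parameters at once);
#'   only applied when the fits carry standard errors.
#' @return List with `mode`, `mixed_flag`, `km_fold`, `vmax_fold`,
#'   `rule_mode` and `disagreement`.
#' @export
classify_mode <- function(fit_no_inh, fits_with_inh, global = NULL,
                          fold_tol = 1.25, z_tol = 2.5) {
  top <- fits_with_inh[[length(fits_with_inh)]]
  km_fold <- top$km / fit_no_inh$km
  vmax_fold <- top$vmax / fit_no_inh$vmax
  # A parameter has "changed" when its fold movement at the top inhibitor
  # concentration clears the tolerance and, where the fits carry standard
  # errors, the trend pooled over all concentrations (inverse-variance
  # weighted log folds) is resolvable against measurement noise.
  trend_z <- function(field, se_field) {
    num <- 0; den <- 0; have_se <- FALSE
    for (f in fits_with_inh) {
      l <- log(f[[field]] / fit_no_inh[[field]])
      sa <- f[[se_field]]; s0 <- fit_no_inh[[se_field]]
      if (is.null(sa) || is.null(s0) || anyNA(c(sa, s0))) next
      have_se <- TRUE
      v <- (sa / f[[field]])^2 + (s0 / fit_no_inh[[field]])^2
      num <- num + l / v
      den <- den + 1 / v
    }
    if (!have_se || den == 0) return(Inf)   # no SEs: fold tolerance decides
    num / sqrt(den)
  }
  km_changed <- abs(log(km_fold)) > log(fold_tol) &&
    abs(trend_z("km", "km_se")) > z_tol
  vmax_changed <- abs(log(vmax_fold)) > log(fold_tol) &&
    abs(trend_z("vmax", "vmax_se")) > z_tol
  mixed_flag <- FALSE
  if (!km_changed && !vmax_changed) {
    mode <- "none"
  } else if (km_changed && !vmax_changed) {
    mode <- "competitive"
    mixed_flag <- vmax_fold < 1 / (1 + (fold_tol - 1) * 0.8)
  } else if (!km_changed && vmax_changed) {
    mode <- if (vmax_fold < 1) "noncompetitive" else "none"
  } else {
    lk <- abs(log(km_fold))
    lv <- abs(log(vmax_fold))
    if (lk > 3 * lv) {
      mode <- "competitive"; mixed_flag <- TRUE
    } else if (lv > 3 * lk) {
      mode <- "noncompetitive"; mixed_flag <- TRUE
    } else {
      mode <- "mixed"
    }
  }
  rule_mode <- mode
  disagreement <- FALSE
  if (!is.null(global)) {
    disagreement <- !identical(global$mode, rule_mode)
    mode <- global$mode
  }
  list(mode = mode, mixed_flag = mixed_flag, km_fold = km_fold,
       vmax_fold = vmax_fold, rule_mode = rule_mode,
       disagreement = disagreement)
}
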