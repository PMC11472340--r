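# Differential scanning fluorimetry: melt-curve fitting, thermal shifts and
# the stabilisation scoring rubric.

#' Construct a melt curve
#'
#' @param temperature Strictly increasing temperatures (deg C).
#' @param fluorescence Dye fluorescence (arbitrary units), same length.
#' @param protein_label Protein identity (wild type or variant label).
#' @param compound_label,compound_conc Compound identity and concentration
#'   (uM), `NA` for the no-compound reference.
#' @param replicate_id Replicate index.
#' @return A `melt_curve` data frame.
#' @export
melt_curve <- function(temperature, fluorescence, protein_label = "WT",
                       compound_label = NA_character_,
                       compound_conc = NA_real_, replicate_id = 1L) {
  if (length(temperature) != length(fluorescence)) {
    stop_pct("temperature and fluorescence must have equal length")
  }
  if (any(diff(temperature) <= 0)) {
    stop_pct("temperature must be strictly increasing")
  }
  out <- data.frame(temperature = as.numeric(temperature),
                    fluorescence = as.numeric(fluorescence))
  attr(out, "protein_label") <- protein_label
  attr(out, "compound_label") <- compound_label
  attr(out, "compound_conc") <- compound_conc
  attr(out, "replicate_id") <- replicate_id
  class(out) <- c("melt_curve", "data.frame")
  out
}

# Rough transition locations from the smoothed derivative; returns the `k`
# most prominent, well-separated local maxima of dF/dT (starting values).
melt_start_tms <- function(temperature, fluorescence, k = 1L, min_sep = 4) {
  n <- length(temperature)
  f_sm <- max(0.08, 5 / n)
  sm <- stats::lowess(temperature, fluorescence, f = f_sm)$y
  dF <- abs(diff(sm) / diff(temperature))
  mid <- (temperature[-1] + temperature[-n]) / 2
  ord <- order(dF, decreasing = TRUE)
  picks <- numeric(0)
  for (j in ord) {
    if (length(picks) >= k) break
    if (!length(picks) || all(abs(mid[j] - picks) >= min_sep)) {
      picks <- c(picks, mid[j])
    }
  }
  if (length(picks) < k) {
    picks <- c(picks, stats::quantile(temperature,
                                      seq(0.25, 0.75,
                                          length.out = k - length(picks))))
  }
  sort(picks)
}

#' Fit a thermal melt curve
#'
#' Nonlinear least-squares fit of a two-state sigmoid with linear baselines
#' (monophasic) or a sum of two sigmoids (biphasic) to a dye-reported
#' denaturation trace. The melting temperature `Tm` is the fitted sigmoid
#' midpoint. The fit never throws on failure: an unconverged result is
#' returned with `converged = FALSE` and a `reason`.
#'
#' @param curve A [melt_curve()] (or data frame with `temperature` and
#'   `fluorescence` columns).
#' @param model `"monophasic"` or `"biphasic"`.
#' @param baseline_slopes Fit linear baseline slopes (monophasic only);
#'   default `FALSE` (flat baselines).
#' @return A `melt_fit` with components `tm`, `tm2` (biphasic), `amplitude`,
#'   `baselines`, `width`, `fit_rmse`, `converged`, `reason`, and the
#'   annotations of the input curve.
#' @export
fit_melt_curve <- function(curve, model = c("monophasic", "biphasic"),
                           baseline_slopes = FALSE) {
  model <- match.arg(model)
  temperature <- curve$temperature
  fluorescence <- curve$fluorescence
  if (length(temperature) < 10L) stop_pct("need at least 10 points to fit a melt")
  fail <- function(reason) {
    structure(list(tm = NA_real_, tm2 = NA_real_, amplitude = NA_real_,
                   baselines = c(pre = NA_real_, post = NA_real_),
                   width = NA_real_, fit_rmse = NA_real_, converged = FALSE,
                   reason = reason, model = model,
                   protein_label = attr(curve, "protein_label"),
                   compound_label = attr(curve, "compound_label"),
                   compound_conc = attr(curve, "compound_conc"),
                   data = data.frame(temperature, fluorescence)),
              class = "melt_fit")
  }
  amp0 <- diff(range(fluorescence))
  if (amp0 <= .Machine$double.eps^0.5) return(fail("no transition"))
  n_lo <- max(3L, length(temperature) %/% 5L)
  f_pre0 <- mean(utils::head(fluorescence, n_lo))
  f_post0 <- mean(utils::tail(fluorescence, n_lo))

  fit <- NULL
  if (model == "monophasic") {
    tm0 <- melt_start_tms(temperature, fluorescence, 1L)
    df <- data.frame(x = temperature, y = fluorescence)
    form <- if (baseline_slopes) {
      y ~ (f_pre + s_pre * x) +
        ((f_post + s_post * x) - (f_pre + s_pre * x)) * plogis((x - tm) / w)
    } else {
      y ~ f_pre + (f_post - f_pre) * plogis((x - tm) / w)
    }
    start <- list(f_pre = f_pre0, f_post = f_post0, tm = tm0, w = 1)
    if (baseline_slopes) start <- c(start, list(s_pre = 0, s_post = 0))
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(fail("optimizer failed"))
    cf <- stats::coef(fit)
    rmse <- sqrt(mean(stats::residuals(fit)^2))
    if (cf[["tm"]] < min(temperature) || cf[["tm"]] > max(temperature)) {
      return(fail("Tm outside observed range"))
    }
    if (abs(cf[["f_post"]] - cf[["f_pre"]]) < 5 * rmse) {
      return(fail("no transition"))
    }
    # a very wide "sigmoid" is a ramp, not a resolved unfolding transition
    if (abs(cf[["w"]]) > diff(range(temperature)) / 4) {
      return(fail("no transition"))
    }
    out <- list(tm = unname(cf["tm"]), tm2 = NA_real_,
                amplitude = unname(cf["f_post"] - cf["f_pre"]),
                baselines = c(pre = unname(cf["f_pre"]),
                              post = unname(cf["f_post"])),
                width = unname(cf["w"]), fit_rmse = rmse, converged = TRUE,
                reason = NA_character_, model = model, fit = fit)
  } else {
    df <- data.frame(x = temperature, y = fluorescence)
    starts <- list(melt_start_tms(temperature, fluorescence, 2L),
                   stats::quantile(temperature, c(0.35, 0.65)),
                   stats::quantile(temperature, c(0.25, 0.55)))
    fit <- NULL
    best_rss <- Inf
    for (tms0 in starts) {
      cand <- tryCatch(
        minpack.lm::nlsLM(
          y ~ f_pre + a1 * plogis((x - tm1) / w1) + a2 * plogis((x - tm2) / w2),
          data = df,
          start = list(f_pre = f_pre0, a1 = (f_post0 - f_pre0) / 2,
                       a2 = (f_post0 - f_pre0) / 2,
                       tm1 = tms0[[1]], tm2 = tms0[[2]], w1 = 1, w2 = 1),
          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(cand)) {
        rss <- sum(stats::residuals(cand)^2)
        if (rss < best_rss) {
          best_rss <- rss
          fit <- cand
        }
      }
    }
    if (is.null(fit)) return(fail("optimizer failed"))
    cf <- stats::coef(fit)
    tm_lo <- min(cf[["tm1"]], cf[["tm2"]])
    tm_hi <- max(cf[["tm1"]], cf[["tm2"]])
    if (tm_lo < min(temperature) || tm_hi > max(temperature)) {
      return(fail("Tm outside observed range"))
    }
    rmse <- sqrt(mean(stats::residuals(fit)^2))
    out <- list(tm = tm_lo, tm2 = tm_hi,
                amplitude = unname(cf["a1"] + cf["a2"]),
                baselines = c(pre = unname(cf["f_pre"]),
                              post = unname(cf["f_pre"] + cf["a1"] + cf["a2"])),
                width = unname(cf["w1"]), fit_rmse = rmse, converged = TRUE,
                reason = NA_character_, model = model, fit = fit)
  }
  out$protein_label <- attr(curve, "protein_label")
  out$compound_label <- attr(curve, "compound_label")
  out$compound_conc <- attr(curve, "compound_conc")
  out$data <- data.frame(temperature, fluorescence)
  structure(out, class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Melt-curve fit (", x$model, ")\n", sep = "")
  if (!x$converged) {
    cat("  not converged:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  Tm = %.2f degC", x$tm))
  if (!is.na(x$tm2)) cat(sprintf("  Tm2 = %.2f degC", x$tm2))
  cat(sprintf("  width = %.2f  amplitude = %.3g  rmse = %.3g\n",
              x$width, x$amplitude, x$fit_rmse))
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(tm = object$tm, tm2 = object$tm2, amplitude = object$amplitude,
    width = object$width, f_pre = unname(object$baselines["pre"]),
    f_post = unname(object$baselines["post"]))
}

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop_pct("cannot predict from an unconverged fit")
  x <- if (is.null(newdata)) object$data$temperature else newdata$temperature
  stats::predict(object$fit, newdata = data.frame(x = x))
}

#' @export
residuals.melt_fit <- function(object, ...) {
  if (!object$converged) return(rep(NA_real_, nrow(object$data)))
  object$data$fluorescence - predict(object)
}

#' @export
plot.melt_fit <- function(x, ...) {
  plot(x$data$temperature, x$data$fluorescence,
       xlab = "Temperature (degC)", ylab = "Fluorescence (a.u.)", ...)
  if (x$converged) {
    tt <- seq(min(x$data$temperature), max(x$data$temperature), length.out = 200)
    graphics::lines(tt, predict(x, data.frame(temperature = tt)))
    graphics::abline(v = c(x$tm, x$tm2), lty = 2)
  }
  invisible(x)
}

#' Thermal shift against a no-compound reference
#'
#' @param fit,reference Converged [fit_melt_curve()] results for the same
#'   protein, with and without compound.
#' @return `fit$tm - reference$tm` (deg C).
#' @export
delta_tm <- function(fit, reference) {
  stopifnot(inherits(fit, "melt_fit"), inherits(reference, "melt_fit"))
  if (!fit$converged || !reference$converged) {
    stop_pct("both fits must have converged")
  }
  if (!is.null(fit$protein_label) && !is.null(reference$protein_label) &&
      !identical(fit$protein_label, reference$protein_label)) {
    stop_pct("protein labels differ: ", fit$protein_label, " vs ",
             reference$protein_label)
  }
  fit$tm - reference$tm
}

#' Stabilisation score from a thermal shift
#'
#' Rubric: score 1 for shifts above 1 degC, 2 above 2 degC and 4 above
#' 3 degC; shifts within \[-1, 1\] score 0. Destabilising shifts mirror the
#' positive thresholds with negative scores (-1, -2, -4). Boundary values
#' take the lower bin (strict inequalities).
#'
#' @param delta Thermal shift(s), deg C. Must be finite.
#' @return Integer score(s) in `{-4, -2, -1, 0, 1, 2, 4}`.
#' @export
#' @examples
#' score_delta_tm(c(0.5, 1.5, 2.5, 3.5, -3.5))
score_delta_tm <- function(delta) {
  if (any(!is.finite(delta))) stop_pct("delta must be finite")
  pos <- findInterval(delta, c(1, 2, 3), left.open = TRUE)   # 0..3
  neg <- findInterval(-delta, c(1, 2, 3), left.open = TRUE)
  map <- c(0L, 1L, 2L, 4L)
  ifelse(delta >= 0, map[pos + 1L], -map[neg + 1L])
}

#' Sum stabilisation scores across protein variants
#'
#' A compound's combined stability score is the arithmetic sum of its
#' per-variant scores (wild type plus the screened disease variants).
#'
#' @param scores Integer scores, one per variant.
#' @return Their sum.
#' @export
combine_scores <- function(scores) {
  if (!length(scores)) stop_pct("need at least one score")
  sum(as.integer(scores))
}

#' Score from the best of several tested concentrations
#'
#' Each compound is screened at several concentrations; its per-variant score
#' derives from the highest thermal shift observed among them.
#'
#' @param delta_tms Thermal shifts (deg C) at the tested concentrations.
#' @return Integer score of `max(delta_tms)`, with the selected shift as
#'   attribute `"delta_tm"`.
#' @export
best_of_concentrations <- function(delta_tms) {
  if (!length(delta_tms)) stop_pct("need at least one concentration")
  best <- max(delta_tms)
  structure(score_delta_tm(best), delta_tm = best)
}

#' Dose-response of the thermal shift
#'
#' Summarises thermal shifts over a concentration series and flags a
#' monotone nondecreasing (dose-dependent) trend, defined as Spearman rank
#' correlation of shift vs concentration of at least `rho_min`.
#'
#' @param delta_tms Thermal shifts (deg C), one per concentration.
#' @param concentrations Compound concentrations (uM), at least 3.
#' @param rho_min Spearman threshold for the monotone flag (default 0.8).
#' @return List with `delta_tm_per_conc` (named by concentration),
#'   `monotone_flag`, `rho`, and `plateau` (shift gain over the final
#'   concentration step below 10% of the total range).
#' @export
dose_response_tm <- function(delta_tms, concentrations, rho_min = 0.8) {
  if (length(concentrations) < 3L) stop_pct("need at least 3 concentrations")
  stopifnot(length(delta_tms) == length(concentrations))
  ord <- order(concentrations)
  d <- delta_tms[ord]
  rho <- if (stats::sd(d) == 0) NA_real_ else
    suppressWarnings(stats::cor(concentrations[ord], d, method = "spearman"))
  rng <- diff(range(d))
  plateau <- rng > 0 && (d[length(d)] - d[length(d) - 1L]) < 0.1 * rng
  list(delta_tm_per_conc = stats::setNames(d, concentrations[ord]),
       monotone_flag = !is.na(rho) && rho >= rho_min,
       rho = rho, plateau = plateau)
}
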