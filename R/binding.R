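# Binding assays: tryptophan-quenching titrations (KB from the inverse
# slope) and one-site calorimetric isotherm fits with thermodynamic
# decomposition.

#' Fit a tryptophan-quenching titration
#'
#' Ordinary least-squares regression of normalised fluorescence `F/F0`
#' against compound concentration. The binding constant `KB` is the inverse
#' of the slope magnitude (the steeper the quenching, the tighter the
#' apparent binding). If the 95% confidence interval of the slope covers
#' zero the series is called `no_binding` and `KB` is left unset.
#'
#' @param series A [titration_series()] (columns `conc_uM`, `response`) with
#'   at least 5 concentrations including 0; responses normalised to `F/F0`.
#' @return A `quench_fit` with `slope` (per uM), `slope_se`, `kb` (uM, `NA`
#'   when no binding), `r_squared` and `binding_call` (`"binder"` or
#'   `"no_binding"`).
#' @export
#' @examples
#' s <- gen_quench_titration(ground_truth("quench", list(kb = 100)),
#'                           c(0, 5, 10, 25, 50, 100))
#' fit_quench(s)
fit_quench <- function(series) {
  conc <- series$conc_uM
  resp <- series$response
  if (length(conc) < 5L) stop_pct("need at least 5 concentrations")
  if (!any(conc == 0)) stop_pct("titration must include a zero-concentration point")
  out <- list(slope = NA_real_, slope_se = NA_real_, kb = NA_real_,
              kb_se = NA_real_, r_squared = NA_real_,
              binding_call = "no_binding")
  if (stats::sd(resp) == 0) {
    return(structure(out, class = "quench_fit"))
  }
  fit <- stats::lm(resp ~ conc)
  sm <- suppressWarnings(summary(fit))  # noiseless titrations fit perfectly
  slope <- unname(stats::coef(fit)[2L])
  se <- sm$coefficients[2L, 2L]
  ci <- slope + c(-1, 1) * stats::qt(0.975, fit$df.residual) * se
  out$slope <- slope
  out$slope_se <- se
  out$r_squared <- sm$r.squared
  if (ci[1] < 0 && ci[2] > 0) {
    return(structure(out, class = "quench_fit"))
  }
  out$kb <- 1 / abs(slope)
  out$kb_se <- se / slope^2     # delta method on 1/|slope|
  out$binding_call <- "binder"
  structure(out, class = "quench_fit")
}

#' @export
print.quench_fit <- function(x, ...) {
  cat("Tryptophan-quenching fit\n")
  if (x$binding_call == "no_binding") {
    cat("  no binding (slope indistinguishable from 0)\n")
  } else {
    cat(sprintf("  slope = %.4g per uM  KB = %.3g uM  R^2 = %.3f\n",
                x$slope, x$kb, x$r_squared))
  }
  invisible(x)
}

#' @export
coef.quench_fit <- function(object, ...) {
  c(slope = object$slope, kb = object$kb)
}

#' Fit a one-site calorimetric isotherm
#'
#' Nonlinear least-squares fit of dissociation constant `Kd`, binding
#' enthalpy `dH` and stoichiometry `N` to per-injection heats, using the same
#' perfusion-cell dilution bookkeeping as [gen_itc_experiment()]. `Kd` is
#' fitted on the log scale for conditioning. The free energy
#' `dG = R T ln(Kd)` (Kd in molar) and entropic term `-T dS = dG - dH` are
#' derived at the experiment temperature, so `dG = dH + (-T dS)` holds
#' exactly by construction.
#'
#' A run whose total integrated heat is below three times the injection
#' noise estimate is called `no_binding`. A fitted Wiseman c-parameter
#' (`N * [cell] / Kd`) outside `[0.5, 5000]` marks the fit low-confidence.
#'
#' @param series An [itc_series()] (from [gen_itc_experiment()] or
#'   [read_itc_csv()]); at least 10 injections.
#' @param temperature_K Experiment temperature (K); defaults to the value
#'   stored on the series, else 293.15 K (20 C).
#' @param drop_first Discard the first injection before fitting (common
#'   practice for the small pre-diffusion artefact); default `FALSE`.
#' @param noise_sd Per-injection noise (kcal/mol) for the no-binding call;
#'   estimated from the last injections when `NULL`.
#' @return An `itc_fit` with `kd` (uM), `dh` (kcal/mol), `n`, `dg`,
#'   `minus_tds` (kcal/mol), `temperature_K`, `binding_call`
#'   (`"binder"`/`"no_binding"`), `low_confidence`, `c_parameter`,
#'   `fit_rmse`.
#' @export
fit_itc <- function(series, temperature_K = NULL, drop_first = FALSE,
                    noise_sd = NULL) {
  stopifnot(inherits(series, "itc_series"))
  if (any(diff(series$molar_ratio) <= 0)) {
    stop_pct("molar ratios must be strictly increasing")
  }
  if (nrow(series) < 10L) stop_pct("need at least 10 injections")
  temperature_K <- temperature_K %||% attr(series, "temperature_K") %||% 293.15
  cell_conc <- attr(series, "cell_conc")
  syr_conc <- attr(series, "syringe_conc")
  vols <- attr(series, "inj_vol")
  cell_vol <- attr(series, "cell_vol")
  if (is.null(cell_conc) || is.null(syr_conc) || is.null(cell_vol)) {
    stop_pct("series must carry cell/syringe concentrations and cell volume")
  }
  heats <- series$heat_per_mole
  keep <- seq_along(heats)
  if (drop_first) keep <- keep[-1L]

  # noise estimate from the saturated tail (last quarter, >= 3 injections)
  tail_n <- max(3L, length(heats) %/% 4L)
  if (is.null(noise_sd)) {
    noise_sd <- stats::sd(utils::tail(heats, tail_n))
    if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- 1e-3
  }
  moles_inj <- syr_conc * 1e-6 * vols * 1e-6
  total_heat <- sum(heats * moles_inj)              # kcal
  noise_heat <- noise_sd * sqrt(sum(moles_inj^2))   # kcal, propagated

  out <- list(kd = NA_real_, dh = NA_real_, n = NA_real_, dg = NA_real_,
              minus_tds = NA_real_, temperature_K = temperature_K,
              gas_constant = GAS_CONSTANT_KCAL, binding_call = "no_binding",
              low_confidence = FALSE, c_parameter = NA_real_,
              fit_rmse = NA_real_, data = series)
  if (abs(total_heat) < 3 * noise_heat) {
    return(structure(out, class = "itc_fit"))
  }

  # starting values: dH from the earliest heats, N from the molar ratio at
  # half cumulative heat (isotherm inflection), Kd from the cell concentration
  dh0 <- mean(heats[seq_len(min(3L, length(heats)))])
  cum <- cumsum(heats * moles_inj)
  n0 <- series$molar_ratio[which.min(abs(cum - total_heat / 2))]
  n0 <- min(max(n0, 0.2), 5)
  model_fun <- function(log_kd, dh, n) {
    itc_forward(exp(log_kd), dh, n, cell_conc, syr_conc, vols,
                cell_vol)$heat_per_mole[keep]
  }
  obs <- heats[keep]
  fit <- NULL
  for (kd0 in c(cell_conc / 10, cell_conc, cell_conc / 100)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(obs ~ model_fun(log_kd, dh, n),
                        start = list(log_kd = log(kd0), dh = dh0, n = n0),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    out$low_confidence <- TRUE
    return(structure(out, class = "itc_fit"))
  }
  cf <- stats::coef(fit)
  kd <- exp(unname(cf["log_kd"]))
  out$kd <- kd
  out$dh <- unname(cf["dh"])
  out$n <- unname(cf["n"])
  out$dg <- GAS_CONSTANT_KCAL * temperature_K * log(kd * 1e-6)
  out$minus_tds <- out$dg - out$dh
  out$c_parameter <- out$n * cell_conc / kd
  out$fit_rmse <- sqrt(mean(stats::residuals(fit)^2))
  out$binding_call <- "binder"
  out$low_confidence <- out$c_parameter < 0.5 || out$c_parameter > 5000
  out$fit <- fit
  structure(out, class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("One-site calorimetric fit\n")
  if (x$binding_call == "no_binding") {
    cat("  no binding (total heat below noise)\n")
    return(invisible(x))
  }
  cat(sprintf("  Kd = %.3g uM  dH = %.3g kcal/mol  N = %.2f\n",
              x$kd, x$dh, x$n))
  cat(sprintf("  dG = %.3g  -TdS = %.3g kcal/mol at %.2f K  (c = %.3g)\n",
              x$dg, x$minus_tds, x$temperature_K, x$c_parameter))
  if (x$low_confidence) cat("  [low confidence]\n")
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...) {
  c(kd = object$kd, dh = object$dh, n = object$n, dg = object$dg,
    minus_tds = object$minus_tds)
}

#' @export
plot.itc_fit <- function(x, ...) {
  s <- x$data
  plot(s$molar_ratio, s$heat_per_mole, xlab = "Molar ratio",
       ylab = "Heat (kcal/mol of injectant)", ...)
  if (x$binding_call == "binder") {
    pred <- itc_forward(x$kd, x$dh, x$n, attr(s, "cell_conc"),
                        attr(s, "syringe_conc"), attr(s, "inj_vol"),
                        attr(s, "cell_vol"))$heat_per_mole
    graphics::lines(s$molar_ratio, pred)
  }
  invisible(x)
}

#' Binding evidence from the two orthogonal assays
#'
#' A compound shows binding evidence if calorimetry produced a binder call or
#' the quenching-derived constant is below `kb_cutoff` (default 100 uM).
#'
#' @param quench A [fit_quench()] result, or a numeric `KB` (uM), or `NULL`.
#' @param itc A [fit_itc()] result, or `NULL`.
#' @param kb_cutoff KB threshold (uM), strict `<`.
#' @return Logical flag.
#' @export
binding_evidence <- function(quench = NULL, itc = NULL, kb_cutoff = 100) {
  if (is.null(quench) && is.null(itc)) {
    stop_pct("at least one of quench/itc must be supplied")
  }
  itc_binds <- !is.null(itc) && identical(itc$binding_call, "binder")
  kb <- if (is.numeric(quench)) quench else quench$kb
  kb_binds <- !is.null(quench) && !is.na(kb) && kb < kb_cutoff
  itc_binds || kb_binds
}
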