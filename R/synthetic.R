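# Synthetic assay-signal generators with known ground truth.
#
# Each screening stage in the triage cascade has a forward signal model:
# two-state (optionally biphasic) thermal melts, linear tryptophan quenching,
# one-site calorimetric titrations, Michaelis-Menten kinetics with the four
# classical inhibition modes, and four-parameter logistic dose-response.
# The generators simulate those signals with configurable Gaussian noise so
# every downstream fitter can be tested by parameter recovery.

#' Ground truth for a simulated assay
#'
#' Bundles the generating parameters of one synthetic assay signal together
#' with a noise level and a seed. Identical `(parameters, seed)` pairs
#' reproduce bit-identical output from every generator.
#'
#' @param assay_kind One of `"melt"`, `"quench"`, `"itc"`, `"rate"`,
#'   `"dose_response"`.
#' @param parameters Named list of generating values in the assay's units:
#'   \describe{
#'     \item{melt}{`tm` (deg C), `w` (deg C), `f_pre`, `f_post` (fluorescence
#'       units); optional `slope_pre`, `slope_post`; for biphasic curves
#'       supply `tm`, `tm2`, `a1`, `a2`, `f_pre`, `w` (and optionally `w2`)
#'       with `tm < tm2`.}
#'     \item{quench}{`kb` (uM), the quenching binding constant; response is
#'       normalised fluorescence F/F0.}
#'     \item{itc}{`kd` (uM), `dh` (kcal/mol), `n` (stoichiometry).}
#'     \item{rate}{`km` (uM), `vmax` (uM/s); `ki` (uM) and for mixed
#'       inhibition `ki_prime` (uM) when an inhibition model is simulated.}
#'     \item{dose_response}{`ic50` (uM), `top`, `bottom` (percent activity),
#'       `hill`.}
#'   }
#' @param noise_sd Gaussian noise standard deviation in response units
#'   (fluorescence, F/F0, kcal/mol of injectant, uM/s, or percent). Must be
#'   `>= 0`.
#' @param seed Integer seed for the generator's private RNG stream.
#'
#' @return An object of class `"ground_truth"`.
#' @export
ground_truth <- function(assay_kind = c("melt", "quench", "itc", "rate",
                                        "dose_response"),
                         parameters, noise_sd = 0, seed = 1L) {
  assay_kind <- match.arg(assay_kind)
  stopifnot(is.list(parameters))
  if (!is_number(noise_sd) || noise_sd < 0) {
    stop_pct("`noise_sd` must be a single nonnegative number")
  }
  required <- switch(assay_kind,
    melt = if (!is.null(parameters$tm2)) c("tm", "tm2", "a1", "a2", "f_pre", "w")
           else c("tm", "w", "f_pre", "f_post"),
    quench = "kb",
    itc = c("kd", "dh", "n"),
    rate = c("km", "vmax"),
    dose_response = c("ic50", "top", "bottom", "hill")
  )
  missing <- setdiff(required, names(parameters))
  if (length(missing)) {
    stop_pct("missing generating parameter(s) for assay '", assay_kind,
             "': ", paste(missing, collapse = ", "))
  }
  if (assay_kind == "quench" && parameters$kb <= 0) {
    stop_pct("quenching constant `kb` must be positive")
  }
  if (assay_kind == "melt" && !is.null(parameters$tm2) &&
      parameters$tm >= parameters$tm2) {
    stop_pct("biphasic truth requires tm < tm2")
  }
  if (assay_kind == "rate" && (parameters$km <= 0 || parameters$vmax <= 0)) {
    stop_pct("`km` and `vmax` must be positive")
  }
  structure(list(assay_kind = assay_kind, parameters = parameters,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth for assay:", x$assay_kind, "\n")
  cat("  parameters:",
      paste(names(x$parameters), signif(unlist(x$parameters), 4),
            sep = " = ", collapse = ", "), "\n")
  cat("  noise_sd:", x$noise_sd, "  seed:", x$seed, "\n")
  invisible(x)
}

# --- forward models ---------------------------------------------------------

#' Two-state (optionally biphasic) melt signal
#'
#' Fluorescence of a thermal denaturation reported by an environment-
#' sensitive dye: linear pre-transition baseline plus one or two logistic
#' transitions, `F(T) = pre(T) + (post(T) - pre(T)) / (1 + exp((Tm - T)/w))`.
#'
#' @param temperature Temperatures (deg C).
#' @param tm,w Midpoint (deg C) and width (deg C) of the (first) transition.
#' @param f_pre,f_post Baseline fluorescence before/after the transition.
#' @param slope_pre,slope_post Baseline slopes (fluorescence per deg C).
#' @param tm2,a1,a2,w2 Second-transition midpoint, the two transition
#'   amplitudes and the second width for biphasic profiles (then `f_post` is
#'   ignored and the post level is `f_pre + a1 + a2`).
#' @return Numeric vector of noiseless fluorescence values.
#' @export
melt_signal <- function(temperature, tm, w = 1, f_pre = 0, f_post = 1,
                        slope_pre = 0, slope_post = 0,
                        tm2 = NULL, a1 = NULL, a2 = NULL, w2 = NULL) {
  pre <- f_pre + slope_pre * temperature
  if (is.null(tm2)) {
    post <- f_post + slope_post * temperature
    pre + (post - pre) * stats::plogis((temperature - tm) / w)
  } else {
    w2 <- w2 %||% w
    pre + a1 * stats::plogis((temperature - tm) / w) +
      a2 * stats::plogis((temperature - tm2) / w2)
  }
}

#' Michaelis-Menten rate with classical inhibition terms
#'
#' `v = Vmax * S / (alpha * Km + alpha' * S)` with
#' competitive `alpha = 1 + I/Ki, alpha' = 1`;
#' noncompetitive `alpha = alpha' = 1 + I/Ki`;
#' uncompetitive `alpha = 1, alpha' = 1 + I/Ki`;
#' mixed `alpha = 1 + I/Ki, alpha' = 1 + I/Ki'`.
#'
#' @param s Substrate concentrations (uM).
#' @param i Inhibitor concentration(s) (uM), recycled against `s`.
#' @param km,vmax Michaelis constant (uM) and limiting rate (uM/s).
#' @param ki,ki_prime Inhibition constants (uM) as required by `model`.
#' @param model Inhibition mode.
#' @return Rates (uM/s).
#' @export
mm_rate <- function(s, i = 0, km, vmax, ki = Inf, ki_prime = Inf,
                    model = c("none", "competitive", "noncompetitive",
                              "uncompetitive", "mixed")) {
  model <- match.arg(model)
  alpha <- switch(model,
    none = 1, competitive = 1 + i / ki, noncompetitive = 1 + i / ki,
    uncompetitive = 1, mixed = 1 + i / ki)
  alpha_p <- switch(model,
    none = 1, competitive = 1, noncompetitive = 1 + i / ki,
    uncompetitive = 1 + i / ki, mixed = 1 + i / ki_prime)
  vmax * s / (alpha * km + alpha_p * s)
}

#' Four-parameter logistic dose-response
#'
#' `resp(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)` for an
#' inhibitory curve (response falls with concentration when `hill > 0`).
#'
#' @param conc Concentrations (uM).
#' @param ic50 Midpoint (uM).
#' @param top,bottom Upper/lower asymptotes (percent of control).
#' @param hill Hill slope.
#' @export
fourpl <- function(conc, ic50, top = 100, bottom = 0, hill = 1) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

# --- generators -------------------------------------------------------------

#' Simulate a thermal melt curve
#'
#' @param truth A [ground_truth()] of kind `"melt"`.
#' @param temp_grid Strictly increasing temperatures (deg C); at least 10
#'   points are required for the curve to be fittable.
#' @param protein_label,compound_label,compound_conc,replicate_id Optional
#'   annotations carried on the returned curve.
#'
#' @return A `melt_curve`: data frame with columns `temperature` and
#'   `fluorescence` plus annotation attributes. If the generating `tm` falls
#'   outside the grid the curve carries `attr(, "warn_tm_outside") = TRUE`.
#' @export
gen_melt_curve <- function(truth, temp_grid, protein_label = "WT",
                           compound_label = NA_character_,
                           compound_conc = NA_real_, replicate_id = 1L) {
  stopifnot(inherits(truth, "ground_truth"), truth$assay_kind == "melt")
  if (length(temp_grid) < 10L) {
    stop_pct("temp_grid has fewer than 10 points; curve would be unfittable")
  }
  if (any(diff(temp_grid) <= 0)) stop_pct("temp_grid must be strictly increasing")
  p <- truth$parameters
  f <- melt_signal(temp_grid, tm = p$tm, w = p$w %||% 1,
                   f_pre = p$f_pre %||% 0, f_post = p$f_post %||% 1,
                   slope_pre = p$slope_pre %||% 0,
                   slope_post = p$slope_post %||% 0,
                   tm2 = p$tm2, a1 = p$a1, a2 = p$a2, w2 = p$w2)
  if (truth$noise_sd > 0) {
    f <- f + with_seed(truth$seed, stats::rnorm(length(f), 0, truth$noise_sd))
  }
  out <- melt_curve(temp_grid, f, protein_label = protein_label,
                    compound_label = compound_label,
                    compound_conc = compound_conc,
                    replicate_id = replicate_id)
  tms <- c(p$tm, p$tm2)
  if (any(tms < min(temp_grid) | tms > max(temp_grid))) {
    attr(out, "warn_tm_outside") <- TRUE
  }
  out
}

#' Simulate a tryptophan-quenching titration
#'
#' Normalised fluorescence falls linearly with compound concentration,
#' `F/F0 = 1 - c / KB`, clipped at zero, matching a linear-regression
#' analysis of intrinsic-fluorescence quenching.
#'
#' @param truth A [ground_truth()] of kind `"quench"` (parameter `kb`, uM).
#' @param concentrations Nonnegative compound concentrations (uM) including 0.
#' @return A `titration_series` data frame with columns `conc_uM`, `response`.
#' @export
gen_quench_titration <- function(truth, concentrations) {
  stopifnot(inherits(truth, "ground_truth"), truth$assay_kind == "quench")
  if (any(concentrations < 0)) stop_pct("concentrations must be nonnegative")
  if (!any(concentrations == 0)) stop_pct("concentrations must include 0")
  kb <- truth$parameters$kb
  resp <- pmax(0, 1 - concentrations / kb)
  if (truth$noise_sd > 0) {
    resp <- resp + with_seed(truth$seed,
                             stats::rnorm(length(resp), 0, truth$noise_sd))
  }
  titration_series(concentrations, resp)
}

#' A concentration-indexed response series
#'
#' Container used for quenching titrations, dose-response curves and
#' solubility standards alike.
#'
#' @param conc_uM Concentrations (uM).
#' @param response Responses (normalised F/F0, percent activity, peak area).
#' @param response_sd Optional per-point standard deviations.
#' @export
titration_series <- function(conc_uM, response, response_sd = NULL) {
  stopifnot(length(conc_uM) == length(response))
  out <- data.frame(conc_uM = as.numeric(conc_uM),
                    response = as.numeric(response))
  if (!is.null(response_sd)) out$response_sd <- as.numeric(response_sd)
  class(out) <- c("titration_series", "data.frame")
  out
}

# One-site binding: complex concentration from totals via the quadratic root.
# pt, lt in uM (pt is the *binding-site-bearing* protein monomer total);
# n sites per monomer.
one_site_complex <- function(pt, lt, kd, n = 1) {
  b <- n * pt + lt + kd
  0.5 * (b - sqrt(pmax(b * b - 4 * n * pt * lt, 0)))
}

#' Simulate a one-site calorimetric titration
#'
#' Generates per-injection heats (kcal per mole of injectant) for a titration
#' of ligand into protein under the one-site binding model with the standard
#' perfusion-cell bookkeeping: each injection displaces cell content, so both
#' cell concentrations are diluted by `(1 - v/V0)` per step while titrant
#' accumulates. The injection heat is the change in cell heat content
#' `Q = V0 * dH * [PL]` corrected for the displaced complex.
#'
#' @param truth A [ground_truth()] of kind `"itc"` (`kd` uM, `dh` kcal/mol,
#'   `n` sites).
#' @param cell_conc Protein concentration in the cell (uM).
#' @param syringe_conc Titrant concentration in the syringe (uM).
#' @param n_inj Number of injections.
#' @param inj_vol Injection volume (uL), scalar or per-injection vector.
#' @param cell_vol Calorimeter cell volume (uL).
#' @param temperature_K Experiment temperature (K); default 293.15 (20 C).
#'
#' @return An `itc_series`: data frame with `injection`, `molar_ratio`
#'   (cumulative ligand/protein in the cell) and `heat_per_mole` (kcal/mol of
#'   injectant), with the run geometry stored as attributes. A warning
#'   attribute is set when `syringe_conc <= cell_conc` (the titration cannot
#'   saturate).
#' @export
gen_itc_experiment <- function(truth, cell_conc = 30, syringe_conc = 500,
                               n_inj = 19L, inj_vol = 2, cell_vol = 200,
                               temperature_K = 293.15) {
  stopifnot(inherits(truth, "ground_truth"), truth$assay_kind == "itc")
  if (cell_conc <= 0 || syringe_conc <= 0 || cell_vol <= 0 || any(inj_vol <= 0)) {
    stop_pct("concentrations and volumes must be positive")
  }
  p <- truth$parameters
  vols <- rep_len(inj_vol, n_inj)
  heats <- itc_forward(p$kd, p$dh, p$n, cell_conc, syringe_conc, vols, cell_vol)
  if (truth$noise_sd > 0) {
    heats$heat_per_mole <- heats$heat_per_mole +
      with_seed(truth$seed, stats::rnorm(n_inj, 0, truth$noise_sd))
  }
  out <- itc_series(injection = seq_len(n_inj),
                    molar_ratio = heats$molar_ratio,
                    heat_per_mole = heats$heat_per_mole,
                    cell_conc = cell_conc, syringe_conc = syringe_conc,
                    inj_vol = vols, cell_vol = cell_vol,
                    temperature_K = temperature_K)
  if (syringe_conc <= cell_conc) attr(out, "warn_no_saturation") <- TRUE
  out
}

# Noiseless forward model used by both the generator and the fitter.
# Returns molar ratios, per-mole injection heats (kcal/mol) and raw heats
# (kcal).
itc_forward <- function(kd, dh, n, cell_conc, syringe_conc, vols, cell_vol) {
  n_inj <- length(vols)
  pt <- cell_conc
  lt <- 0
  q_prev <- one_site_complex(pt, lt, kd, n) * cell_vol * 1e-12 * dh # kcal
  heat_per_mole <- raw_heat <- molar_ratio <- numeric(n_inj)
  for (i in seq_len(n_inj)) {
    d <- vols[i] / cell_vol
    pt <- pt * (1 - d)
    lt <- lt * (1 - d) + syringe_conc * d
    q <- one_site_complex(pt, lt, kd, n) * cell_vol * 1e-12 * dh
    raw_heat[i] <- q - q_prev * (1 - d)
    moles_injected <- syringe_conc * 1e-6 * vols[i] * 1e-6
    heat_per_mole[i] <- raw_heat[i] / moles_injected
    molar_ratio[i] <- lt / pt
    q_prev <- q
  }
  list(molar_ratio = molar_ratio, heat_per_mole = heat_per_mole,
       raw_heat = raw_heat)
}

#' Injection-heat series container
#'
#' @param injection Injection indices.
#' @param molar_ratio Cumulative titrant/protein molar ratio in the cell;
#'   must be strictly increasing.
#' @param heat_per_mole Integrated heats, kcal per mole of injectant.
#' @param cell_conc,syringe_conc,inj_vol,cell_vol,temperature_K Run geometry
#'   (uM, uM, uL, uL, K).
#' @export
itc_series <- function(injection, molar_ratio, heat_per_mole,
                       cell_conc, syringe_conc, inj_vol, cell_vol,
                       temperature_K = 293.15) {
  stopifnot(length(injection) == length(molar_ratio),
            length(molar_ratio) == length(heat_per_mole))
  if (any(diff(molar_ratio) <= 0)) {
    stop_pct("molar_ratio must be strictly increasing")
  }
  out <- data.frame(injection = as.integer(injection),
                    molar_ratio = molar_ratio,
                    heat_per_mole = heat_per_mole)
  attr(out, "cell_conc") <- cell_conc
  attr(out, "syringe_conc") <- syringe_conc
  attr(out, "inj_vol") <- rep_len(inj_vol, length(injection))
  attr(out, "cell_vol") <- cell_vol
  attr(out, "temperature_K") <- temperature_K
  class(out) <- c("itc_series", "data.frame")
  out
}

#' Simulate initial-rate data with an inhibition mode
#'
#' @param truth A [ground_truth()] of kind `"rate"` (`km` uM, `vmax` uM/s,
#'   plus `ki` and, for mixed, `ki_prime` when `model != "none"`).
#' @param substrate_grid Substrate concentrations (uM), nonnegative.
#' @param inhibitor_concs Inhibitor concentrations (uM); one rate series is
#'   generated per concentration.
#' @param model Inhibition mode used to generate the data.
#' @return A `rate_series` data frame with columns `substrate_uM`,
#'   `inhibitor_uM`, `rate`.
#' @export
gen_rate_series <- function(truth, substrate_grid, inhibitor_concs = 0,
                            model = c("none", "competitive", "noncompetitive",
                                      "uncompetitive", "mixed")) {
  stopifnot(inherits(truth, "ground_truth"), truth$assay_kind == "rate")
  model <- match.arg(model)
  if (any(substrate_grid < 0)) stop_pct("substrate concentrations must be nonnegative")
  p <- truth$parameters
  if (model != "none" && (is.null(p$ki) || p$ki <= 0)) {
    stop_pct("model '", model, "' requires a positive `ki`")
  }
  if (model == "mixed" && (is.null(p$ki_prime) || p$ki_prime <= 0)) {
    stop_pct("mixed model requires a positive `ki_prime`")
  }
  grid <- expand.grid(substrate_uM = substrate_grid,
                      inhibitor_uM = inhibitor_concs)
  v <- mm_rate(grid$substrate_uM, grid$inhibitor_uM, km = p$km, vmax = p$vmax,
               ki = p$ki %||% Inf, ki_prime = p$ki_prime %||% Inf,
               model = model)
  if (truth$noise_sd > 0) {
    v <- v + with_seed(truth$seed, stats::rnorm(length(v), 0, truth$noise_sd))
  }
  out <- data.frame(substrate_uM = grid$substrate_uM,
                    inhibitor_uM = grid$inhibitor_uM, rate = v)
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Simulate a four-parameter logistic dose-response
#'
#' @param truth A [ground_truth()] of kind `"dose_response"` (`ic50` uM,
#'   `top`, `bottom`, `hill`).
#' @param concentrations Compound concentrations (uM).
#' @return A [titration_series()] of percent activity vs concentration.
#' @export
gen_dose_response <- function(truth, concentrations) {
  stopifnot(inherits(truth, "ground_truth"),
            truth$assay_kind == "dose_response")
  p <- truth$parameters
  resp <- fourpl(concentrations, p$ic50, p$top, p$bottom, p$hill)
  if (truth$noise_sd > 0) {
    resp <- resp + with_seed(truth$seed,
                             stats::rnorm(length(resp), 0, truth$noise_sd))
  }
  titration_series(concentrations, resp)
}
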