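---
title: "Models and methods behind the chaperone triage pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the chaperone triage pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pctriage)
```

## The problem

A pharmacological chaperone is a small molecule that binds and stabilises an
unstable or misfolded protein so that more of it survives to do its job.
When the chaperone binds an *allosteric* pocket rather than the active site,
stabilisation need not be paid for with substrate-competitive inhibition.
Finding such molecules is a triage problem: a docking campaign proposes
candidates, and a cascade of orthogonal assays — thermal shift (DSF),
tryptophan-fluorescence quenching, isothermal titration calorimetry (ITC),
and enzyme kinetics — winnows them to a handful of leads. `pctriage`
implements the analysis side of that cascade for a screen against
glutaryl-CoA dehydrogenase (GCDH), the enzyme deficient in glutaric acidemia
type 1, and ships the screen's published 25-compound summary panel as a
fixture so every rule can be exercised end to end.

This vignette records the models, the tunable parameters and the design
decisions, in the package's own words. Every number quoted here is computed
by the package's tests or its acceptance script; nothing is asserted that
the code does not reproduce.

## Thermal melts and the stability score

A dye-reported melt is modelled as a two-state transition with linear
baselines:

$$F(T) = \mathrm{pre}(T) + \frac{\mathrm{post}(T) - \mathrm{pre}(T)}
{1 + e^{(T_m - T)/w}}$$

`fit_melt_curve()` estimates the midpoint $T_m$ (°C), width $w$ (°C) and
baselines by Levenberg–Marquardt. Choices worth stating:

* **Midpoint, not derivative maximum.** $T_m$ is the fitted sigmoid
  midpoint; it is noise-robust and matches the "transition midpoint"
  convention of DSF analysis.
* **Failure is a value, not an exception.** Flat traces, ramps that a wide
  sigmoid could impersonate (fitted $w$ greater than a quarter of the
  temperature span), amplitudes under five times the residual RMSE, and
  midpoints outside the observed range all return `converged = FALSE` with
  a reason.
* **Biphasic profiles** (two transitions, as one screened variant showed)
  are fitted as a sum of two sigmoids with multi-start midpoints. Such
  variants are excluded from combined scoring by default because their two
  midpoints are not comparable with a single-transition $T_m$; inclusion is
  a configuration switch.
* **Replicates** are fitted per curve and summarised afterwards (mean
  $T_m$), rather than averaging curves before fitting; per-replicate fits
  keep the replicate-to-replicate spread visible.

The stabilisation rubric `score_delta_tm()` maps a shift
$\Delta T_m = T_m^{\mathrm{compound}} - T_m^{\mathrm{reference}}$ to
$\{1, 2, 4\}$ for shifts above 1, 2 and 3 °C, with 0 inside $[-1, 1]$.
Destabilising shifts mirror those thresholds as $\{-1, -2, -4\}$: the
published panel prints a $-4$, but no negative rubric, and mirroring is the
minimal consistent extension. Boundary values take the lower bin because the
published thresholds are strict inequalities. Per-compound scores use the
best shift among the three tested concentrations (10, 30, 100 µM), and
per-variant scores are summed across the wild type and screened variants.

## Quenching and calorimetry

**Quenching.** Intrinsic tryptophan fluorescence, normalised as $F/F_0$, is
modelled as linear in compound concentration; the binding constant is the
inverse slope magnitude, $K_B = 1/|\mathrm{slope}|$ (µM). The forward model
is deliberately linear (not a saturating isotherm) because the analysis
contract is a linear regression; simulated responses are clipped at zero.
A slope whose 95% confidence interval covers zero is a `no_binding` call.
The sign of the slope is dropped by contract — quenching gives falling
$F/F_0$.

**Calorimetry.** Injection heats follow the one-site model. With cell
protein total $P_t$, accumulated titrant $L_t$ and dissociation constant
$K_d$ (all µM), the complex concentration is the quadratic root

$$[PL] = \tfrac12\left[(N P_t + L_t + K_d) -
\sqrt{(N P_t + L_t + K_d)^2 - 4 N P_t L_t}\right]$$

and the cell heat content is $Q = V_0\,\Delta H\,[PL]$. Each injection of
volume $v$ displaces cell content, so both totals are diluted by
$(1 - v/V_0)$ per step and the measured heat is
$q_i = Q_i - Q_{i-1}(1 - v/V_0)$, normalised per mole of injectant. This
perfusion convention is stated explicitly because vendor software hides it.
The default run geometry is the screen's protocol: 19 × 2 µL of 500 µM
titrant into a 30 µM cell at 20 °C (293.15 K), with a 200 µL cell volume.
`fit_itc()` fits $(\log K_d, \Delta H, N)$ — $K_d$ on the log scale for
conditioning, stoichiometry seeded at the molar ratio of half-total heat —
and derives $\Delta G = RT\ln K_d$ (molar units,
$R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹) and $-T\Delta S = \Delta G -
\Delta H$, so the thermodynamic closure holds exactly by construction.
A run whose total heat is below three times the injection-noise estimate is
`no_binding` (the screen itself never defined its criterion; this is ours).
A Wiseman c-parameter $N P_t / K_d$ outside $[0.5, 5000]$ flags the fit
low-confidence. The first injection is kept by default; discarding it is a
flag.

Binding evidence for the lead rule is: a calorimetric binder call **or**
$K_B < 100$ µM (strict).

## Enzyme kinetics

Initial rates come from the linear slope of the ferrocenium absorbance
trace at 300 nm via Beer–Lambert; the extinction coefficient, path length
and electron stoichiometry are configuration values. Rates are expressed in
µM/s. One published unit ambiguity is worth recording: the screen prints
Michaelis constants in µM (0.026–0.22) against substrate ranges in mM
(0–1.5) and $V_{max}$ as "µM/s⁻¹". The package works in µM and µM/s
throughout, reproduces the printed numbers as printed, and leaves the
inconsistency unresolved; CSV readers accept `substrate_mM` columns and
convert.

Inhibition uses the general form
$v = V_{max} S / (\alpha K_m + \alpha' S)$ with
$(\alpha, \alpha') = (1 + I/K_i,\, 1)$ for competitive,
$(\alpha, \alpha)$ for noncompetitive, $(1,\, 1 + I/K_i)$ for
uncompetitive, and distinct constants for mixed inhibition.
`fit_inhibition_global()` fits all five candidate models (including no
inhibition) globally across inhibitor concentrations and selects the mode
by AICc, with a parsimony tie rule: within a ΔAICc window of 2, the model
with fewer parameters wins. Fits run on log-parameters through the
Levenberg–Marquardt residual interface, which tolerates the zero-residual
case of noiseless data.

`classify_mode()` is the complementary rule-based reading of apparent
parameters: per-concentration Michaelis–Menten fits give apparent $K_m$ and
$V_{max}$, and a parameter counts as *changed* only when its fold movement
at the top inhibitor concentration clears a 1.25× tolerance **and** its
log-fold trend pooled across all concentrations (inverse-variance weighted)
is resolvable against the fits' standard errors at $z > 2.5$ — conservative
against reading two parameters at once. Without standard errors (summary
inputs) the fold tolerance alone decides. Rising $K_m$ at constant
$V_{max}$ is competitive-like; falling $V_{max}$ at constant $K_m$ is
noncompetitive-like; both moving is mixed, with the dominant axis (3× in
log fold) winning and the secondary movement recorded as a `mixed_flag`.
When a global fit is supplied and disagrees, the disagreement is reported
and the global fit wins.

A note on model selection near the boundary: the mixed model nests the
noncompetitive one, and AICc with a ΔAICc < 2 parsimony window accepts the
extra parameter with probability near
$P(F_{1,n-k} > 4) \approx 5\%$ on data truly generated from the simpler
model — an intrinsic property of the criterion, not of the optimizer. The
pooled-trend rule in `classify_mode()` does not share this floor, which is
why the package's accuracy checks exercise it directly.

Dose–response uses the four-parameter logistic
$r(c) = b + (t - b)/(1 + (c/\mathrm{IC}_{50})^h)$; a response range under
5 percentage points is a "no inhibition" call, and non-monotonicity beyond
four residual RMSEs flags low confidence. Potencies below the tested
concentration floor are bounds, not fittable targets.

Relative activity is $100\,\bar v_{\mathrm{sample}}/\bar
v_{\mathrm{control}}$ with first-order error propagation; significance is a
one-sample t-test against 100% (optionally Bonferroni-corrected across a
panel). This deliberately replaces a Dunnett post-test: Dunnett's critical
values need multivariate-t machinery and the triage decision only needs a
conservative flag. With the panel's published summaries (n = 3, α = 0.05),
135 ± 59 is not significant (t ≈ 1.03 < 4.30) while 2.6 ± 2.3 is.

## In-silico triage rules

Docked poses are abstract typed feature points — the package does not dock.
A pharmacophore point (one hydrogen-bond acceptor plus three hydrophobic
groups in the screen's model) is satisfied when a feature of matching type
lies within its radius; all four restraints are mandatory by default.
Poses are kept below a raw intermolecular score of −18.0 and ranked by
score per heavy atom, ties broken by compound id so ranking is
input-order-invariant. Property rules are interval tests; substructure
alerts (reactive/frequent-hitter patterns) flag but never auto-reject.
Fingerprints default to OpenBabel's MACCS structural keys via ChemmineR,
but every similarity, clustering and analogue-search function accepts plain
bit vectors, because key definitions vary by toolkit. Clustering is
classic sphere exclusion (leaders by descending neighbour count at a
Tanimoto threshold, default 0.7 — the screen names no threshold), which is
deterministic for a fixed input order.

Solubility follows the LC-MS single-point quantification
$S = C_{std} \cdot \frac{A_{sample}}{A_{std}} \cdot
\frac{V^{inj}_{std}}{V^{inj}_{sample}} \cdot DF$, and
`correlate_solubility_effects()` tests whether solubility explains assay
effects by Spearman correlation with a seeded permutation p-value
(exhaustive enumeration below n = 8).

**The lead rule.** A compound is a lead when it simultaneously (i) changes
activity by more than 25 percentage points, (ii) significantly so,
(iii) has a summed stability score above 3, (iv) shows binding evidence,
and (v) retains at least 10% residual activity. The floor and the
significance requirement are our interpretation, stated as such: the
published criteria alone would also admit a near-total inhibitor
(2.6% residual activity — whatever its binding, a molecule that abolishes
the enzyme cannot chaperone it) and a compound whose activity change is
indistinguishable from noise (135 ± 59). With them, the packaged panel
yields exactly the five published leads, with a per-criterion audit trail
for every exclusion.

```{r leads}
leads <- select_leads(load_table1_fixture())
leads
subset(attr(leads, "audit"), !lead, select = c(compound, failed_criteria))[1:5, ]
```

## The simulators, and what passing tests do not show

Every assay has a generator (`gen_melt_curve()`, `gen_quench_titration()`,
`gen_itc_experiment()`, `gen_rate_series()`, `gen_dose_response()`) driven
by a `ground_truth()` object: generating parameters, a homoscedastic
Gaussian noise SD in response units, and an explicit seed — never global
RNG state. Identical truth and seed give bit-identical output. Defaults
mirror the screen's printed conditions: melts on a 25–60 °C grid at 1 °C
steps; quenching at the 16 published concentrations (0–100 µM); ITC at the
19 × 2 µL protocol; kinetics on substrate ranges spanning 0–1.5 mM with
duplicate assays per condition, as the kinetics experiments were run.
Simulation sizes in the test suite (200 melt seeds, 50 ITC seeds per grid
point, 100 datasets per inhibition mode) were chosen to estimate recovery
medians and confusion rates with a few percent of Monte Carlo error while
keeping the suite quick.

The simulators emulate idealised signal models. They do not emulate
aggregation, compound insolubility at high concentration (the screen's ITC
lost several compounds to it), inner-filter effects in fluorescence,
baseline drift and integration artefacts in calorimetry, or substrate
depletion in rate traces. Parameter-recovery tests therefore demonstrate
that the fitters are correct and well-conditioned against their own signal
models — a necessary condition — not that the models capture everything
real plates produce.

## Numerical choices

* All nonlinear fits use Levenberg–Marquardt (minpack.lm), log-parameterised
  wherever positivity is structural ($K_d$, $K_m$, $V_{max}$, $K_i$), with
  multi-start where starts matter (melt midpoints, $K_m$).
* Model-selection RSS values are floored at $10^{-12}\sum v^2$ so that
  noiseless fits tie instead of producing $-\infty$ information criteria;
  the parsimony rule then decides.
* The rubric's strict inequalities put boundary shifts (exactly 2.000 °C)
  in the lower bin; the fine-grid monotonicity property pins this down.
* Degenerate inputs refuse loudly (too-short grids, negative binding
  constants, non-monotone molar ratios, empty sites) or return flagged
  results (unconverged melt fits, low-confidence ITC and IC50 fits); which
  of the two happens is part of each function's contract.

## Known limitations

Docking scores and pose features are inputs, not computations; the hit-rate
of the original virtual screen is not reproducible here. Quenching is
analysed strictly linearly, so saturating titrations would bias $K_B$
downward. The ITC model is single-site and non-cooperative. Dunnett's exact
post-test is approximated conservatively. The uncompetitive mode is hard to
distinguish from noncompetitive by apparent-parameter rules at moderate
noise; the global AICc fit is the arbiter there.
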