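# pctriage

Screening and triage of pharmacological chaperones from multi-assay data.

Pharmacological chaperones are small molecules that bind and stabilise an
unstable or misfolded protein, rescuing its function; allosteric chaperones
do so from a noncatalytic pocket, so stabilisation is not bought with
active-site inhibition. Campaigns that hunt for them produce a cascade of
heterogeneous assay data — thermal melts, fluorescence titrations,
calorimetric isotherms, initial-rate tables, docking poses — that must be
fitted, scored and combined into a defensible lead list. `pctriage`
implements that analysis cascade as a tested R package, exercised end to end
on simulated assays with known ground truth and on a packaged summary panel
of a published 25-compound screen against glutaryl-CoA dehydrogenase (GCDH),
the enzyme deficient in glutaric acidemia type 1.

## What it computes

* **Thermal shifts.** Two-state (optionally biphasic) melt fits
  `F(T) = pre(T) + (post(T) − pre(T)) / (1 + exp((Tm − T)/w))`, shifts
  ΔTm against a no-compound reference, and the stabilisation rubric
  (score 1/2/4 for ΔTm > 1/2/3 °C, mirrored for destabilisation), summed
  across protein variants.
* **Binding.** Quenching constants `KB = 1/|slope|` from linear F/F0
  titrations; one-site calorimetric fits of (Kd, ΔH, N) with perfusion-cell
  dilution bookkeeping and the decomposition ΔG = RT·ln Kd,
  −TΔS = ΔG − ΔH.
* **Kinetics.** Initial rates from absorbance traces, relative activity
  with a one-sample t-test vs control, Michaelis–Menten fits
  `v = Vmax·S/(Km + S)`, 4PL IC50 fits, global inhibition-model fits
  (competitive / noncompetitive / uncompetitive / mixed) selected by AICc
  with a parsimony tie rule, and a noise-aware apparent-parameter mode
  classifier.
* **In-silico triage.** Pharmacophore-restraint checks, docking-score
  filtering and per-heavy-atom ranking, property and substructure (SMARTS)
  filters, MACCS/Tanimoto sphere-exclusion clustering, analogue search,
  LC-MS solubility, and the multi-assay lead rule with per-criterion audit.
* **Simulators.** Every assay signal can be generated with known ground
  truth, Gaussian noise and an explicit seed, so each fitter is testable by
  parameter recovery.

## Worked example

```r
library(pctriage)

# The packaged 25-compound screen summary
panel <- load_table1_fixture()
nrow(panel)
#> [1] 25
sum(panel$kb_uM < 100)                      # quenching-derived binders
#> [1] 13

# The multi-assay lead rule, with audit trail
leads <- select_leads(panel)
leads
#> [1] "A49" "A55" "A71" "B29" "B31"
attr(leads, "audit")$failed_criteria[attr(leads, "audit")$compound == "A34"]
#> [1] "binding"

# Recover a melting temperature from a simulated noisy melt
truth <- ground_truth("melt", list(tm = 45, w = 1, f_pre = 0, f_post = 4),
                      noise_sd = 0.08, seed = 42)
fit <- fit_melt_curve(gen_melt_curve(truth, seq(25, 60, 0.5)))
fit
#> Melt-curve fit (monophasic)
#>   Tm = 45.07 degC  width = 0.97  amplitude = 4.01  rmse = 0.0859

# One-site calorimetry at the screen's protocol (19 x 2 uL, 500 uM into 30 uM)
itc <- gen_itc_experiment(ground_truth("itc", list(kd = 3.4, dh = -10, n = 1)))
fit_itc(itc)
#> One-site calorimetric fit
#>   Kd = 3.4 uM  dH = -10 kcal/mol  N = 1.00
#>   dG = -7.34  -TdS = 2.66 kcal/mol at 293.15 K  (c = 8.82)
```

The lead list is the set of compounds that simultaneously change enzymatic
activity by more than 25 percentage points (significantly), carry a summed
stability score above 3, show binding evidence (a measured calorimetric Kd
or KB < 100 µM), and retain at least 10% residual activity. The audit table
names the failed criteria for every excluded compound.

See `vignettes/chaperone-triage-methods.Rmd` for the models, parameter
choices and limitations.

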