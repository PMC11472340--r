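Package: pctriage
Title: Screening and Triage of Pharmacological Chaperones from Biophysical and Biochemical Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and triaging pharmacological chaperones
    (allosteric protein stabilisers) from a multi-assay screening cascade:
    differential scanning fluorimetry melt-curve fitting with a thermal-shift
    scoring rubric across protein variants, tryptophan-quenching binding
    constants from linear titrations, one-site isothermal titration
    calorimetry isotherm fits with thermodynamic decomposition,
    Michaelis-Menten kinetics with inhibition-mode classification by
    small-sample information criteria, four-parameter logistic dose-response
    fits, pharmacophore/docking-score/property filters with fingerprint
    clustering, LC-MS solubility computation, and a multi-assay lead-selection
    rule with a per-criterion audit trail. Includes generators that simulate
    every assay signal with known ground truth and a packaged summary panel of
    a published 25-compound glutaryl-CoA dehydrogenase screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    ChemmineR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    bio3d
Config/testthat/edition: 3
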