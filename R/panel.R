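# Packaged assay panel of the published 25-compound GCDH screen.

#' Load the packaged 25-compound GCDH assay panel
#'
#' The published screen of glutaryl-CoA dehydrogenase (GCDH) chaperone
#' candidates summarised 25 compounds by chemical scaffold, relative
#' enzymatic activity (% of DMSO control, mean +/- SD of three replicates at
#' 10 uM compound), per-variant thermal-shift scores (WT, R88C, V400M,
#' A433E), tryptophan-quenching binding constants (KB, uM) and calorimetric
#' dissociation constants (Kd, uM) where measurable. The panel ships with the
#' package as a versioned CSV so the triage rules can be exercised without
#' any external data.
#'
#' @return An `assay_panel`: data frame with one row per compound and columns
#'   `compound`, `scaffold` (`"1"`, `"2"`, `"others"`), `activity_pct`,
#'   `activity_sd`, `score_wt`, `score_r88c`, `score_v400m`, `score_a433e`,
#'   `kb_uM`, `itc_kd_uM` (NA when not measurable), `itc_kd_sd`, and
#'   `itc_status` (`"measured"`, `"insoluble"`, `"no_binding"`).
#' @export
#' @examples
#' panel <- load_table1_fixture()
#' nrow(panel)            # 25 compounds
#' sum(panel$kb_uM < 100) # quenching-derived binders
load_table1_fixture <- function() {
  path <- system.file("extdata", "gcdh_panel_table1.csv", package = "pctriage",
                      mustWork = TRUE)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  as_assay_panel(panel)
}

#' Validate and class an assay panel
#'
#' @param panel Data frame with the columns described in
#'   [load_table1_fixture()].
#' @return The validated panel with class `assay_panel`.
#' @export
as_assay_panel <- function(panel) {
  required <- c("compound", "scaffold", "activity_pct", "activity_sd",
                "score_wt", "score_r88c", "score_v400m", "score_a433e",
                "kb_uM", "itc_status")
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    stop_pct("assay panel is missing column(s): ",
             paste(missing, collapse = ", "))
  }
  if (anyDuplicated(panel$compound)) stop_pct("duplicate compound ids in panel")
  scores <- unlist(panel[, c("score_wt", "score_r88c", "score_v400m",
                             "score_a433e")])
  bad <- !scores %in% c(-4L, -2L, -1L, 0L, 1L, 2L, 4L)
  if (any(bad)) {
    stop_pct("per-variant scores must lie in {-4,-2,-1,0,1,2,4}")
  }
  if (!"itc_kd_uM" %in% names(panel)) panel$itc_kd_uM <- NA_real_
  class(panel) <- unique(c("assay_panel", class(panel)))
  panel
}

#' Per-variant score columns of an assay panel
#' @param panel An `assay_panel`.
#' @return Integer matrix of the four per-variant stability scores.
#' @export
panel_scores <- function(panel) {
  as.matrix(panel[, c("score_wt", "score_r88c", "score_v400m", "score_a433e")])
}
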