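# Readers, writers, configuration and the end-to-end triage pipeline.
#
# CSV dialect: comma-separated, UTF-8, mandatory header row, units encoded
# in column names (conc_uM, substrate_mM, heat_ucal, ...). Malformed rows
# are collected into a rejects attribute, never silently dropped.

read_validated_csv <- function(path, required, numeric_cols, comment = "") {
  if (!file.exists(path)) stop_pct("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = comment,
                        na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_pct("missing required column(s) in ", basename(path), ": ",
             paste(missing, collapse = ", "))
  }
  if (!nrow(df)) stop_pct("empty file (header only): ", basename(path))
  bad <- rep(FALSE, nrow(df))
  for (col in intersect(numeric_cols, names(df))) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- bad | (is.na(val) & !is.na(df[[col]]))
    df[[col]] <- val
  }
  rejects <- df[bad, , drop = FALSE]
  df <- df[!bad, , drop = FALSE]
  if (!nrow(df)) stop_pct("no valid rows in ", basename(path))
  attr(df, "rejects") <- rejects
  df
}

#' Read melt curves from a long-format CSV
#'
#' Expected columns: `temperature`, `fluorescence`, `protein`, `compound`,
#' `conc_uM`, `replicate`. One [melt_curve()] is returned per
#' (protein, compound, concentration, replicate) combination.
#'
#' @param path CSV path.
#' @return List of `melt_curve` objects; rows that fail numeric validation
#'   are attached as attribute `"rejects"`.
#' @export
read_melt_csv <- function(path) {
  df <- read_validated_csv(path,
    required = c("temperature", "fluorescence", "protein", "compound",
                 "conc_uM", "replicate"),
    numeric_cols = c("temperature", "fluorescence", "conc_uM"))
  key <- interaction(df$protein, df$compound, df$conc_uM, df$replicate,
                     drop = TRUE)
  curves <- lapply(split(df, key), function(g) {
    g <- g[order(g$temperature), , drop = FALSE]
    melt_curve(g$temperature, g$fluorescence, protein_label = g$protein[1],
               compound_label = g$compound[1], compound_conc = g$conc_uM[1],
               replicate_id = g$replicate[1])
  })
  attr(curves, "rejects") <- attr(df, "rejects")
  curves
}

#' Write melt curves to the long-format CSV dialect
#' @param curves List of [melt_curve()]s (or a single curve).
#' @param path Output CSV path.
#' @export
write_melt_csv <- function(curves, path) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cu) {
    data.frame(temperature = cu$temperature, fluorescence = cu$fluorescence,
               protein = attr(cu, "protein_label"),
               compound = attr(cu, "compound_label"),
               conc_uM = attr(cu, "compound_conc"),
               replicate = attr(cu, "replicate_id"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a quenching titration CSV (`conc_uM`, `F_over_F0`)
#' @param path CSV path.
#' @return A [titration_series()] (plus `"rejects"` attribute).
#' @export
read_quench_csv <- function(path) {
  df <- read_validated_csv(path, required = c("conc_uM", "F_over_F0"),
                           numeric_cols = c("conc_uM", "F_over_F0"))
  out <- titration_series(df$conc_uM, df$F_over_F0)
  attr(out, "rejects") <- attr(df, "rejects")
  out
}

#' Write a quenching titration CSV
#' @param series A [titration_series()].
#' @param path Output path.
#' @export
write_quench_csv <- function(series, path) {
  utils::write.csv(data.frame(conc_uM = series$conc_uM,
                              F_over_F0 = series$response),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a calorimetric titration CSV
#'
#' Format: a comment header block of `# key = value` lines declaring
#' `cell_conc_uM`, `syringe_conc_uM`, `cell_vol_uL` (and optionally
#' `temperature_K`), followed by columns `injection`, `volume_uL`,
#' `heat_ucal` (integrated heats in microcalories). Heats are converted to
#' kcal per mole of injectant.
#'
#' @param path CSV path.
#' @return An [itc_series()].
#' @export
read_itc_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=")[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  for (key in c("cell_conc_uM", "syringe_conc_uM", "cell_vol_uL")) {
    if (is.null(meta[[key]])) stop_pct("ITC header block lacks ", key)
  }
  df <- read_validated_csv(path, required = c("injection", "volume_uL",
                                              "heat_ucal"),
                           numeric_cols = c("injection", "volume_uL",
                                            "heat_ucal"),
                           comment = "#")
  moles <- meta$syringe_conc_uM * 1e-6 * df$volume_uL * 1e-6
  heat_kcal_mol <- df$heat_ucal * 1e-9 / moles
  # reconstruct molar ratios from the declared geometry
  pt <- meta$cell_conc_uM
  lt <- 0
  ratio <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    d <- df$volume_uL[i] / meta$cell_vol_uL
    pt <- pt * (1 - d)
    lt <- lt * (1 - d) + meta$syringe_conc_uM * d
    ratio[i] <- lt / pt
  }
  itc_series(df$injection, ratio, heat_kcal_mol,
             cell_conc = meta$cell_conc_uM,
             syringe_conc = meta$syringe_conc_uM,
             inj_vol = df$volume_uL, cell_vol = meta$cell_vol_uL,
             temperature_K = meta$temperature_K %||% 293.15)
}

#' Write a calorimetric titration CSV
#' @param series An [itc_series()].
#' @param path Output path.
#' @export
write_itc_csv <- function(series, path) {
  moles <- attr(series, "syringe_conc") * 1e-6 * attr(series, "inj_vol") * 1e-6
  heat_ucal <- series$heat_per_mole * moles / 1e-9
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# cell_conc_uM = %.10g", attr(series, "cell_conc")),
    sprintf("# syringe_conc_uM = %.10g", attr(series, "syringe_conc")),
    sprintf("# cell_vol_uL = %.10g", attr(series, "cell_vol")),
    sprintf("# temperature_K = %.10g", attr(series, "temperature_K"))), con)
  utils::write.csv(data.frame(injection = series$injection,
                              volume_uL = attr(series, "inj_vol"),
                              heat_ucal = heat_ucal),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read initial-rate series from CSV
#'
#' Expected columns: `substrate_mM`, `inhibitor_uM`, `rate` (uM/s), plus
#' optional `protein`, `compound`, `replicate`. Substrate is converted to uM
#' internally.
#'
#' @param path CSV path.
#' @return A `rate_series` data frame with `substrate_uM`.
#' @export
read_rates_csv <- function(path) {
  df <- read_validated_csv(path,
    required = c("substrate_mM", "inhibitor_uM", "rate"),
    numeric_cols = c("substrate_mM", "inhibitor_uM", "rate"))
  out <- data.frame(substrate_uM = df$substrate_mM * 1000,
                    inhibitor_uM = df$inhibitor_uM, rate = df$rate)
  for (col in c("protein", "compound", "replicate")) {
    if (col %in% names(df)) out[[col]] <- df[[col]]
  }
  class(out) <- c("rate_series", "data.frame")
  attr(out, "rejects") <- attr(df, "rejects")
  out
}

#' Write a rate series CSV
#' @param series A `rate_series` (with `substrate_uM`).
#' @param path Output path.
#' @export
write_rates_csv <- function(series, path) {
  df <- data.frame(substrate_mM = series$substrate_uM / 1000,
                   inhibitor_uM = series$inhibitor_uM, rate = series$rate)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an assay panel CSV
#' @param path CSV with the columns of [load_table1_fixture()].
#' @return An `assay_panel`.
#' @export
read_panel_csv <- function(path) {
  df <- read_validated_csv(path,
    required = c("compound", "scaffold", "activity_pct", "activity_sd",
                 "score_wt", "score_r88c", "score_v400m", "score_a433e",
                 "kb_uM", "itc_status"),
    numeric_cols = c("activity_pct", "activity_sd", "score_wt", "score_r88c",
                     "score_v400m", "score_a433e", "kb_uM", "itc_kd_uM"))
  rejects <- attr(df, "rejects")
  out <- as_assay_panel(df)
  attr(out, "rejects") <- rejects
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the triage cascade with defaults matching the
#' packaged screen's documented choices.
#'
#' @param panel_csv Assay-panel CSV; default is the packaged 25-compound
#'   panel.
#' @param poses_csv Optional docked-pose table (`compound_id`, `score`,
#'   `heavy_atoms`).
#' @param docking_cutoff Intermolecular docking-score threshold.
#' @param kb_cutoff Quenching-constant binder threshold (uM).
#' @param activity_change,activity_floor Lead-rule activity thresholds (%).
#' @param score_min Combined stability-score threshold.
#' @param require_significance Require significant activity change.
#' @param alpha,n_replicates Significance test settings.
#' @param cluster_threshold Tanimoto threshold for clustering.
#' @param temperature_K Calorimetry temperature.
#' @param include_biphasic Include biphasic-profile variants in combined
#'   scoring (default FALSE; such variants are scored separately).
#' @param itc_drop_first Discard each run's first injection.
#' @param seed Master seed; stage-local seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(panel_csv = NULL, poses_csv = NULL,
                            docking_cutoff = -18.0, kb_cutoff = 100,
                            activity_change = 25, activity_floor = 10,
                            score_min = 3, require_significance = TRUE,
                            alpha = 0.05, n_replicates = 3L,
                            cluster_threshold = 0.7, temperature_K = 293.15,
                            include_biphasic = FALSE, itc_drop_first = FALSE,
                            seed = 1L) {
  cfg <- list(panel_csv = panel_csv, poses_csv = poses_csv,
              docking_cutoff = docking_cutoff, kb_cutoff = kb_cutoff,
              activity_change = activity_change,
              activity_floor = activity_floor, score_min = score_min,
              require_significance = require_significance, alpha = alpha,
              n_replicates = n_replicates,
              cluster_threshold = cluster_threshold,
              temperature_K = temperature_K,
              include_biphasic = include_biphasic,
              itc_drop_first = itc_drop_first, seed = as.integer(seed))
  num <- unlist(cfg[c("docking_cutoff", "kb_cutoff", "activity_change",
                      "activity_floor", "score_min", "alpha",
                      "cluster_threshold", "temperature_K")])
  if (any(!is.finite(num))) stop_pct("all thresholds must be finite")
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[order(names(unclass(config)))], file = tmp)
  unname(tools::md5sum(tmp))
}

#' Run the triage cascade end to end
#'
#' Executes the stages in cascade order — docking-pose filtering (when a
#' pose table is configured), panel loading, per-compound combined stability
#' scores and significance, binding evidence, and the lead-selection rule —
#' logging per-stage counts, and returns a deterministic report.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return A `triage_report`: list with `table` (per-compound summary with
#'   lead flag and failed criteria), `leads`, `stage_counts`, and `metadata`
#'   (config hash, seed, package version).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  counts <- list()

  if (!is.null(config$poses_csv)) {
    poses <- read_validated_csv(config$poses_csv,
      required = c("compound_id", "score", "heavy_atoms"),
      numeric_cols = c("score", "heavy_atoms"))
    ranked <- rank_poses(poses, config$docking_cutoff)
    counts$poses_in <- nrow(poses)
    counts$poses_kept <- nrow(ranked)
    say("docking filter: ", nrow(ranked), "/", nrow(poses), " poses kept")
  }

  panel <- if (is.null(config$panel_csv)) load_table1_fixture()
           else read_panel_csv(config$panel_csv)
  counts$panel <- nrow(panel)
  say("panel: ", nrow(panel), " compounds")

  combined <- rowSums(panel_scores(panel))
  sig <- activity_significance(panel$activity_pct, panel$activity_sd,
                               n = config$n_replicates,
                               alpha = config$alpha)$significant
  binding <- (!is.na(panel$itc_kd_uM) & panel$itc_status == "measured") |
    (!is.na(panel$kb_uM) & panel$kb_uM < config$kb_cutoff)
  counts$stability_hits <- sum(combined > config$score_min)
  counts$binders <- sum(binding)
  say("stability score > ", config$score_min, ": ", counts$stability_hits,
      "; binding evidence: ", counts$binders)

  leads <- select_leads(panel,
                        activity_change = config$activity_change,
                        score_min = config$score_min,
                        kb_cutoff = config$kb_cutoff,
                        activity_floor = config$activity_floor,
                        require_significance = config$require_significance,
                        alpha = config$alpha,
                        n_replicates = config$n_replicates)
  audit <- attr(leads, "audit")
  counts$leads <- length(leads)
  say("leads: ", paste(leads, collapse = ", "))

  tab <- data.frame(compound = panel$compound, scaffold = panel$scaffold,
                    activity_pct = panel$activity_pct,
                    activity_sd = panel$activity_sd,
                    combined_score = combined,
                    kb_uM = panel$kb_uM, itc_kd_uM = panel$itc_kd_uM,
                    itc_status = panel$itc_status,
                    activity_significant = sig, binding_evidence = binding,
                    lead = panel$compound %in% leads,
                    failed_criteria = audit$failed_criteria[
                      match(panel$compound, audit$compound)])
  structure(list(table = tab, leads = as.character(leads),
                 stage_counts = counts,
                 metadata = list(config_hash = config_hash(config),
                                 seed = config$seed,
                                 package_version =
                                   as.character(utils::packageVersion("pctriage")))),
            class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  cat("Triage report (", nrow(x$table), " compounds)\n", sep = "")
  cat("  leads:", if (length(x$leads)) paste(x$leads, collapse = ", ")
      else "(none)", "\n")
  cat("  stage counts:",
      paste(names(x$stage_counts), unlist(x$stage_counts), sep = " = ",
            collapse = ", "), "\n")
  cat("  config:", x$metadata$config_hash, " seed:", x$metadata$seed, "\n")
  invisible(x)
}

#' Write a triage report
#'
#' Writes the per-compound table as CSV and the leads/audit/metadata as
#' JSON next to it.
#'
#' @param report A `triage_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_triage_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "triage_table.csv")
  js <- file.path(out_dir, "triage_report.json")
  utils::write.csv(report$table, csv, row.names = FALSE)
  jsonlite::write_json(list(leads = report$leads,
                            stage_counts = report$stage_counts,
                            metadata = report$metadata),
                       js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv, js))
}
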