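# In-silico triage: pharmacophore restraints, docking-score ranking,
# property and substructure filters, fingerprint clustering, analogue
# search, site geometry, solubility and the multi-assay lead-selection rule.

#' Define a pharmacophore model
#'
#' @param points Data frame with columns `feature_type` (`"HBA"` or
#'   `"hydrophobic"`), `x`, `y`, `z` (Angstrom) and `radius` (Angstrom, > 0).
#' @param mandatory_count How many points a pose must satisfy to pass;
#'   defaults to all of them (fully mandatory restraints).
#' @return A `pharmacophore_model`.
#' @export
pharmacophore_model <- function(points, mandatory_count = nrow(points)) {
  required <- c("feature_type", "x", "y", "z", "radius")
  if (!nrow(points)) stop_pct("pharmacophore model must have at least one point")
  missing <- setdiff(required, names(points))
  if (length(missing)) stop_pct("points missing column(s): ",
                                paste(missing, collapse = ", "))
  if (any(points$radius <= 0)) stop_pct("radii must be positive")
  if (mandatory_count > nrow(points)) {
    stop_pct("mandatory_count exceeds the number of points")
  }
  structure(list(points = points, mandatory_count = mandatory_count),
            class = "pharmacophore_model")
}

#' Check a docked pose against a pharmacophore model
#'
#' A model point is satisfied when at least one pose feature of the matching
#' type lies within its radius. The pose passes when the number of satisfied
#' points reaches the model's mandatory count.
#'
#' @param pose_features Data frame with columns `feature_type`, `x`, `y`,
#'   `z` for the pose's typed feature coordinates (Angstrom).
#' @param model A [pharmacophore_model()].
#' @return List with `satisfied_count` and `pass`.
#' @export
check_pharmacophore <- function(pose_features, model) {
  stopifnot(inherits(model, "pharmacophore_model"))
  pts <- model$points
  satisfied <- vapply(seq_len(nrow(pts)), function(j) {
    feats <- pose_features[pose_features$feature_type == pts$feature_type[j], ,
                           drop = FALSE]
    if (!nrow(feats)) return(FALSE)
    d2 <- (feats$x - pts$x[j])^2 + (feats$y - pts$y[j])^2 +
      (feats$z - pts$z[j])^2
    any(d2 <= pts$radius[j]^2)
  }, logical(1))
  list(satisfied_count = sum(satisfied),
       pass = sum(satisfied) >= model$mandatory_count)
}

#' Filter and rank docked poses by normalised score
#'
#' Retains poses with an intermolecular docking score below `score_cutoff`
#' (more negative is better) and orders them by normalised score
#' (intermolecular score divided by the number of non-hydrogen atoms),
#' ascending, with ties broken by compound id so the ranking is invariant to
#' input order.
#'
#' @param poses Data frame with columns `compound_id`, `score` and
#'   `heavy_atoms` (or a precomputed `normalized_score`).
#' @param score_cutoff Intermolecular score threshold (default -18.0, strict
#'   `<`).
#' @return The retained poses, ranked, with a `normalized_score` column.
#' @export
rank_poses <- function(poses, score_cutoff = -18.0) {
  if (any(!is.finite(poses$score))) stop_pct("scores must be finite")
  if (!"normalized_score" %in% names(poses)) {
    if (!"heavy_atoms" %in% names(poses)) {
      stop_pct("poses need a heavy_atoms (or normalized_score) column")
    }
    if (any(poses$heavy_atoms < 1)) stop_pct("heavy_atoms must be >= 1")
    poses$normalized_score <- poses$score / poses$heavy_atoms
  }
  kept <- poses[poses$score < score_cutoff, , drop = FALSE]
  kept <- kept[order(kept$normalized_score, kept$compound_id), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Interval-based drug-likeness property filter
#'
#' Each rule is `c(min, max)` (use `-Inf`/`Inf` for one-sided bounds) tested
#' against a descriptor of the same name. A compound passes when every
#' evaluable mandatory rule passes; missing descriptors leave the rule
#' `"unevaluated"` (failing the compound unless the rule is listed in
#' `optional`).
#'
#' @param descriptors Named list/vector of descriptor values (e.g. `MW`,
#'   `logP`, `HBA`, `HBD`, `rotatable_bonds`, `TPSA`, `logS`).
#' @param rules Named list of `c(min, max)` intervals.
#' @param optional Character vector of rule names that may go unevaluated.
#' @return List with `pass`, `failed_rules`, `unevaluated`.
#' @export
property_filter <- function(descriptors, rules, optional = character()) {
  if (!length(rules)) stop_pct("no rules supplied")
  failed <- character()
  uneval <- character()
  for (nm in names(rules)) {
    val <- descriptors[[nm]]
    if (is.null(val) || is.na(val)) {
      uneval <- c(uneval, nm)
      next
    }
    r <- rules[[nm]]
    if (val < r[1] || val > r[2]) failed <- c(failed, nm)
  }
  hard_uneval <- setdiff(uneval, optional)
  list(pass = !length(failed) && !length(hard_uneval),
       failed_rules = failed, unevaluated = uneval)
}

#' Flag compounds matching substructure alert patterns
#'
#' Screens SMILES against SMARTS alert patterns (reactive-group and
#' frequent-hitter style rules). Compounds are flagged, never auto-rejected;
#' rejection is a downstream policy decision. Unparsable structures are
#' reported per record and do not stop the scan.
#'
#' @param smiles Named character vector of SMILES (names are compound ids).
#' @param patterns Named character vector of SMARTS patterns.
#' @return List with `flags` (logical matrix, compounds x patterns) and
#'   `errors` (named character vector of per-compound parse errors).
#' @export
substructure_flags <- function(smiles, patterns) {
  ids <- names(smiles) %||% paste0("cmp", seq_along(smiles))
  flags <- matrix(FALSE, length(smiles), length(patterns),
                  dimnames = list(ids, names(patterns)))
  errors <- character()
  for (k in seq_along(smiles)) {
    sdf <- tryCatch(suppressWarnings(
      ChemmineR::smiles2sdf(stats::setNames(smiles[k], ids[k]))),
      error = function(e) NULL)
    if (is.null(sdf) || !length(sdf)) {
      errors[ids[k]] <- "unparsable structure"
      next
    }
    for (p in seq_along(patterns)) {
      hit <- tryCatch(
        ChemmineR::smartsSearchOB(sdf, patterns[[p]], uniqueMatches = FALSE),
        error = function(e) NA_integer_)
      if (is.na(hit[1])) {
        errors[ids[k]] <- "pattern match failed"
      } else {
        flags[k, p] <- hit[1] > 0
      }
    }
  }
  list(flags = flags, errors = errors)
}

#' MACCS-style structural-key fingerprints from SMILES
#'
#' Computes structural-key bit vectors with OpenBabel's MACCS key definition
#' (via ChemmineR). The scheme is pluggable: every similarity and clustering
#' function in the package accepts plain 0/1 vectors of any fixed length.
#'
#' @param smiles Named character vector of SMILES.
#' @return A 0/1 integer matrix, one row per compound.
#' @export
fingerprint_from_smiles <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(smiles)
  fp <- ChemmineR::fingerprintOB(sdf, "MACCS")
  m <- as.matrix(fp)
  storage.mode(m) <- "integer"
  rownames(m) <- names(smiles) %||% rownames(m)
  m
}

#' Tanimoto similarity of two bit vectors
#'
#' `|a AND b| / |a OR b|`; defined as 0 when both vectors are empty.
#'
#' @param fp_a,fp_b Equal-length 0/1 (or logical) vectors.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) stop_pct("fingerprint lengths differ")
  a <- as.logical(fp_a)
  b <- as.logical(fp_b)
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

# Pairwise Tanimoto matrix for a 0/1 row-matrix, via bit-count algebra.
tanimoto_matrix <- function(fps) {
  m <- as.matrix(fps) * 1
  common <- tcrossprod(m)
  counts <- diag(common)
  un <- outer(counts, counts, "+") - common
  sim <- ifelse(un == 0, 0, common / un)
  diag(sim) <- ifelse(counts == 0, 0, 1)
  sim
}

#' Leader-style (sphere-exclusion) fingerprint clustering
#'
#' Classic sphere-exclusion clustering: compounds are ranked by how many
#' neighbours they have at or above the similarity threshold; the
#' best-connected unassigned compound becomes a cluster leader and captures
#' its unassigned neighbours; repeat. Deterministic for a fixed input order
#' (ties broken by input position).
#'
#' @param fps 0/1 matrix, one fingerprint per row.
#' @param threshold Tanimoto similarity defining neighbourhood (default 0.7).
#' @return Integer vector of cluster ids (1 = first-formed cluster), one per
#'   input row; leaders carry attribute `"leaders"`.
#' @export
cluster_library <- function(fps, threshold = 0.7) {
  n <- nrow(fps)
  if (is.null(n) || n == 0) stop_pct("need at least one fingerprint")
  sim <- tanimoto_matrix(fps)
  neigh <- sim >= threshold
  diag(neigh) <- FALSE
  assigned <- rep(NA_integer_, n)
  leaders <- integer()
  cl <- 0L
  while (anyNA(assigned)) {
    open <- which(is.na(assigned))
    counts <- vapply(open, function(j) sum(neigh[j, open]), integer(1))
    leader <- open[which.max(counts)]   # ties -> earliest input position
    cl <- cl + 1L
    members <- open[neigh[leader, open]]
    assigned[c(leader, members)] <- cl
    leaders <- c(leaders, leader)
  }
  structure(assigned, leaders = leaders)
}

#' Analogue search by catalogue
#'
#' Retrieves library compounds whose best Tanimoto similarity to any
#' confirmed hit reaches `similarity_cutoff`, ranked by that similarity
#' (ties by library position).
#'
#' @param hit_fps,library_fps 0/1 fingerprint matrices in the same scheme.
#' @param similarity_cutoff Minimum max-over-hits similarity (default 0.7).
#' @return Data frame `library_index`, `best_hit`, `similarity`, ranked.
#' @export
sar_by_catalogue <- function(hit_fps, library_fps, similarity_cutoff = 0.7) {
  hit_fps <- rbind(hit_fps)
  library_fps <- rbind(library_fps)
  if (ncol(hit_fps) != ncol(library_fps)) {
    stop_pct("fingerprint schemes differ in length")
  }
  sims <- apply(library_fps, 1L, function(lf) {
    vapply(seq_len(nrow(hit_fps)), function(h) tanimoto(hit_fps[h, ], lf),
           numeric(1))
  })
  sims <- matrix(sims, nrow = nrow(hit_fps))   # hits x library
  best <- apply(sims, 2L, max)
  which_hit <- apply(sims, 2L, which.max)
  keep <- which(best >= similarity_cutoff)
  out <- data.frame(library_index = keep, best_hit = which_hit[keep],
                    similarity = best[keep])
  out <- out[order(-out$similarity, out$library_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse a prose residue list into a site definition
#'
#' Extracts residue tokens of the form `Xaa123` (three-letter code plus
#' sequence number) from free text, e.g. the residue list of a reported
#' binding site.
#'
#' @param text Character string naming residues.
#' @return A `site_definition`: data frame with `resname`, `resno`.
#' @export
parse_residue_list <- function(text) {
  m <- regmatches(text, gregexpr("[A-Z][a-z]{2}\\s?[0-9]+", text))[[1]]
  if (!length(m)) stop_pct("no residue tokens found")
  resname <- sub("\\s?[0-9]+$", "", m)
  resno <- as.integer(sub("^[A-Z][a-z]{2}\\s?", "", m))
  site_definition(data.frame(resname = resname, resno = resno))
}

#' Construct a site definition
#'
#' @param residues Data frame with `resname` and `resno`, optionally `x`,
#'   `y`, `z` coordinates (Angstrom, e.g. C-alpha positions).
#' @return A `site_definition`.
#' @export
site_definition <- function(residues) {
  if (!nrow(residues)) stop_pct("site must contain at least one residue")
  stopifnot(all(c("resname", "resno") %in% names(residues)))
  structure(residues, class = c("site_definition", "data.frame"))
}

#' Attach coordinates to a site definition from a PDB file
#'
#' Reads C-alpha coordinates for the site's residue numbers from a PDB file
#' (via bio3d).
#'
#' @param site A [site_definition()].
#' @param pdb_path Path to a PDB file.
#' @param chain Chain identifier (default first chain).
#' @return The site with `x`, `y`, `z` columns filled.
#' @export
site_coords_from_pdb <- function(site, pdb_path, chain = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop_pct("bio3d is required to read PDB coordinates")
  }
  pdb <- bio3d::read.pdb(pdb_path)
  atoms <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  if (!is.null(chain)) atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  idx <- match(site$resno, atoms$resno)
  if (anyNA(idx)) {
    stop_pct("residue(s) absent from PDB: ",
             paste(site$resno[is.na(idx)], collapse = ", "))
  }
  site$x <- atoms$x[idx]
  site$y <- atoms$y[idx]
  site$z <- atoms$z[idx]
  site
}

#' Number of residues in a site definition
#' @param site A [site_definition()].
#' @export
site_residue_count <- function(site) nrow(site)

#' Distance between the centroids of two sites
#'
#' Euclidean distance between the unweighted residue-coordinate centroids.
#'
#' @param site_a,site_b [site_definition()]s with `x`, `y`, `z` columns.
#' @return Distance in Angstrom.
#' @export
centroid_distance <- function(site_a, site_b) {
  for (s in list(site_a, site_b)) {
    if (!nrow(s)) stop_pct("site is empty")
    if (!all(c("x", "y", "z") %in% names(s))) {
      stop_pct("sites need x/y/z coordinates")
    }
  }
  ca <- colMeans(site_a[, c("x", "y", "z")])
  cb <- colMeans(site_b[, c("x", "y", "z")])
  sqrt(sum((ca - cb)^2))
}

#' The reported 18-residue allosteric site of GCDH
#'
#' The allosteric pocket targeted by the packaged screen, located where the
#' two alpha-helical bundle domains of the GCDH monomer converge (behind the
#' active site), defined by 18 residues of the full-length sequence.
#'
#' @return A [site_definition()] with 18 residues (no coordinates; attach
#'   them from a structure with [site_coords_from_pdb()]).
#' @export
gcdh_allosteric_site <- function() {
  parse_residue_list(paste(
    "Gly107, Pro108, Thr109, Ile110, Ser120, Tyr123, Ser145, Ser146,",
    "Met149, His150, Asn291, Asn292, Tyr295, Leu353, Gly354, Lys357,",
    "Ala362, and Val367"))
}

#' Apparent solubility from LC-MS peak areas
#'
#' `S = std_conc * (area_sample / area_std) * (inj_vol_std / inj_vol_sample)
#' * DF`, the standard single-point LC-MS quantification against a known
#' calibration standard with a dilution factor.
#'
#' @param area_sample,area_std Peak areas (sample and standard), > 0.
#' @param inj_vol_sample,inj_vol_std Injection volumes (uL), > 0.
#' @param df Dilution factor.
#' @param std_conc Standard concentration (uM).
#' @return Apparent solubility (uM).
#' @export
solubility_from_lcms <- function(area_sample, area_std, inj_vol_sample,
                                 inj_vol_std, df = 1, std_conc = 10) {
  if (any(area_std <= 0)) stop_pct("standard peak area must be positive")
  if (any(c(area_sample, inj_vol_sample, inj_vol_std) <= 0)) {
    stop_pct("areas and injection volumes must be positive")
  }
  std_conc * (area_sample / area_std) * (inj_vol_std / inj_vol_sample) * df
}

#' Multi-assay lead selection
#'
#' Applies the documented lead rule to an assay panel: an activity change of
#' more than `activity_change` percentage points from the vehicle control
#' (significant by a one-sample t-test when `require_significance`), a
#' summed per-variant stability score above `score_min`, binding evidence
#' (a measured calorimetric Kd or a quenching constant below `kb_cutoff`),
#' and residual activity of at least `activity_floor` percent — the floor
#' excludes near-total inhibitors, which cannot act as chaperones however
#' well they bind.
#'
#' @param panel An `assay_panel` (see [load_table1_fixture()]).
#' @param activity_change Minimum |relative activity - 100| (percentage
#'   points, strict `>`).
#' @param score_min Combined stability score threshold (strict `>`).
#' @param kb_cutoff Quenching-constant threshold (uM, strict `<`).
#' @param activity_floor Minimum residual activity (% of control).
#' @param require_significance Require the activity change to be
#'   statistically significant.
#' @param alpha,n_replicates t-test level and replicate count for panels that
#'   carry only mean +/- SD.
#' @return Character vector of selected compound ids (sorted), with the full
#'   per-criterion audit table as attribute `"audit"`: one row per compound,
#'   one logical column per criterion, and `failed_criteria` naming every
#'   criterion each excluded compound failed.
#' @export
#' @examples
#' leads <- select_leads(load_table1_fixture())
#' leads
#' head(attr(leads, "audit"))
select_leads <- function(panel, activity_change = 25, score_min = 3,
                         kb_cutoff = 100, activity_floor = 10,
                         require_significance = TRUE, alpha = 0.05,
                         n_replicates = 3L) {
  panel <- as_assay_panel(panel)
  if (!nrow(panel)) {
    return(structure(character(), audit = data.frame()))
  }
  combined <- rowSums(panel_scores(panel))
  sig <- activity_significance(panel$activity_pct, panel$activity_sd,
                               n = n_replicates, alpha = alpha)$significant
  crit <- data.frame(
    compound = panel$compound,
    activity_change = abs(panel$activity_pct - 100) > activity_change,
    activity_significant = if (require_significance) sig else TRUE,
    stability = combined > score_min,
    binding = (!is.na(panel$itc_kd_uM) & panel$itc_status == "measured") |
      (!is.na(panel$kb_uM) & panel$kb_uM < kb_cutoff),
    activity_floor = panel$activity_pct >= activity_floor)
  pass_cols <- setdiff(names(crit), "compound")
  crit$lead <- Reduce(`&`, crit[pass_cols])
  crit$failed_criteria <- vapply(seq_len(nrow(crit)), function(r) {
    paste(pass_cols[!unlist(crit[r, pass_cols])], collapse = ",")
  }, character(1))
  leads <- sort(crit$compound[crit$lead])
  structure(leads, audit = crit)
}

#' Spearman rank correlation with a permutation test
#'
#' @param x,y Paired numeric vectors.
#' @param n_perm Number of random permutations (ignored when `exact`).
#' @param seed Seed for the permutation draw.
#' @param exact Enumerate all `length(x)!` permutations (feasible for
#'   `n <= 8`) for an exact p-value.
#' @return List with `rho` and two-sided `p` (`NA` with a reason when either
#'   vector is constant).
#' @export
spearman_perm <- function(x, y, n_perm = 10000L, seed = 1L, exact = FALSE) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, reason = "constant column"))
  }
  rho_obs <- stats::cor(x, y, method = "spearman")
  if (exact) {
    if (length(x) > 8L) stop_pct("exact enumeration limited to n <= 8")
    perms <- permutations_of(length(y))
    rhos <- apply(perms, 1L, function(p) stats::cor(x, y[p],
                                                    method = "spearman"))
    p <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  } else {
    rhos <- with_seed(seed, replicate(n_perm,
      stats::cor(x, sample(y), method = "spearman")))
    p <- (1 + sum(abs(rhos) >= abs(rho_obs) - 1e-12)) / (n_perm + 1)
  }
  list(rho = rho_obs, p = p)
}

# all permutations of 1..n as a matrix (n! rows); recursion is fine for the
# small n used in exact tests
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Rank correlation of solubility against assay effects
#'
#' Tests whether apparent solubility explains the measured effects: Spearman
#' correlation with a seeded permutation p-value per assay column.
#'
#' @param panel Data frame with a solubility column and effect columns.
#' @param solubility_col Name of the solubility column.
#' @param effect_cols Names of the assay-effect columns.
#' @param n_perm,seed,exact Passed to [spearman_perm()].
#' @return Data frame with `assay`, `rho`, `p`, `n` (complete pairs).
#' @export
correlate_solubility_effects <- function(panel, solubility_col = "solubility_uM",
                                         effect_cols, n_perm = 10000L,
                                         seed = 1L, exact = FALSE) {
  res <- lapply(effect_cols, function(col) {
    ok <- stats::complete.cases(panel[[solubility_col]], panel[[col]])
    if (sum(ok) < 5L) {
      return(data.frame(assay = col, rho = NA_real_, p = NA_real_,
                        n = sum(ok)))
    }
    sp <- spearman_perm(panel[[solubility_col]][ok], panel[[col]][ok],
                        n_perm = n_perm, seed = seed, exact = exact)
    data.frame(assay = col, rho = sp$rho, p = sp$p, n = sum(ok))
  })
  do.call(rbind, res)
}
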