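# In-silico triage: pharmacophore, ranking, filters, fingerprints,
# clustering, site geometry, solubility, lead selection, correlations.

test_that("pharmacophore restraints count satisfied points", {
  model <- example_pharmacophore()
  exact <- data.frame(feature_type = model$points$feature_type,
                      x = model$points$x, y = model$points$y,
                      z = model$points$z)
  res <- check_pharmacophore(exact, model)
  expect_equal(res$satisfied_count, 4)
  expect_true(res$pass)
  displaced <- exact
  displaced$x[2] <- displaced$x[2] + 5  # beyond its 1.5 A radius
  res2 <- check_pharmacophore(displaced, model)
  expect_equal(res2$satisfied_count, 3)
  expect_false(res2$pass)
  expect_error(pharmacophore_model(data.frame()), "at least one")
})

test_that("pharmacophore counts equal the brute-force all-pairs oracle", {
  model <- example_pharmacophore(radius = 2)
  set.seed(7)
  for (k in 1:1000) {
    pose <- random_pose(model$points)
    expect_identical(check_pharmacophore(pose, model)$satisfied_count,
                     brute_pharmacophore_count(pose, model$points))
  }
})

test_that("pose ranking filters on raw score and orders by normalised score", {
  poses <- data.frame(compound_id = c("c1", "c2"),
                      score = c(-18.5, -17.0), heavy_atoms = c(20, 20))
  expect_equal(rank_poses(poses)$compound_id, "c1")
  p2 <- data.frame(compound_id = "x", score = -20, heavy_atoms = 25)
  expect_equal(rank_poses(p2)$normalized_score, -0.8)
  # equal normalised scores: stable order by compound id, invariant to input order
  tie <- data.frame(compound_id = c("b", "a"), score = c(-20, -20),
                    heavy_atoms = c(10, 10))
  expect_equal(rank_poses(tie)$compound_id, c("a", "b"))
  expect_equal(rank_poses(tie[2:1, ])$compound_id, c("a", "b"))
})

test_that("property filter equals the per-rule brute-force AND", {
  rules <- list(MW = c(0, 500), logP = c(-2, 5), HBA = c(0, 10),
                HBD = c(0, 5), TPSA = c(0, 140))
  good <- list(MW = 320, logP = 2.1, HBA = 4, HBD = 1, TPSA = 75)
  expect_true(property_filter(good, rules)$pass)
  heavy <- good; heavy$MW <- 612
  res <- property_filter(heavy, rules)
  expect_false(res$pass)
  expect_equal(res$failed_rules, "MW")
  nolog <- good; nolog$logP <- NULL
  expect_false(property_filter(nolog, rules)$pass)
  expect_true(property_filter(nolog, rules, optional = "logP")$pass)
  set.seed(3)
  lib <- replicate(40, list(MW = runif(1, 100, 700),
                            logP = runif(1, -4, 8), HBA = sample(0:14, 1),
                            HBD = sample(0:8, 1), TPSA = runif(1, 0, 220)),
                   simplify = FALSE)
  for (cmp in lib) {
    brute <- all(vapply(names(rules), function(nm)
      cmp[[nm]] >= rules[[nm]][1] && cmp[[nm]] <= rules[[nm]][2],
      logical(1)))
    expect_identical(property_filter(cmp, rules)$pass, brute)
  }
})

test_that("substructure alerts flag matching compounds and survive bad input", {
  smi <- c(benzene = "c1ccccc1", nitrobenzene = "c1ccccc1[N+](=O)[O-]",
           aldehyde = "CC=O", broken = "C1CC")
  pats <- c(nitro = "[N+](=O)[O-]", aldehyde = "[CX3H1]=O")
  res <- substructure_flags(smi, pats)
  expect_false(res$flags["benzene", "nitro"])
  expect_true(res$flags["nitrobenzene", "nitro"])
  expect_true(res$flags["aldehyde", "aldehyde"])
  expect_false(res$flags["benzene", "aldehyde"])
  expect_true("broken" %in% names(res$errors))
  # per-pattern scan oracle: one compound at a time, same answers
  for (id in c("benzene", "nitrobenzene", "aldehyde")) {
    single <- substructure_flags(smi[id], pats)
    expect_identical(unname(single$flags[1, ]), unname(res$flags[id, ]))
  }
})

test_that("tanimoto similarity obeys its identities", {
  a <- c(1, 1, 0, 1, 0, 1)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, 1 - a), 0)
  expect_equal(tanimoto(c(1, 1, 1, 1, 0), c(1, 1, 0, 0, 0)), 0.5)
  expect_equal(tanimoto(rep(0, 6), rep(0, 6)), 0)
  expect_error(tanimoto(a, a[-1]), "length")
  set.seed(5)
  for (k in 1:50) {
    x <- rbinom(32, 1, 0.4); y <- rbinom(32, 1, 0.4)
    expect_equal(tanimoto(x, y), tanimoto(y, x))
  }
})

test_that("sphere-exclusion clustering matches the naive reference", {
  same <- matrix(rep(c(1, 0, 1, 1), 6), nrow = 6, byrow = TRUE)
  expect_equal(unique(as.integer(cluster_library(same, 0.7))), 1L)
  blocks <- rbind(matrix(rep(c(1, 1, 0, 0), 3), 3, byrow = TRUE),
                  matrix(rep(c(0, 0, 1, 1), 3), 3, byrow = TRUE))
  expect_equal(length(unique(cluster_library(blocks, 0.7))), 2L)
  fps <- random_fps(50, bits = 48, seed = 13)
  for (thr in c(0.5, 0.7)) {
    expect_identical(as.integer(cluster_library(fps, thr)),
                     reference_cluster(fps, thr))
  }
})

test_that("analogue search retrieves by max-over-hits similarity", {
  lib <- random_fps(30, bits = 48, seed = 2)
  hits <- lib[c(4, 18), , drop = FALSE]
  res <- sar_by_catalogue(hits, lib, similarity_cutoff = 0.99)
  expect_true(all(c(4, 18) %in% res$library_index))
  expect_equal(res$similarity[res$library_index == 4], 1)
  expect_equal(nrow(sar_by_catalogue(hits, lib, similarity_cutoff = 1.01)), 0)
  # brute-force all-pairs oracle at a permissive cutoff
  res2 <- sar_by_catalogue(hits, lib, similarity_cutoff = 0.3)
  brute <- sapply(seq_len(nrow(lib)), function(j)
    max(tanimoto(hits[1, ], lib[j, ]), tanimoto(hits[2, ], lib[j, ])))
  expect_setequal(res2$library_index, which(brute >= 0.3))
  expect_equal(res2$similarity, sort(brute[brute >= 0.3], decreasing = TRUE))
})

test_that("site utilities parse residue lists and measure centroid geometry", {
  site <- gcdh_allosteric_site()
  expect_equal(site_residue_count(site), 18)
  expect_equal(site$resno[1], 107L)
  expect_equal(site$resname[site$resno == 367], "Val")
  a <- site_definition(data.frame(resname = "Gly", resno = 1,
                                  x = 0, y = 0, z = 0))
  b <- site_definition(data.frame(resname = "Ala", resno = 2,
                                  x = 3, y = 4, z = 0))
  expect_equal(centroid_distance(a, b), 5)
  expect_equal(centroid_distance(a, a), 0)
  expect_error(site_definition(data.frame()), "at least one")
})

test_that("site coordinates can be read from a PDB file", {
  skip_if_not_installed("bio3d")
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, c(0, 3, 6), c(0, 4, 8), c(0, 0, 0)),
    "END"), pdb)
  site <- site_definition(data.frame(resname = c("Gly", "Gly"),
                                     resno = c(1, 3)))
  got <- site_coords_from_pdb(site, pdb)
  expect_equal(got$x, c(0, 6))
  expect_equal(got$y, c(0, 8))
  unlink(pdb)
})

test_that("solubility follows the LC-MS area-ratio formula", {
  expect_equal(solubility_from_lcms(100, 100, 5, 5, df = 1, std_conc = 10), 10)
  expect_equal(solubility_from_lcms(50, 100, 5, 5, df = 1, std_conc = 10), 5)
  expect_equal(solubility_from_lcms(50, 100, 5, 5, df = 10, std_conc = 10), 50)
  expect_equal(solubility_from_lcms(100, 100, 2, 5, df = 1, std_conc = 10), 25)
  expect_error(solubility_from_lcms(100, 0, 5, 5), "positive")
})

test_that("the lead rule reproduces the published five leads with audit", {
  panel <- load_table1_fixture()
  leads <- select_leads(panel)
  expect_equal(as.character(leads), c("A49", "A55", "A71", "B29", "B31"))
  audit <- attr(leads, "audit")
  expect_true(all(audit$failed_criteria[audit$lead] == ""))
  excluded <- audit[!audit$lead, ]
  expect_true(all(nchar(excluded$failed_criteria) > 0))
  # near-total inhibition is excluded by the activity floor, not by binding
  expect_match(audit$failed_criteria[audit$compound == "B49"],
               "activity_floor")
  # a compound failing only binding reports exactly that criterion
  one <- panel[panel$compound == "A34", , drop = FALSE]
  res <- select_leads(one)
  expect_length(res, 0)
  expect_equal(attr(res, "audit")$failed_criteria, "binding")
  empty <- panel[0, , drop = FALSE]
  expect_length(select_leads(empty), 0)
})

test_that("solubility correlation uses a permutation test that matches enumeration", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_perm(x, x * 2)$rho, 1)
  expect_equal(spearman_perm(x, -x)$rho, -1)
  set.seed(44)
  y <- rnorm(6)
  exact <- spearman_perm(x, y, exact = TRUE)
  sampled <- spearman_perm(x, y, n_perm = 10000, seed = 8)
  expect_equal(sampled$p, exact$p, tolerance = 0.02)
  const <- spearman_perm(rep(1, 6), y)
  expect_true(is.na(const$rho))
  expect_equal(const$reason, "constant column")
  panel <- data.frame(solubility_uM = c(5, 1, 40, 12, 80, 3),
                      dtm = c(1, 0.5, 3, 2, 6, 0.7))
  res <- correlate_solubility_effects(panel, "solubility_uM", "dtm",
                                      n_perm = 2000, seed = 2)
  expect_equal(res$rho, 1)
})
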