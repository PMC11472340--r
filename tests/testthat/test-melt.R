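# Melt-curve fitting, thermal shifts and the scoring rubric.

test_that("noiseless melt curves are recovered exactly", {
  tr <- ground_truth("melt", list(tm = 45, w = 1.2, f_pre = 1, f_post = 5))
  fit <- fit_melt_curve(gen_melt_curve(tr, melt_grid()))
  expect_true(fit$converged)
  expect_equal(fit$tm, 45, tolerance = 0.01 / 45)
  expect_equal(fit$width, 1.2, tolerance = 1e-4)
  expect_equal(unname(fit$baselines), c(1, 5), tolerance = 1e-3)
})

test_that("fitted Tm of a noisy curve agrees with the exhaustive grid-search oracle", {
  tr <- ground_truth("melt", list(tm = 44.3, w = 1, f_pre = 0, f_post = 4),
                     noise_sd = 0.08, seed = 42)
  cu <- gen_melt_curve(tr, melt_grid())
  fit <- fit_melt_curve(cu)
  oracle <- grid_search_tm(cu$temperature, cu$fluorescence,
                           tm_range = c(40, 50))
  expect_true(fit$converged)
  expect_lt(abs(fit$tm - oracle), 0.05)
})

test_that("biphasic profiles recover both midpoints", {
  tr <- ground_truth("melt",
                     list(tm = 40, tm2 = 52, a1 = 2, a2 = 3, f_pre = 1, w = 1))
  cu <- gen_melt_curve(tr, melt_grid())
  fit <- fit_melt_curve(cu, model = "biphasic")
  expect_true(fit$converged)
  expect_lt(abs(fit$tm - 40), 0.2)
  expect_lt(abs(fit$tm2 - 52), 0.2)
  expect_lt(fit$tm, fit$tm2)
  oracle <- grid_search_tm2(cu$temperature, cu$fluorescence)
  expect_lt(abs(fit$tm - oracle[1]), 0.2)
  expect_lt(abs(fit$tm2 - oracle[2]), 0.2)
})

test_that("curves without a transition never converge", {
  grid <- melt_grid()
  expect_false(fit_melt_curve(melt_curve(grid, rep(2, length(grid))))$converged)
  flat <- fit_melt_curve(melt_curve(grid, rep(2, length(grid))))
  expect_equal(flat$reason, "no transition")
  ramp <- fit_melt_curve(melt_curve(grid, 1 + 0.1 * grid))
  expect_false(ramp$converged)
  expect_equal(ramp$reason, "no transition")
})

test_that("Tm recovery stays accurate across 200 seeded noisy curves", {
  tr0 <- list(tm = 46, w = 1, f_pre = 0, f_post = 4)
  errs <- vapply(1:200, function(k) {
    tr <- ground_truth("melt", tr0, noise_sd = 0.02 * 4, seed = k)
    fit <- fit_melt_curve(gen_melt_curve(tr, melt_grid()))
    if (!fit$converged) return(NA_real_)
    abs(fit$tm - 46)
  }, numeric(1))
  expect_true(all(!is.na(errs)))
  expect_lt(median(errs), 0.2)
})

test_that("delta_tm is a guarded difference of midpoints", {
  mk <- function(tm, protein = "WT") {
    tr <- ground_truth("melt", list(tm = tm, w = 1, f_pre = 0, f_post = 4))
    fit_melt_curve(gen_melt_curve(tr, melt_grid(), protein_label = protein))
  }
  expect_equal(delta_tm(mk(47.5), mk(45)), 2.5, tolerance = 1e-4)
  ref <- mk(45)
  expect_equal(delta_tm(ref, ref), 0)
  expect_equal(delta_tm(mk(42), mk(45)), -3, tolerance = 1e-4)
  expect_error(delta_tm(mk(47, "V400M"), mk(45, "WT")), "labels differ")
})

test_that("the scoring rubric maps shifts to the published bins", {
  expect_identical(score_delta_tm(2.5), 2L)
  expect_identical(score_delta_tm(0.5), 0L)
  expect_identical(score_delta_tm(-3.5), -4L)
  # boundaries take the lower bin (strict inequalities)
  expect_identical(score_delta_tm(c(1, 2, 3, -1, -2, -3)),
                   c(0L, 1L, 2L, 0L, -1L, -2L))
  expect_identical(score_delta_tm(c(1.01, 3.01, -1.01, -3.01)),
                   c(1L, 4L, -1L, -4L))
  expect_error(score_delta_tm(NaN), "finite")
})

test_that("scores combine by summation and by best concentration", {
  expect_equal(combine_scores(c(0, 2, 4, 1)), 7)   # A49
  expect_equal(combine_scores(c(4, 4, 4, 0)), 12)  # B56
  expect_equal(combine_scores(rep(0, 4)), 0)
  expect_identical(as.integer(best_of_concentrations(c(0.5, 1.5, 2.5))), 2L)
  expect_identical(as.integer(best_of_concentrations(c(1.5, 1.5, 1.5))), 1L)
  # mixed signs: the best shift (0) scores 0 even though one dose destabilises
  expect_identical(as.integer(best_of_concentrations(c(-2, 0, 0))), 0L)
})

test_that("dose-dependence of the thermal shift is flagged by rank correlation", {
  expect_true(dose_response_tm(c(0.5, 1.2, 2.4), c(10, 30, 100))$monotone_flag)
  expect_false(dose_response_tm(c(0, 0, 0), c(10, 30, 100))$monotone_flag)
  conc <- c(1, 5, 10, 30, 100, 300)
  sat <- 3 * conc / (conc + 10)      # saturating dose-response
  res <- dose_response_tm(sat, conc)
  expect_true(res$monotone_flag)
  expect_true(res$plateau)
})
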