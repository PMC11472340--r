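# Initial rates, relative activity, MM/4PL fits, inhibition-mode calls.

test_that("initial rate converts absorbance slopes with Beer-Lambert", {
  t <- seq(0, 300, 10)
  r <- initial_rate(t, 1 - (0.006 / 60) * t, epsilon = 1, path_cm = 1)
  expect_equal(as.numeric(r), 0.1, tolerance = 1e-9)
  expect_equal(as.numeric(initial_rate(t, rep(0.5, length(t)), epsilon = 1)), 0)
  # synthetic noisy trace: recovery within 2%
  set.seed(21)
  true_rate <- 0.25  # uM/s at epsilon 1.2, path 0.5
  slope <- true_rate * 1.2 * 0.5 / 1000
  tr <- 1 - slope * t + rnorm(length(t), 0, 2e-4)
  rec <- initial_rate(t, tr, epsilon = 1.2, path_cm = 0.5)
  expect_equal(as.numeric(rec), true_rate, tolerance = 0.02)
  curved <- 1 - slope * t + 5e-7 * t^2
  expect_true(attr(initial_rate(t, curved, epsilon = 1.2, path_cm = 0.5),
                   "low_confidence"))
})

test_that("relative activity reproduces the panel's significance calls", {
  ctrl <- c(1, 1.02, 0.98)
  expect_equal(relative_activity(ctrl, ctrl)$relative_activity, 100)
  expect_error(relative_activity(c(1, 1), c(-1, 1)), "positive")
  # published-style summaries: 135 +/- 59 (n = 3) is not significant,
  # 2.6 +/- 2.3 (n = 3) is a significant decrease
  a41 <- activity_significance(135, 59, n = 3)
  expect_false(a41$significant)
  expect_equal(a41$t, 35 / (59 / sqrt(3)), tolerance = 1e-9)
  b49 <- activity_significance(2.6, 2.3, n = 3)
  expect_true(b49$significant)
  expect_lt(b49$t, 0)
})

test_that("Michaelis-Menten fit recovers the published kinetic constants", {
  sg <- c(0, 0.01, 0.025, 0.05, 0.1, 1, 5, 25, 100, 500, 1000, 1500)
  tr <- ground_truth("rate", list(km = 0.026, vmax = 0.67))
  f <- fit_mm(gen_rate_series(tr, sg))
  expect_equal(f$km, 0.026, tolerance = 1e-6)
  expect_equal(f$vmax, 0.67, tolerance = 1e-6)
  # the fitted curve honours v(Km) = Vmax/2
  expect_equal(predict(f, data.frame(substrate_uM = f$km)), f$vmax / 2,
               tolerance = 1e-9)
})

test_that("noisy MM fit matches the exhaustive grid-search oracle", {
  sg <- c(2, 5, 10, 20, 50, 100, 200)
  tr <- ground_truth("rate", list(km = 20, vmax = 1), noise_sd = 0.02,
                     seed = 17)
  rs <- gen_rate_series(tr, sg)
  f <- fit_mm(rs)
  oracle <- grid_search_mm(rs$substrate_uM, rs$rate,
                           km_grid = seq(5, 60, length.out = 500),
                           vmax_grid = seq(0.5, 1.5, length.out = 500))
  expect_equal(f$km, oracle[1], tolerance = 0.01)
  expect_equal(f$vmax, oracle[2], tolerance = 0.005)
})

test_that("4PL fit recovers the midpoint and handles flat responses", {
  conc <- c(0.25, 0.5, 1, 2, 4, 8, 16, 31.25, 62.5, 125)
  tr <- ground_truth("dose_response",
                     list(ic50 = 18, top = 100, bottom = 0, hill = 1))
  f <- fit_ic50(gen_dose_response(tr, conc))
  expect_equal(f$ic50, 18, tolerance = 1e-6)
  # response at the fitted IC50 is the curve midpoint
  expect_equal(predict(f, data.frame(conc_uM = f$ic50)),
               (f$top + f$bottom) / 2, tolerance = 1e-9)
  flat <- titration_series(conc, rep(100, length(conc)))
  expect_true(fit_ic50(flat)$no_inhibition)
  # recovery bias < 2% across the potency range
  for (ic in c(0.1, 1, 18, 100)) {
    grid <- 10^seq(log10(ic) - 2, log10(ic) + 2, length.out = 9)
    tri <- ground_truth("dose_response",
                        list(ic50 = ic, top = 100, bottom = 0, hill = 1))
    fi <- fit_ic50(gen_dose_response(tri, grid))
    expect_equal(fi$ic50, ic, tolerance = 0.02)
  }
})

test_that("global inhibition fit identifies the mode and its constants", {
  sg <- c(1, 2, 5, 10, 20, 50, 100, 200)
  # competitive: apparent Km obeys Km(1 + I/Ki); Vmax untouched
  tr <- ground_truth("rate", list(km = 10, vmax = 1, ki = 5))
  rs <- gen_rate_series(tr, sg, c(0, 2.5, 5, 10), model = "competitive")
  g <- fit_inhibition_global(rs)
  expect_equal(g$mode, "competitive")
  for (i in c(2.5, 5, 10)) {
    app <- fit_mm(rs[rs$inhibitor_uM == i, ])
    expect_equal(app$km, g$km * (1 + i / g$ki), tolerance = 0.03)
  }
  # noncompetitive: apparent Vmax halves at I = Ki
  trn <- ground_truth("rate", list(km = 10, vmax = 0.2, ki = 5))
  rsn <- gen_rate_series(trn, sg, c(0, 5), model = "noncompetitive")
  gn <- fit_inhibition_global(rsn)
  expect_equal(gn$mode, "noncompetitive")
  appn <- fit_mm(rsn[rsn$inhibitor_uM == 5, ])
  expect_equal(appn$vmax, 0.1, tolerance = 1e-4)
  # no inhibitor effect selects the plain MM model
  tr0 <- ground_truth("rate", list(km = 10, vmax = 1))
  rs0 <- gen_rate_series(tr0, sg, c(0, 5, 10), model = "none")
  expect_equal(fit_inhibition_global(rs0)$mode, "none")
  expect_error(fit_inhibition_global(gen_rate_series(tr0, sg, 0)),
               "at least 2 inhibitor")
})

test_that("rule-based classification matches the reported parameter trends", {
  mk <- function(km, vmax) structure(list(km = km, vmax = vmax),
                                     class = "mm_fit")
  # constant Km with falling Vmax (0.2 -> 0.08): noncompetitive
  expect_equal(classify_mode(mk(0.05, 0.2), list(mk(0.05, 0.08)))$mode,
               "noncompetitive")
  # Km 0.026 -> 0.22 with Vmax 0.67 -> 0.53: competitive-like, mixed flagged
  cl <- classify_mode(mk(0.026, 0.67), list(mk(0.22, 0.53)))
  expect_equal(cl$mode, "competitive")
  expect_true(cl$mixed_flag)
  expect_equal(classify_mode(mk(10, 1), list(mk(10, 1)))$mode, "none")
  # the global fit overrides a disagreeing rule label
  fake_global <- structure(list(mode = "mixed"), class = "kinetic_fit")
  over <- classify_mode(mk(0.05, 0.2), list(mk(0.05, 0.08)),
                        global = fake_global)
  expect_equal(over$mode, "mixed")
  expect_true(over$disagreement)
})
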