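# Generators: forward-model identities, noise behaviour, determinism.

test_that("melt generator honours sigmoid geometry and preconditions", {
  tr <- ground_truth("melt", list(tm = 45, w = 1, f_pre = 1, f_post = 5))
  grid <- melt_grid()
  cu <- gen_melt_curve(tr, grid)
  # midpoint of the flat baselines at T = Tm
  expect_equal(cu$fluorescence[which(grid == 45)], (1 + 5) / 2,
               tolerance = 1e-12)
  # monotone nondecreasing for flat baselines and positive amplitude
  expect_true(all(diff(cu$fluorescence) >= 0))
  expect_error(gen_melt_curve(tr, seq(40, 50, length.out = 5)),
               "fewer than 10")
  expect_error(gen_melt_curve(tr, c(25, 25, 26:40)), "strictly increasing")
  out <- gen_melt_curve(tr, seq(50, 70, 1))
  expect_true(isTRUE(attr(out, "warn_tm_outside")))
})

test_that("mean of replicate noisy melt curves converges on the noiseless curve", {
  grid <- melt_grid(30, 60, 1)
  noiseless <- gen_melt_curve(
    ground_truth("melt", list(tm = 45, w = 1, f_pre = 0, f_post = 4)),
    grid)$fluorescence
  sd <- 0.3
  reps <- sapply(1:100, function(k) {
    gen_melt_curve(ground_truth("melt",
                                list(tm = 45, w = 1, f_pre = 0, f_post = 4),
                                noise_sd = sd, seed = k),
                   grid)$fluorescence
  })
  expect_true(all(abs(rowMeans(reps) - noiseless) < 3 * sd / sqrt(100)))
})

test_that("generators are deterministic in (parameters, seed)", {
  tr <- ground_truth("melt", list(tm = 45, w = 1, f_pre = 0, f_post = 4),
                     noise_sd = 0.2, seed = 11)
  expect_identical(gen_melt_curve(tr, melt_grid()),
                   gen_melt_curve(tr, melt_grid()))
  tr2 <- ground_truth("quench", list(kb = 100), noise_sd = 0.01, seed = 5)
  expect_identical(gen_quench_titration(tr2, quench_concs),
                   gen_quench_titration(tr2, quench_concs))
  tr3 <- tr2; tr3$seed <- 6L
  expect_false(identical(gen_quench_titration(tr2, quench_concs),
                         gen_quench_titration(tr3, quench_concs)))
})

test_that("quenching generator is the clipped line 1 - c/KB", {
  tr <- ground_truth("quench", list(kb = 100))
  s <- gen_quench_titration(tr, c(0, 25, 50, 100, 150))
  expect_equal(s$response, c(1, 0.75, 0.5, 0, 0))  # clipped at zero
  tr283 <- ground_truth("quench", list(kb = 283))
  s283 <- gen_quench_titration(tr283, quench_concs)
  expect_equal(s283$response[s283$conc_uM == 0], 1)
  # slope of the unclipped region is exactly -1/KB
  sl <- coef(lm(response ~ conc_uM, s283))[[2]]
  expect_equal(sl, -1 / 283, tolerance = 1e-12)
  expect_error(ground_truth("quench", list(kb = -5)), "positive")
  expect_error(gen_quench_titration(tr, c(1, 5, 10)), "include 0")
})

test_that("calorimetric generator propagates sign, vanishes at weak binding, and conserves heat", {
  exo <- ground_truth("itc", list(kd = 3.4, dh = -10, n = 1))
  s <- gen_itc_experiment(exo)
  expect_lt(s$heat_per_mole[1], 0)
  expect_true(all(diff(s$molar_ratio) > 0))
  weak <- ground_truth("itc", list(kd = 1e9, dh = -10, n = 1))
  sw <- gen_itc_experiment(weak)
  expect_true(all(abs(sw$heat_per_mole) < 1e-4))
  # conservation at strong saturation: summed raw heats vs N*dH*Pt*V0
  fw <- pctriage:::itc_forward(0.1, -10, 1, 30, 500, rep(2, 19), 200)
  total <- sum(fw$raw_heat)
  expected <- 1 * -10 * 30e-6 * 200e-6
  expect_equal(total / expected, 1, tolerance = 0.05)
  expect_true(isTRUE(attr(gen_itc_experiment(exo, cell_conc = 30,
                                             syringe_conc = 20),
                          "warn_no_saturation")))
})

test_that("rate generator reproduces the textbook inhibition limits", {
  tr <- ground_truth("rate", list(km = 10, vmax = 1))
  s <- gen_rate_series(tr, c(10))
  expect_equal(s$rate, 0.5)  # v(S = Km) = Vmax/2
  trn <- ground_truth("rate", list(km = 10, vmax = 1, ki = 5))
  sn <- gen_rate_series(trn, 1e6, inhibitor_concs = 5,
                        model = "noncompetitive")
  expect_equal(sn$rate, 0.5, tolerance = 1e-4)  # alpha' = 2 at I = Ki
  sc <- gen_rate_series(trn, 1e8, inhibitor_concs = 50, model = "competitive")
  expect_equal(sc$rate, 1, tolerance = 1e-4)    # competitive preserves Vmax
  expect_error(gen_rate_series(tr, c(-1, 5)), "nonnegative")
  expect_error(gen_rate_series(tr, 10, 5, model = "competitive"), "ki")
})

test_that("dose-response generator sits at the 4PL midpoint at IC50", {
  tr <- ground_truth("dose_response",
                     list(ic50 = 18, top = 100, bottom = 0, hill = 1))
  d <- gen_dose_response(tr, c(18))
  expect_equal(d$response, 50)
})

test_that("the packaged 25-compound panel matches the published summary", {
  p <- load_table1_fixture()
  expect_s3_class(p, "assay_panel")
  expect_equal(nrow(p), 25L)
  a49 <- p[p$compound == "A49", ]
  expect_equal(unname(unlist(a49[c("score_wt", "score_r88c", "score_v400m",
                                   "score_a433e")])), c(0, 2, 4, 1))
  expect_equal(a49$kb_uM, 55)
  expect_equal(a49$itc_kd_uM, 3.4)
  expect_equal(p$score_v400m[p$compound == "B40"], -4)
  expect_equal(p$score_a433e[p$compound == "B40"], -4)
})
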