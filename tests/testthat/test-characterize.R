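test_that("calibration fitting recovers exact and noisy lines", {
  conc <- c(0, 5, 10, 20, 40)
  cal <- fit_calibration(conc, 100 * conc + 50)
  expect_equal(cal$slope, 100)
  expect_equal(cal$intercept, 50)

  expect_error(fit_calibration(c(5, 5, 5), c(1, 2, 3)), "distinct")
  expect_error(fit_calibration(c(0, 10), c(0, 10)), ">= 3")
  expect_error(fit_calibration(conc, 100 - 2 * conc), "slope")

  set.seed(8)
  rfu <- 80 * conc + 20 + rnorm(length(conc), 0, 5)
  fit <- lm(rfu ~ conc)
  cal2 <- fit_calibration(conc, rfu)
  expect_lt(abs(cal2$slope - 80), 3 * summary(fit)$coefficients[2, 2])
})

test_that("initial-rate estimation applies the 10% consumption rule", {
  cal <- calibration(slope = 1, intercept = 0)
  # noiseless linear P(t) = 0.2 t uM/s -> 12 uM/min
  times <- seq(0, 100, 10)
  tc <- structure(list(clone_id = "c", substrate = "MU-C", conc0 = 240,
                       times = times, rfu = 0.2 * times, od600 = NULL,
                       condition = NULL), class = "timecourse")
  expect_equal(estimate_initial_rate(tc, cal), 12)

  # points past 10% depletion never change the estimate
  times2 <- seq(0, 400, 10)   # beyond t = 120 s, P > 24 uM
  p2 <- pmin(0.2 * times2, 60)
  tc2 <- structure(list(clone_id = "c", substrate = "MU-C", conc0 = 240,
                        times = times2, rfu = p2, od600 = NULL,
                        condition = NULL), class = "timecourse")
  expect_equal(estimate_initial_rate(tc2, cal), 12)

  # deep depletion by the second sample -> flagged, not an error
  enz <- make_enzyme(kcat = c("MU-C" = 1000), km = 0.01)
  tc3 <- simulate_timecourse(enz, "MU-C", conc0 = 240,
                             times = c(0, 60, 120, 180), cal,
                             enzyme_conc_um = 0.01)
  expect_identical(estimate_initial_rate(tc3, cal), "depleted")

  # OD600 normalization divides the rate
  tc4 <- tc
  tc4$od600 <- 2
  expect_equal(estimate_initial_rate(tc4, cal), 6)
  expect_equal(estimate_initial_rate(tc4, cal, normalize_od = FALSE), 12)

  # zero-order simulated course with 1% signal noise recovers 1 uM/min within 5%
  set.seed(12)
  enz5 <- make_enzyme(kcat = c("MU-C" = 1 / 60 / 0.01), km = 0.0002)
  tc5 <- simulate_timecourse(enz5, "MU-C", conc0 = 240,
                             times = seq(0, 600, 30), cal,
                             noise_sd = 0.01 * 10, enzyme_conc_um = 0.01)
  expect_equal(estimate_initial_rate(tc5, cal), 1, tolerance = 0.05)
})

test_that("substrate preference takes the panel argmax with declared tie-breaks", {
  expect_equal(substrate_preference(c("MU-Glc" = 5, "MU-C" = 2)), "MU-Glc")
  expect_equal(substrate_preference(c("MU-Glc" = 0, "MU-C" = 0)), "none")
  expect_equal(substrate_preference(c("MU-Glc" = 5, "MU-C" = 5)), "MU-C")
  r <- c("MU-Xyl" = 3, "MU-Man" = 1, "MU-C" = 2)
  expect_equal(substrate_preference(r), substrate_preference(r * 17.3))
  expect_equal(substrate_preference(list("MU-C" = "depleted", "MU-Glc" = 1)),
               "MU-Glc")
})

test_that("pH optimum uses the extension series only when censored at the boundary", {
  prim <- data.frame(ph = seq(4, 7.7, 0.3),
                     rate = exp(-(seq(4, 7.7, 0.3) - 5.5)^2 / 2))
  expect_equal(ph_optimum(prim), 5.5)

  rising <- data.frame(ph = seq(4, 7.7, 0.3), rate = seq(4, 7.7, 0.3))
  ext <- data.frame(ph = seq(7, 9.8, 0.4), rate = c(5, 6, 9, 10, 9, 6, 5, 4))
  expect_equal(ph_optimum(rising, ext), 8.2)
  expect_error(ph_optimum(rising), "extension series needed")

  # ties resolve to the lower pH
  flat <- data.frame(ph = c(4, 5, 6, 7), rate = c(1, 3, 3, 1))
  expect_equal(ph_optimum(flat), 5)
})

test_that("pH optimum recovery is modal at the true grid point under 2% noise", {
  grid <- seq(4, 7.6, 0.4)   # includes the true optimum 6.0
  enz <- make_enzyme(ph_opt = 6.0, ph_width = 1.0)
  rec <- vapply(1:50, function(s) {
    set.seed(700 + s)
    ph_optimum(simulate_ph_series(enz, grid, noise = 0.02))
  }, numeric(1))
  expect_equal(as.numeric(names(which.max(table(rec)))), 6.0)
})

test_that("van't Hoff fitting recovers the midpoint and enthalpy", {
  grid <- seq(37, 90, 3)
  enz <- make_enzyme(tm = 50, dh = 200)
  th <- simulate_thermal_series(enz, grid, noise = 0, rate_ref = 10)
  fit <- fit_vant_hoff(th)
  expect_lt(abs(fit$tm - 50), 0.1)
  expect_equal(fit$dh_vh, 200, tolerance = 1e-3)
  expect_equal(fit$v0, 10, tolerance = 1e-3)
  # midpoint identity: the fitted curve evaluated at the fitted Tm is v0/2
  at_tm <- fit$v0 * fosmidscreen:::vant_hoff_fraction(fit$tm, fit$tm, fit$dh_vh)
  expect_equal(at_tm, fit$v0 / 2)
  expect_false(fit$extrapolated)

  flat <- data.frame(temperature = grid, rate = rep(5, length(grid)))
  expect_error(fit_vant_hoff(flat), "unidentifiable")
  expect_error(fit_vant_hoff(th[1:3, ]), ">= 4")
})

test_that("Tm recovery across the observed span stays within a degree at 3% noise", {
  grid <- seq(37, 90, 3)
  set.seed(77)
  tms <- runif(100, 38, 74)
  errs <- vapply(seq_along(tms), function(i) {
    enz <- make_enzyme(tm = tms[i], dh = runif(1, 150, 400))
    th <- simulate_thermal_series(enz, grid, noise = 0.03, rate_ref = 10)
    abs(fit_vant_hoff(th)$tm - tms[i])
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("mechanism classification splits retainers from inverters", {
  expect_equal(classify_mechanism(0.05, 1.0)$mechanism, "retaining")
  expect_equal(classify_mechanism(0.98, 1.0)$mechanism, "inverting")
  expect_error(classify_mechanism(0.5, 0), "control")

  # cohort: at a 58% retaining fraction the classified fraction lands nearby
  fracs <- vapply(1:20, function(s) {
    cfg <- simulation_config(seed = 800 + s)
    set.seed(800 + s)
    calls <- vapply(1:122, function(i) {
      enz <- simulate_enzyme(cfg)
      pair <- simulate_inactivation(enz, control_rate = 1, noise = 0.05)
      classify_mechanism(pair$residual_rate, pair$control_rate)$mechanism
    }, character(1))
    mean(calls == "retaining")
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.58), 0.05)
})

test_that("end-to-end characterization recovers the latent profile at zero noise", {
  cfg <- simulation_config(seed = 5)
  enz <- make_enzyme(kcat = c("MU-Xyl" = 20, "MU-C" = 4), km = 0.3,
                     ph_opt = 5.8, tm = 61, dh = 250, mechanism = "inverting")
  clone <- make_clone("LIB01_01_B02", enzymes = list(enz))
  prof <- characterize_clone(clone, cfg,
                             ph_grid_primary = seq(4, 7.6, 0.4),
                             thermal_grid = seq(37, 90, 3))
  expect_equal(prof$optimal_substrate, "MU-Xyl")
  expect_equal(prof$ph_optimum, 5.6)   # grid point nearest the latent 5.8
  expect_lt(abs(prof$tm - 61), 0.1)
  expect_equal(prof$mechanism, "inverting")
})
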