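# Calibration gain fitting and inversion into secretion rates and K_D.

chem <- assay_chemistry()
sched <- acquisition_schedule()

test_that("gain fitting is self-consistent on noiseless anchors", {
  chem5 <- assay_chemistry(kappa_red = 5, kappa_green = 8)
  anchors <- simulate_anchor_traces(calibration_panel(), chem = chem5,
                                    sched = sched)
  cal <- fit_calibration(anchors, chem = chem5)
  expect_equal(cal$kappa_red, 5, tolerance = 1e-6)
  expect_equal(cal$kappa_green, 8, tolerance = 1e-6)
  expect_lt(cal$rms_red, 1e-9)
})

test_that("gains are recovered within 5% under 1% anchor noise", {
  for (seed in 1:100) {
    anchors <- simulate_anchor_traces(calibration_panel(), chem = chem,
                                      sched = sched, noise_sd = 0.01,
                                      seed = seed)
    cal <- fit_calibration(anchors, chem = chem)
    expect_equal(cal$kappa_red, chem$kappa_red, tolerance = 0.05)
    expect_equal(cal$kappa_green, chem$kappa_green, tolerance = 0.05)
  }
})

test_that("degenerate anchor panels are refused", {
  expect_error(fit_calibration(NULL), "empty anchor panel")
  one_conc <- calibration_panel(concentrations = 10e-9)
  anchors <- simulate_anchor_traces(one_conc, chem = chem, sched = sched)
  expect_error(fit_calibration(anchors, chem = chem), "single concentration")
  one_kd <- simulate_anchor_traces(
    calibration_panel(kds = rep(1e-9, 2), clones = c("a", "b")),
    chem = chem, sched = sched)
  expect_error(fit_calibration(one_kd, chem = chem), "distinct K_D")
})

cal <- fit_calibration(
  simulate_anchor_traces(calibration_panel(), chem = chem, sched = sched),
  chem = chem)

test_that("secretion-rate inversion round-trips and censors at 4-800", {
  tr <- forward_kinetics(33, 65e-9, chem, sched)
  est <- infer_secretion_rate(tr$r_red, tr$times_min, cal)
  expect_equal(est$rate, 33, tolerance = 0.01)
  expect_equal(est$flag, "IN_RANGE")

  tr_hi <- forward_kinetics(1000, 65e-9, chem, sched)
  est_hi <- infer_secretion_rate(tr_hi$r_red, tr_hi$times_min, cal)
  expect_equal(est_hi$rate, 800)
  expect_equal(est_hi$flag, "ABOVE_800")

  tr_lo <- forward_kinetics(2, 65e-9, chem, sched)
  est_lo <- infer_secretion_rate(tr_lo$r_red, tr_lo$times_min, cal)
  expect_equal(est_lo$rate, 4)
  expect_equal(est_lo$flag, "BELOW_4")

  tr0 <- forward_kinetics(0, 65e-9, chem, sched)
  expect_equal(infer_secretion_rate(tr0$r_red, tr0$times_min, cal)$flag,
               "NO_RATE")
})

test_that("K_D inversion round-trips with depletion correction", {
  # isotherm midpoint: occupancy 1/2 at free ligand = kd = 30 nM
  tr <- forward_kinetics(50, 30e-9, chem, sched)
  est <- infer_kd(tr$r_red, tr$r_green, cal)
  expect_equal(est$kd, 30e-9, tolerance = 0.01)
  expect_equal(est$flag, "IN_RANGE")

  tr65 <- forward_kinetics(50, 65e-9, chem, sched)
  expect_equal(infer_kd(tr65$r_red, tr65$r_green, cal)$kd, 65e-9,
               tolerance = 0.05)

  # sub-nanomolar: extrapolated below 2.3 nM, classified HIGH
  tr_hi <- forward_kinetics(50, 0.5e-9, chem, sched)
  est_hi <- infer_kd(tr_hi$r_red, tr_hi$r_green, cal)
  expect_lt(est_hi$kd, 1e-9)
  expect_equal(est_hi$flag, "EXTRAPOLATED_LT_2.3")
  expect_equal(classify_affinity(est_hi$kd, est_hi$flag)$affinity_class,
               "HIGH")
})

test_that("forward-inverse identity holds across the working windows", {
  for (s in 10^seq(log10(4), log10(800), length.out = 9)) {
    tr <- forward_kinetics(s, 30e-9, chem, sched)
    expect_equal(infer_secretion_rate(tr$r_red, tr$times_min, cal)$rate, s,
                 tolerance = 0.01)
  }
  for (kd in 10^seq(log10(2.3e-9), log10(100e-9), length.out = 9)) {
    tr <- forward_kinetics(50, kd, chem, sched)
    est <- infer_kd(tr$r_red, tr$r_green, cal)
    expect_equal(est$kd, kd, tolerance = 0.05)
  }
})

test_that("inversion preserves ordering of true parameters", {
  s_grid <- c(5, 15, 40, 120, 400)
  s_hat <- vapply(s_grid, function(s) {
    tr <- forward_kinetics(s, 30e-9, chem, sched)
    infer_secretion_rate(tr$r_red, tr$times_min, cal)$rate
  }, numeric(1))
  expect_true(all(diff(s_hat) > 0))

  kd_grid <- c(0.5, 3, 12, 45, 95) * 1e-9
  kd_hat <- vapply(kd_grid, function(kd) {
    tr <- forward_kinetics(50, kd, chem, sched)
    infer_kd(tr$r_red, tr$r_green, cal)$kd
  }, numeric(1))
  expect_true(all(diff(kd_hat) > 0))
})

test_that("affinity classes and specificity follow the printed boundaries", {
  cl <- classify_affinity(c(10, 0.99, 150, 5) * 1e-9)
  expect_equal(cl$affinity_class, c("LOW", "HIGH", NA, "MEDIUM"))
  expect_equal(cl$is_gpi_specific, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("every record carries exactly one rate flag and one kd flag", {
  run <- run_noiseless_cohort(
    40, function(n) rlnorm_truncated(n, 3.317, 0.6, c(4, 800)),
    function(n) 10^runif(n, -8.6, -5), seed = 91)
  rec <- run$records
  expect_true(all(rec$rate_flag %in%
                    c("IN_RANGE", "BELOW_4", "ABOVE_800", "NO_RATE")))
  expect_true(all(rec$kd_flag %in%
                    c("IN_RANGE", "EXTRAPOLATED_LT_2.3",
                      "NONSPECIFIC_GE_100", "NO_GREEN_SIGNAL")))
  # flag tallies reconcile with the cohort total
  expect_equal(sum(table(rec$rate_flag)), nrow(rec))
  expect_equal(sum(table(rec$kd_flag)), nrow(rec))
  expect_true(all(rec$is_gpi_specific == (!is.na(rec$kd) &
                                            rec$kd < 100e-9 &
                                            rec$kd_flag != "NO_GREEN_SIGNAL")))
})
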