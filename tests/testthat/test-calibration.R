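test_that("forward response hits its boundary cases", {
  cal <- make_cal(R0 = 2, Ksv = 0.02, alpha = 0.1)
  expect_equal(stern_volmer_forward(0, cal), 2)          # zero-oxygen ratio
  # high-quenching asymptote approaches the nonquenchable floor alpha*R0
  expect_equal(stern_volmer_forward(1e9, cal), 0.2, tolerance = 1e-6)
  # measured coefficient set at full air saturation: R0/(1 + 100*Ksv)
  cal_a <- calibration_curve("a", R0 = 1.881, Ksv = 0.012)
  expect_equal(stern_volmer_forward(100, cal_a), 1.881 / 2.2)
  expect_equal(stern_volmer_forward(100, cal_a), 0.855, tolerance = 1e-12)
  expect_error(stern_volmer_forward(-1, cal), "nonnegative")
})

test_that("forward response is strictly decreasing when quenching is active", {
  set.seed(11)
  for (i in 1:50) {
    cal <- make_cal(R0 = runif(1, 0.5, 3), Ksv = runif(1, 0.001, 0.05),
                    alpha = runif(1, 0, 0.9))
    C <- sort(runif(20, 0, 150))
    expect_true(all(diff(stern_volmer_forward(C, cal)) < 0))
  }
})

test_that("closed-form inversion matches forward model and bisection oracle", {
  cal <- make_cal(R0 = 1.9, Ksv = 0.011, alpha = 0.05)
  expect_equal(invert_calibration(cal$R0, cal), 0)
  expect_equal(invert_calibration(stern_volmer_forward(37.5, cal), cal),
               37.5, tolerance = 1e-9)
  # frozen oracle: bisection on the forward model gives 100 for disk-a's
  # full-saturation ratio
  cal_a <- calibration_curve("a", R0 = 1.881, Ksv = 0.012)
  expect_equal(invert_calibration(0.855, cal_a), 100, tolerance = 1e-6)
  expect_equal(bisect_invert(0.855, cal_a), 100, tolerance = 1e-6)

  set.seed(21)
  for (i in 1:1000) {
    cal <- make_cal(R0 = runif(1, 0.5, 3), Ksv = runif(1, 0.002, 0.05),
                    alpha = runif(1, 0, 0.5))
    C <- runif(1, 0.1, 150)
    R <- stern_volmer_forward(C, cal)
    expect_equal(invert_calibration(R, cal), bisect_invert(R, cal),
                 tolerance = 1e-6)
  }
})

test_that("inversion flags super-saturation and rejects dead signal", {
  cal <- make_cal(R0 = 1.9, Ksv = 0.011, alpha = 0.05)
  expect_warning(C <- invert_calibration(2.1, cal), "super-saturated")
  expect_equal(C, 0)
  expect_error(invert_calibration(0.05, cal), "nonquenchable floor")
  flat <- calibration_curve("flat", R0 = 1.9, Ksv = 0)
  expect_error(invert_calibration(1.0, flat), "degenerate")
})

test_that("fit recovers generating parameters from noiseless points", {
  truth <- make_cal(R0 = 1.95, Ksv = 0.010, alpha = 0.08)
  pts <- make_cal_points(truth)
  fit <- fit_calibration(pts, fix_alpha = FALSE)
  expect_equal(fit$R0, 1.95, tolerance = 1e-6)
  expect_equal(fit$Ksv, 0.010, tolerance = 1e-6)
  expect_equal(fit$alpha, 0.08, tolerance = 1e-6)
  expect_gt(fit$r_squared, 0.999999)

  # two-parameter form round-trips a printed coefficient pair
  disk_b <- calibration_curve("b", R0 = 1.948, Ksv = 0.009)
  fit_b <- fit_calibration(make_cal_points(disk_b), fix_alpha = TRUE,
                           disk_id = "b")
  expect_equal(fit_b$R0, 1.948, tolerance = 1e-6)
  expect_equal(fit_b$Ksv, 0.009, tolerance = 1e-6)
})

test_that("fit is deterministic and rejects underdetermined input", {
  truth <- make_cal()
  set.seed(5)
  pts <- make_cal_points(truth, noise_sd = 0.01)
  f1 <- fit_calibration(pts)
  f2 <- fit_calibration(pts)
  expect_identical(stats::setNames(c(f1$R0, f1$Ksv), NULL),
                   stats::setNames(c(f2$R0, f2$Ksv), NULL))
  expect_error(fit_calibration(make_cal_points(truth, C = c(0, 50))),
               "distinct concentrations")
  expect_error(fit_calibration(make_cal_points(truth, C = c(0, 30, 60)),
                               fix_alpha = FALSE),
               "distinct concentrations")
})

test_that("Ksv estimator is accurate under realistic ratio noise", {
  # triplicate response points per level, matching the measurement protocol
  truth <- make_cal(R0 = 1.95, Ksv = 0.010, alpha = 0.08)
  rel_err <- vapply(1:100, function(s) {
    set.seed(s)
    pts <- make_cal_points(truth, noise_sd = 0.005, replicates = 3)
    fit <- fit_calibration(pts, fix_alpha = FALSE)
    abs(fit$Ksv - 0.010) / 0.010
  }, numeric(1))
  expect_lt(median(rel_err), 0.02)
})

test_that("detection limits follow the 3.3/10 sigma-over-slope convention", {
  lin <- data.frame(true_saturation = seq(0.4, 40, by = 2),
                    measured_saturation = seq(0.4, 40, by = 2))
  # unit slope, replicate sd 0.3 -> LOD = 3.3 * 0.3
  reps <- 3.3 + c(-0.3, 0.3, -0.3, 0.3)
  dl <- compute_detection_limits(reps, lin)
  expect_equal(dl$slope_m, 1, tolerance = 1e-12)
  expect_equal(dl$lod, 0.99, tolerance = 1e-9)
  # noiseless replicates
  dl0 <- compute_detection_limits(rep(3.3, 5), lin)
  expect_equal(dl0$lod, 0)
  expect_equal(dl0$loq, 0)
  # the LOQ/LOD ratio is exact by construction, not just numerically close
  set.seed(9)
  dl1 <- compute_detection_limits(rnorm(12, 3.3, 0.4), lin)
  expect_identical(dl1$loq / dl1$lod, 10 / 3.3)
  expect_error(compute_detection_limits(3.3, lin), "at least 2")
  expect_error(compute_detection_limits(
    data.frame(true_saturation = c(3, 4),
               measured_saturation = c(3, 4)), lin),
    "one true concentration")
  flat <- data.frame(true_saturation = seq(1, 40, by = 2),
                     measured_saturation = rep(5, 20))
  expect_error(compute_detection_limits(reps, flat), "slope")
})

test_that("per-disk LOD summary uses mean and population sd", {
  s <- summarize_lods(c(1.15, 0.58, 1.61))
  expect_equal(round(s$mean, 1), 1.1)
  expect_equal(round(s$population_sd, 1), 0.4)
  expect_equal(summarize_lods(c(2, 2, 2))$population_sd, 0)
  expect_error(summarize_lods(numeric(0)), "at least 2")
})

test_that("KS comparison behaves at the extremes", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_calibrations(x, x)
  expect_equal(same$ks_statistic, 0)
  expect_false(same$reject)
  apart <- compare_calibrations(rnorm(50), rnorm(50, 100))
  expect_equal(apart$ks_statistic, 1)
  expect_true(apart$reject)
  expect_error(compare_calibrations(1, x), "at least 2")
})

test_that("curve-level comparison works over a shared ratio grid", {
  a <- make_cal(R0 = 1.9, Ksv = 0.011, alpha = 0)
  b <- make_cal(R0 = 1.5, Ksv = 0.04, alpha = 0, id = "d2")
  res <- compare_calibration_curves(a, b)
  expect_gt(res$ks_statistic, 0)
  expect_true(res$reject)  # grossly different baseline and quenching
  same <- compare_calibration_curves(a, a)
  expect_equal(same$ks_statistic, 0)
})

test_that("ratio normalisation scales the maximum to one", {
  expect_equal(normalize_ratios(c(2, 1, 0.5)), c(1, 0.5, 0.25))
  expect_equal(normalize_ratios(1), 1)
  set.seed(2)
  x <- runif(30, 0.1, 5)
  expect_equal(max(normalize_ratios(x)), 1)
  expect_error(normalize_ratios(c(0, 0)), "not positive")
})

test_that("calibration registry round-trips losslessly", {
  reg <- list(a = calibration_curve("a", 1.881, 0.012,
                                    r_squared = 0.998, resid_sd = 0.004,
                                    temperature_C = 21,
                                    created_at = "2026-01-01T00:00:00+0000"),
              b = calibration_curve("b", 1.948, 0.009, alpha = 0.02,
                                    ratio_def = "simple",
                                    created_at = "2026-01-02T00:00:00+0000"))
  attr(reg$a, "provenance") <- list(operator = "mk", source = "set1")
  path <- tempfile(fileext = ".json")
  write_calibration_registry(reg, path)
  back <- read_calibration_registry(path)
  expect_identical(names(back), c("a", "b"))
  for (id in names(reg))
    expect_identical(unclass(back[[id]]), unclass(reg[[id]]))
  expect_identical(attr(back$a, "provenance"),
                   attr(reg$a, "provenance"))
  # absent registry reads as empty, enabling create-on-first-write
  expect_length(read_calibration_registry(tempfile()), 0)
})
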