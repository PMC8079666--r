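test_that("fit configuration validates bounds and initial values", {
  expect_s3_class(fit_config(), "fit_config")
  expect_error(fit_config(lower = c(f_m = 0.9, f_a = 0, f_e = 0, omega_a_hz = -30,
                                    omega_m_hz = 0, r2s_m = 50, r2s_e = 0)),
               "within the bounds")
  expect_error(fit_config(fdm_weight = 0))
})

test_that("curves generated at the literature init are recovered exactly", {
  # truth = the standard initial values; identifiable quantities recover
  p0 <- three_pool_params(0.5, 0.5, 0.5, omega_m_hz = 30, omega_a_hz = -8,
                          r2s_m = 150, r2s_a = 0, r2s_e = 25)
  fit <- fit_three_pool(model_roi_curves(p0, default_schedule()))
  expect_equal(unname(fit$fractions_normalized), rep(1 / 3, 3), tolerance = 1e-8)
  expect_equal(fit$delta_omega_hz, 38, tolerance = 1e-8)
  expect_equal(fit$params$r2s_m, 150, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("noiseless posterior-segment curves round-trip within 1e-3", {
  fit <- fit_three_pool(model_roi_curves(seg3_params(), default_schedule()))
  expect_equal(fit$fractions_normalized[["f_m"]], 0.16, tolerance = 1e-3)
  expect_equal(omega_hz(fit$params)[["omega_a_hz"]], -8.5, tolerance = 1e-3)
  expect_equal(omega_hz(fit$params)[["omega_m_hz"]], 27.3, tolerance = 1e-3)
  expect_equal(fit$delta_omega_hz, 35.8, tolerance = 2e-3)
  expect_lt(fit$residual_norm, 1e-6)
})

test_that("fitted parameters respect the box bounds and flag bound hits", {
  set.seed(11)
  for (i in 1:10) {
    rc <- noisy_curves(seg3_params(), sd = 2e-3)
    fit <- fit_three_pool(rc)
    th <- c(f_m = fit$params$f_m, f_a = fit$params$f_a, f_e = fit$params$f_e,
            omega_a_hz = omega_hz(fit$params)[["omega_a_hz"]],
            omega_m_hz = omega_hz(fit$params)[["omega_m_hz"]],
            r2s_m = fit$params$r2s_m, r2s_e = fit$params$r2s_e)
    cfg <- fit_config()
    expect_true(all(th >= cfg$lower - 1e-9 & th <= cfg$upper + 1e-9))
    expect_named(fit$at_bounds, names(cfg$lower))
  }
})

test_that("the fit is invariant to the raw magnitude scale", {
  sched <- default_schedule()
  s <- synthesize_three_pool(seg3_params(), sched)$values * 1234
  rc <- roi_curves(sched, Mod(s) / Mod(s)[1], fdm_from_complex(s, sched))
  fit <- fit_three_pool(rc)
  expect_equal(fit$fractions_normalized[["f_m"]], 0.16, tolerance = 1e-6)
})

test_that("noisy fits at the emulated protocol noise stay within the published SD scale", {
  # curve-level noise 1.1e-4 = per-channel pixel SNR 100 after repeat,
  # polarity, 4-channel and ~400-pixel posterior-segment averaging
  set.seed(12)
  errs <- replicate(200, {
    rc <- noisy_curves(seg3_params(), sd = 1.1e-4)
    fit_three_pool(rc)$fractions_normalized[["f_m"]] - 0.16
  })
  expect_lte(median(abs(errs)), 0.02)
})

test_that("noiseless identifiability holds for sum-one parameter draws", {
  set.seed(13)
  n_ok <- 0
  n <- 100
  cfg <- fit_config(multi_start = 5)
  for (i in seq_len(n)) {
    f_m <- runif(1, 0.05, 0.35)
    rho <- runif(1, 0.3, 0.7)
    wa <- runif(1, -25, -2)
    wm <- runif(1, max(0, wa + 10), 50)  # in bounds, separation >= 10 Hz
    p <- three_pool_params(f_m, rho * (1 - f_m), (1 - rho) * (1 - f_m),
                           omega_m_hz = wm, omega_a_hz = wa,
                           r2s_m = runif(1, 80, 250), r2s_a = 0,
                           r2s_e = runif(1, 5, 80))
    fit <- fit_three_pool(model_roi_curves(p, default_schedule()), cfg)
    ok <- abs(fit$fractions_normalized[["f_m"]] - f_m) < 1e-2 &&
      abs(omega_hz(fit$params)[["omega_a_hz"]] - wa) < 1e-2 &&
      abs(omega_hz(fit$params)[["omega_m_hz"]] - wm) < 1e-2
    n_ok <- n_ok + ok
  }
  expect_gte(n_ok / n, 0.95)
})

test_that("fitted myelin fraction increases monotonically with the true one", {
  grid <- c(0.08, 0.12, 0.16, 0.20, 0.24)
  fits <- vapply(grid, function(fm) {
    p <- three_pool_params(fm, (1 - fm) / 2, (1 - fm) / 2, omega_m_hz = 27.3,
                           omega_a_hz = -8.5, r2s_m = 150, r2s_a = 0, r2s_e = 25)
    fit_three_pool(model_roi_curves(p, default_schedule()))$fractions_normalized[["f_m"]]
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("fixing the intra-axonal decay at zero biases fractions as documented", {
  b <- r2a_constraint_bias(c(0, 5, 10))
  # truth matches the constraint: no bias anywhere
  expect_equal(unlist(b[1, c("err_f_m", "err_f_a", "err_f_e")]),
               c(err_f_m = 0, err_f_a = 0, err_f_e = 0), tolerance = 1e-6)
  # frozen from an independent bounded least-squares run (scipy):
  expect_equal(b$f_m[b$r2s_a_true == 5], 0.156284, tolerance = 1e-3)
  expect_equal(b$f_a[b$r2s_a_true == 5], 0.306889, tolerance = 1e-3)
  expect_equal(b$f_e[b$r2s_a_true == 5], 0.536826, tolerance = 1e-3)
  expect_equal(b$f_m[b$r2s_a_true == 10], 0.150176, tolerance = 1e-3)
  expect_equal(b$f_a[b$r2s_a_true == 10], 0.219953, tolerance = 1e-3)
  expect_equal(b$f_e[b$r2s_a_true == 10], 0.629871, tolerance = 1e-3)
  # direction: intra-axonal fraction under-, extra-axonal over-estimated
  expect_lt(b$err_f_a[3], 0)
  expect_gt(b$err_f_e[3], 0)
  # myelin fraction is far less affected than the intra-axonal fraction
  expect_true(all(abs(b$err_f_m[-1]) < abs(b$err_f_a[-1])))
  expect_error(r2a_constraint_bias(numeric(0)), "empty")
})
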