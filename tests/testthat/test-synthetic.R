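test_that("phantom draws are seeded, centred on segment means, and sum to one", {
  spec <- phantom_spec(grid = c(96, 96))
  a <- generate_phantom(spec, seed = 0)
  b <- generate_phantom(spec, seed = 0)
  expect_identical(a, b)
  c <- generate_phantom(spec, seed = 99)
  expect_false(identical(a$param_maps$f_m, c$param_maps$f_m))
  expect_equal(mean(a$param_maps$f_m[a$masks$labels == 3]), 0.16, tolerance = 0.01)
  expect_equal(mean(a$param_maps$f_m[a$masks$labels == 1]), 0.15, tolerance = 0.01)
  # fraction conservation at every pixel
  tot <- a$param_maps$f_m + a$param_maps$f_a + a$param_maps$f_e
  expect_equal(tot[a$masks$head], rep(1, sum(a$masks$head)), tolerance = 1e-12)
  # degenerate variance gives piecewise-constant maps
  spec0 <- phantom_spec(grid = c(96, 96),
                        pixel_sd = list(f_m = 0, rho = 0, omega_m_hz = 0,
                                        omega_a_hz = 0, r2s_m = 0, r2s_e = 0))
  d <- generate_phantom(spec0, seed = 0)
  expect_equal(unique(d$param_maps$f_m[d$masks$labels == 3]), 0.16)
  expect_error(phantom_spec(grid = c(16, 16)))
})

test_that("acquisition nuisances are stored and invert analytically (noise off)", {
  ph <- generate_phantom(phantom_spec(grid = c(48, 48)), seed = 8)
  stack <- simulate_acquisition(ph, nuisance_spec(10, 1, 0.3, 2, 0), seed = 9)
  tr <- stack$truth
  sched <- stack$schedule
  idx <- which(ph$masks$head)
  for (j in c(2, 7)) for (c in 1:2) for (pol in 1:2) {
    t_s <- sched$te_ms[j] / 1000
    polarity <- c(1, -1)[pol]
    mod <- exp(1i * (tr$rf_phase + 2 * pi * tr$field_hz * t_s +
                     polarity * (-1)^j * tr$eddy_phase_rad)) * tr$coil[, , c]
    rec <- stack$data[, , j, c, pol] / mod
    expect_equal(rec[idx], tr$clean[, , j][idx], tolerance = 1e-10)
  }
  # identity nuisance, single channel: stack phase equals the model phase
  st0 <- simulate_acquisition(ph, no_nuisance(), seed = 1)
  expect_equal(Arg(st0$data[, , 3, 1, 1])[idx], Arg(tr$clean[, , 3])[idx],
               tolerance = 1e-12)
})

test_that("acquisition is deterministic under a fixed seed", {
  ph <- generate_phantom(phantom_spec(grid = c(48, 48)), seed = 8)
  s1 <- simulate_acquisition(ph, nuisance_spec(), seed = 10)
  s2 <- simulate_acquisition(ph, nuisance_spec(), seed = 10)
  expect_identical(s1$data, s2$data)
})

test_that("study generator records its ground truth and respects the design", {
  spec <- study_spec()
  sim <- simulate_study(spec, seed = 3)
  tab <- sim$table
  expect_equal(nrow(tab), 40)
  expect_equal(sum(tab$group == "hd"), 19)
  expect_true(all(tab$cag[tab$group == "hd"] %in% 37:45))
  expect_true(all(is.na(tab$cag[tab$group == "control"])))
  expect_equal(tab$dbs[tab$group == "hd"],
               disease_burden_score(tab$age[tab$group == "hd"],
                                    tab$cag[tab$group == "hd"]))
  expect_true(all(tab$f_m_true > 0 & tab$f_m_true < 1))
  expect_length(sim$curves, 40)
  expect_identical(simulate_study(spec, seed = 3)$table, tab)
  # effect sizes that push f_m out of range are rejected
  expect_error(study_spec(fm_mean = c(control = 0.99, hd = 0.9)), "outside")
})

test_that("noiseless recovery: zero group difference stays centred on zero", {
  spec <- study_spec(fm_mean = c(control = 0.15, hd = 0.15),
                     fm_slope = c(control = -4e-4, hd = -4e-4),
                     fm_subject_sd = 1e-6, fm_visit_sd = 1e-6,
                     roi_noise_sd = 0)
  sim <- simulate_study(spec, seed = 4)
  fit <- fit_group_age_model(cbind(sim$table, f_m = sim$table$f_m_true), "f_m")
  expect_equal(fit$coefficients$estimate[2], 0, tolerance = 1e-4)
})

test_that("repro generator: no visit noise means near-zero CVs", {
  sim <- simulate_repro_study(n_subjects = 2, n_visits = 5,
                              visit_sd = list(f_m = c(0, 0, 0),
                                              omega_a_hz = c(0, 0, 0),
                                              omega_m_hz = c(0, 0, 0)),
                              roi_noise_sd = 0, seed = 5)
  tab <- sim$table
  for (id in unique(tab$subject_id)) for (s in 1:3) {
    v <- tab$f_m_true[tab$subject_id == id & tab$segment == s]
    expect_equal(cv_percent(v), 0, tolerance = 1e-8)
  }
})
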