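test_that("polarity combination cancels opposite-sign phase exactly", {
  sched <- te_schedule(1, 1, 4)
  A <- array(runif(3 * 3 * 4, 0.5, 2), dim = c(3, 3, 4))
  phi <- array(runif(3 * 3 * 4, -2, 2), dim = c(3, 3, 4))
  delta <- array(runif(3 * 3 * 4, -1, 1), dim = c(3, 3, 4))
  sp <- A * exp(1i * (phi + delta))
  sn <- A * exp(1i * (phi - delta))
  out <- polarity_correct(sp, sn)
  expect_equal(Mod(out), A, tolerance = 1e-12)
  expect_equal(Arg(exp(1i * (Arg(out) - phi))), array(0, dim = dim(A)),
               tolerance = 1e-12)
  # identity case
  s <- A * exp(1i * phi)
  out2 <- polarity_correct(s, s)
  expect_equal(out2, s, tolerance = 1e-12)
})

test_that("polarity correction removes the generator's eddy phase to rounding", {
  ph <- generate_phantom(phantom_spec(grid = c(48, 48)), seed = 4)
  stack <- simulate_acquisition(ph, nuisance_spec(0, 0, eddy_phase_rad = 0.3,
                                                  n_channels = 1, noise_sigma = 0),
                                seed = 5)
  pc <- polarity_correct(stack$data[, , , 1, 1], stack$data[, , , 1, 2])
  # the eddy phase flips with polarity and must cancel; the (polarity-
  # independent) coil modulation stays in the combined signal
  expected <- stack$truth$clean
  for (j in seq_len(dim(expected)[3])) {
    expected[, , j] <- expected[, , j] * stack$truth$coil[, , 1]
  }
  idx <- which(ph$masks$head)
  for (j in c(1, 5, 10)) {
    d <- Arg(pc[, , j][idx] * Conj(expected[, , j][idx]))
    expect_lt(max(abs(d)), 1e-10)
  }
})

test_that("coil combination returns the object signal with known sensitivities", {
  sched <- te_schedule(1, 1, 3)
  nx <- 6; ny <- 5
  obj <- array(complex(real = rnorm(nx * ny * 3), imaginary = rnorm(nx * ny * 3)),
               dim = c(nx, ny, 3))
  sens <- array(complex(real = rnorm(nx * ny * 2, 1, 0.2),
                        imaginary = rnorm(nx * ny * 2, 0, 0.2)),
                dim = c(nx, ny, 2))
  stacks <- array(0i, dim = c(nx, ny, 3, 2))
  for (c in 1:2) for (j in 1:3) stacks[, , j, c] <- obj[, , j] * sens[, , c]
  out <- coil_combine(stacks, sens, sched)
  expect_equal(out$data, obj, tolerance = 1e-12)
  # one channel with unit sensitivity is the identity
  s1 <- array(1 + 0i, dim = c(nx, ny, 1))
  out1 <- coil_combine(array(obj, c(nx, ny, 3, 1)), s1, sched)
  expect_equal(out1$data, obj, tolerance = 1e-12)
  # two identical channels are redundant
  s2 <- array(rep(sens[, , 1], 2), dim = c(nx, ny, 2))
  st2 <- array(0i, dim = c(nx, ny, 3, 2))
  for (c in 1:2) for (j in 1:3) st2[, , j, c] <- obj[, , j] * sens[, , 1]
  expect_equal(coil_combine(st2, s2, sched)$data, obj, tolerance = 1e-12)
})

test_that("coil combination is invariant to a consistent per-channel complex scale", {
  sched <- te_schedule(1, 1, 3)
  nx <- 5; ny <- 4
  obj <- array(complex(real = rnorm(nx * ny * 3), imaginary = rnorm(nx * ny * 3)),
               dim = c(nx, ny, 3))
  sens <- array(complex(real = rnorm(nx * ny * 2, 1, 0.1),
                        imaginary = rnorm(nx * ny * 2)), dim = c(nx, ny, 2))
  stacks <- array(0i, dim = c(nx, ny, 3, 2))
  for (c in 1:2) for (j in 1:3) stacks[, , j, c] <- obj[, , j] * sens[, , c]
  g <- c(2.5 * exp(1i * 0.4), 0.7 * exp(-1i * 1.1))
  st_s <- stacks; sn_s <- sens
  for (c in 1:2) { st_s[, , , c] <- st_s[, , , c] * g[c]; sn_s[, , c] <- sn_s[, , c] * g[c] }
  expect_equal(coil_combine(st_s, sn_s, sched)$data,
               coil_combine(stacks, sens, sched)$data, tolerance = 1e-10)
})

test_that("sensitivity estimation recovers smooth generator truth", {
  # uniform object: the smoothed first echo is (nearly) the coil map itself
  set.seed(6)
  nz <- fdm3pool:::realize_nuisance(nuisance_spec(n_channels = 4), c(48L, 48L))
  first <- nz$coil   # object = 1 everywhere
  sens <- estimate_sensitivities(first, sigma_mm = 8)
  rss_t <- sqrt(apply(Mod(nz$coil)^2, c(1, 2), sum))
  for (c in 1:4) {
    expect_gt(cor(as.vector(Mod(sens[, , c])),
                  as.vector(Mod(nz$coil[, , c]) / rss_t)), 0.99)
  }
  # RSS magnitude is one everywhere
  rss <- sqrt(apply(Mod(sens)^2, c(1, 2), sum))
  expect_equal(as.vector(rss), rep(1, 48 * 48), tolerance = 1e-10)
  # on a structured phantom the estimate still tracks the truth inside the head
  ph <- generate_phantom(phantom_spec(grid = c(48, 48)), seed = 6)
  stack <- simulate_acquisition(ph, nuisance_spec(5, 0.5, 0, n_channels = 4,
                                                  noise_sigma = 0), seed = 7)
  sens2 <- estimate_sensitivities(stack$data[, , 1, , 1], sigma_mm = 8)
  idx <- which(ph$masks$head)
  rss_p <- sqrt(apply(Mod(stack$truth$coil)^2, c(1, 2), sum))
  for (c in 1:4) {
    expect_gt(cor(Mod(sens2[, , c][idx]),
                  (Mod(stack$truth$coil[, , c]) / rss_p)[idx]), 0.9)
  }
  expect_error(estimate_sensitivities(array(0i, dim = c(4, 4, 1))), "zero")
  # single constant channel gives a constant unit-magnitude map
  cs <- estimate_sensitivities(array(3 + 0i, dim = c(8, 8, 1)))
  expect_equal(Mod(cs[, , 1]), matrix(1, 8, 8), tolerance = 1e-12)
})

test_that("three-way mask split gives equal extents with the remainder anterior", {
  m <- matrix(FALSE, 8, 40)
  m[3:6, 4:33] <- TRUE               # 30 columns
  lab <- split_cc_three(m)
  sizes <- vapply(1:3, function(s) length(unique(which(lab == s, arr.ind = TRUE)[, 2])),
                  integer(1))
  expect_equal(sizes, c(10L, 10L, 10L))
  m31 <- matrix(FALSE, 8, 40); m31[3:6, 4:34] <- TRUE   # 31 columns
  sizes31 <- vapply(1:3, function(s)
    length(unique(which(split_cc_three(m31) == s, arr.ind = TRUE)[, 2])), integer(1))
  expect_equal(sizes31, c(11L, 10L, 10L))
  # anterior label sits at the low-column end
  expect_true(all(which(lab == 1, arr.ind = TRUE)[, 2] <
                  min(which(lab == 3, arr.ind = TRUE)[, 2])))
  # partition property
  expect_equal(lab > 0, m)
  expect_error(split_cc_three(matrix(FALSE, 4, 4)), "empty")
})

test_that("splitting the generator arc agrees with the generator labels", {
  ph <- generate_phantom(phantom_spec(grid = c(96, 96)), seed = 0)
  lab <- split_cc_three(ph$masks$cc)
  agree <- mean(lab[ph$masks$cc] == ph$masks$labels[ph$masks$cc])
  expect_gte(agree, 0.95)
})

test_that("ROI averaging reduces to the single-pixel curve on uniform segments", {
  sched <- te_schedule(2, 2, 5)
  nx <- 6; ny <- 6
  p <- seg3_params()
  s <- synthesize_three_pool(p, sched)$values
  arr <- array(0i, dim = c(nx, ny, 5))
  for (j in 1:5) arr[, , j] <- s[j]
  cs <- combined_stack(arr, sched)
  fm <- compute_fdm(cs)
  labels <- matrix(0L, nx, ny); labels[2:4, 2:4] <- 3L
  rc <- roi_average(cs, fm, labels, 3)
  expect_equal(rc$magnitude, Mod(s) / Mod(s)[1], tolerance = 1e-12)
  expect_equal(rc$fdm_hz, fdm_from_complex(s, sched), tolerance = 1e-12)
  expect_error(roi_average(cs, fm, labels, 2), "empty")
})

test_that("segment-averaged curves track the segment-mean parameters within 2%", {
  ph <- generate_phantom(phantom_spec(grid = c(96, 96)), seed = 1)
  stack <- simulate_acquisition(ph, nuisance_spec(0, 0, 0, 1, 0), seed = 2)
  cs <- combined_stack(stack$truth$clean, stack$schedule,
                       valid = ph$masks$head, masks = ph$masks)
  fm <- compute_fdm(cs)
  rc <- roi_average(cs, fm, ph$masks$labels, 3)
  mean_p <- three_pool_params(
    mean(ph$param_maps$f_m[ph$masks$labels == 3]),
    mean(ph$param_maps$f_a[ph$masks$labels == 3]),
    mean(ph$param_maps$f_e[ph$masks$labels == 3]),
    omega_m_hz = mean(ph$param_maps$omega_m_hz[ph$masks$labels == 3]),
    omega_a_hz = mean(ph$param_maps$omega_a_hz[ph$masks$labels == 3]),
    r2s_m = mean(ph$param_maps$r2s_m[ph$masks$labels == 3]), r2s_a = 0,
    r2s_e = mean(ph$param_maps$r2s_e[ph$masks$labels == 3]))
  mc <- model_roi_curves(mean_p, stack$schedule)
  expect_equal(rc$magnitude, mc$magnitude, tolerance = 0.02)
  expect_lt(max(abs(rc$fdm_hz - mc$fdm_hz)), 0.02 * max(abs(mc$fdm_hz)))
})
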