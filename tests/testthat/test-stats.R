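test_that("disease burden score follows the stated arithmetic", {
  expect_equal(disease_burden_score(50, 35.5), 0)
  expect_equal(disease_burden_score(40, 42), 260)
  expect_equal(disease_burden_score(20, 39), 70)
  # linear in age at fixed CAG, increasing in CAG at fixed age
  ages <- c(20, 30, 40)
  expect_equal(diff(disease_burden_score(ages, 40)), rep(10 * 4.5, 2))
  expect_true(all(diff(disease_burden_score(45, 37:45)) > 0))
  expect_error(disease_burden_score(-1, 40), "age")
})

test_that("group-by-age regression recovers noiseless coefficients exactly", {
  set.seed(31)
  tab <- data.frame(group = rep(c("control", "hd"), each = 12),
                    age = runif(24, 20, 70))
  g <- as.integer(tab$group == "hd")
  tab$y <- 0.2 - 0.05 * g - 0.001 * tab$age + 0.0004 * g * tab$age
  fit <- suppressWarnings(fit_group_age_model(tab, "y"))  # zero-residual fit
  expect_equal(fit$coefficients$estimate,
               c(0.2, -0.05, -0.001, 0.0004), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n, 24)
})

test_that("group-label swap flips the sign of group and interaction terms only", {
  set.seed(32)
  tab <- data.frame(group = rep(c("control", "hd"), each = 10),
                    age = runif(20, 20, 70))
  tab$y <- rnorm(20, 0.15, 0.02)
  a <- fit_group_age_model(tab, "y")
  tab2 <- tab
  tab2$group <- ifelse(tab$group == "hd", "control", "hd")
  b <- fit_group_age_model(tab2, "y")
  # group coefficient: b0' = b0 + bg, bg' = -bg; age slope: ba' = ba + bga
  expect_equal(b$coefficients$estimate[2],
               -(a$coefficients$estimate[2]), tolerance = 1e-10)
  expect_equal(b$coefficients$estimate[4],
               -(a$coefficients$estimate[4]), tolerance = 1e-10)
  expect_equal(b$coefficients$p_value[c(2, 4)],
               a$coefficients$p_value[c(2, 4)], tolerance = 1e-10)
  expect_equal(b$r_squared, a$r_squared, tolerance = 1e-12)
})

test_that("regression guards degenerate designs", {
  tab <- data.frame(group = rep("hd", 12), age = runif(12, 20, 70), y = rnorm(12))
  expect_error(fit_group_age_model(tab, "y"), "both groups")
  tab2 <- data.frame(group = c(rep("hd", 2), rep("control", 10)),
                     age = runif(12, 20, 70), y = rnorm(12))
  expect_error(fit_group_age_model(tab2, "y"), "5 rows")
})

test_that("interaction-term false-positive rate is nominal under the null", {
  set.seed(33)
  hits <- replicate(400, {
    tab <- data.frame(group = rep(c("control", "hd"), each = 20),
                      age = runif(40, 20, 70), y = rnorm(40))
    fit_group_age_model(tab, "y")$coefficients$p_value[4] < 0.05
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("Spearman correlation is monotone-invariant and sign-correct", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8)
  expect_equal(spearman_rho(x, x^3)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  expect_error(spearman_rho(c(1, 1, 1, 1), c(1, 2, 3, 4)), "constant")
  expect_error(spearman_rho(1:3, 1:3), "4 paired")
})

test_that("null Spearman correlation rejects at about the nominal rate", {
  set.seed(34)
  res <- replicate(600, {
    r <- spearman_rho(runif(19), runif(19))
    c(r$rho, r$p_value < 0.05)
  })
  expect_lt(abs(median(res[1, ])), 0.1)
  expect_gt(mean(res[2, ]), 0.02)
  expect_lt(mean(res[2, ]), 0.09)
})

test_that("partial correlation removes a shared covariate and keeps independence", {
  set.seed(35)
  n <- 200
  z <- rnorm(n)
  x <- 2 * z + rnorm(n, 0, 0.3)
  y <- -1.5 * z + rnorm(n, 0, 0.3)
  pc <- partial_correlation(x, y, z)
  expect_lt(abs(pc$rho), 0.1)
  # covariate independent of both: partial approx plain Spearman
  z2 <- rnorm(n)
  x2 <- rnorm(n); y2 <- 0.6 * x2 + rnorm(n, 0, 0.5)
  expect_equal(partial_correlation(x2, y2, z2)$rho,
               spearman_rho(x2, y2)$rho, tolerance = 0.05)
  # identical variables are perfectly partially correlated
  expect_equal(partial_correlation(x, x, z)$rho, 1, tolerance = 1e-10)
  expect_warning(pc3 <- partial_correlation(x2[1:20], y2[1:20], rep(1, 20)),
                 "constant covariate")
  expect_equal(pc3$rho, spearman_rho(x2[1:20], y2[1:20])$rho)
})

test_that("Bonferroni adjustment caps, scales, and mirrors the two-test family", {
  out <- bonferroni_adjust(0.02, m = 2)
  expect_equal(out$p_adjusted, 0.04)
  expect_true(out$significant)
  expect_equal(bonferroni_adjust(c(0.5, 0.9))$p_adjusted, c(1, 1))
  expect_equal(bonferroni_adjust(0.03)$p_adjusted, 0.03)
  expect_equal(bonferroni_adjust(c(0.01, 0.4))$p_adjusted,
               p.adjust(c(0.01, 0.4), method = "bonferroni"))
  expect_error(bonferroni_adjust(c(0.2, 1.4)), "0, 1")
})

test_that("study-level effects analysis returns the declared structure", {
  sim <- simulate_study(seed = 36)
  ft <- fit_study_curves(sim)
  ge <- analyze_group_effects(ft)
  expect_named(ge, c("regression_f_m", "regression_delta_omega",
                     "correlations", "partial_exec_age"))
  expect_equal(nrow(ge$correlations), 2)
  expect_equal(ge$correlations$p_adjusted,
               pmin(1, 2 * ge$correlations$p_raw))
  expect_equal(ge$regression_f_m$n, 40)
})
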