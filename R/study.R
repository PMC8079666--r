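#' Specification of the simulated patient-control study
#'
#' Defines the cohort and the ground-truth effect structure of the
#' cross-sectional comparison: premanifest gene carriers ("hd") versus
#' matched controls, each subject carrying true posterior-segment tissue
#' parameters that depend on group and age, plus a synthetic scalar
#' "executive score" with a configurable group-by-age interaction.
#'
#' True subject-level myelin fraction follows
#' `f_m = mean_group + slope_group * (age - age_center) + N(0, subject_sd)`,
#' with an additional residual (visit/measurement) deviation per acquired
#' curve; the offset difference `delta omega` carries an age slope but no
#' group effect by default.
#'
#' @param n_hd,n_control Group sizes.
#' @param age_range_hd,age_range_control Uniform age ranges (years).
#' @param cag_mean,cag_sd,cag_range CAG repeat sampler (integers, clamped).
#' @param age_center Age (years) at which the group means are defined.
#' @param fm_mean Named vector `c(control=, hd=)`: true mean `f_m` at
#'   `age_center`.
#' @param fm_slope Named vector of per-year age slopes of `f_m`.
#' @param fm_subject_sd,fm_visit_sd Between-subject and residual SDs of `f_m`.
#' @param dw_mean Named vector of mean `delta omega / 2 pi` (Hz).
#' @param dw_slope Named vector of per-year slopes of `delta omega` (Hz/yr).
#' @param dw_subject_sd,dw_visit_sd Between-subject and residual SDs (Hz).
#' @param omega_a_mean_hz,omega_a_sd_hz Axonal-pool offset distribution.
#' @param exec_coef Named vector `c(intercept=, group=, age=, interaction=)`
#'   for the synthetic executive score.
#' @param exec_fm_coef Coupling of the executive score to the subject's
#'   true myelin fraction (score units per unit `f_m`); gives the
#'   within-patient brain-function correlation. Set to 0 for no coupling.
#' @param exec_sd Residual SD of the executive score.
#' @param n_visits Number of visits per subject (1 for the HD study).
#' @param roi_noise_sd Complex noise SD added to each ROI curve, as a
#'   fraction of the first-echo signal.
#' @return An object of class `study_spec`.
#' @export
study_spec <- function(n_hd = 19L, n_control = 21L,
                       age_range_hd = c(21, 70), age_range_control = c(27, 71),
                       cag_mean = 41.3, cag_sd = 2.14, cag_range = c(37L, 45L),
                       age_center = 45,
                       fm_mean = c(control = 0.16, hd = 0.112),
                       fm_slope = c(control = -8e-4, hd = -1e-4),
                       fm_subject_sd = 0.01, fm_visit_sd = 0.005,
                       dw_mean = c(control = 35.8, hd = 35.8),
                       dw_slope = c(control = 0.05, hd = 0.05),
                       dw_subject_sd = 1.0, dw_visit_sd = 0.5,
                       omega_a_mean_hz = -8.5, omega_a_sd_hz = 0.5,
                       exec_coef = c(intercept = 0.5, group = 1.9,
                                     age = 0.004, interaction = -0.06),
                       exec_fm_coef = 70,
                       exec_sd = 0.9,
                       n_visits = 1L, roi_noise_sd = 1.1e-4) {
  spec <- structure(as.list(environment()), class = "study_spec")
  ages <- c(age_range_hd, age_range_control)
  fm_extremes <- c(
    fm_mean + fm_slope * (min(ages) - age_center),
    fm_mean + fm_slope * (max(ages) - age_center))
  if (any(fm_extremes - 4 * (fm_subject_sd + fm_visit_sd) <= 0) ||
      any(fm_extremes + 4 * (fm_subject_sd + fm_visit_sd) >= 1))
    stop("configured effects drive f_m outside (0, 1)", call. = FALSE)
  spec
}

# draw one subject x visit ROI curve from true parameters + complex noise
noisy_roi_curves <- function(params, schedule, roi_noise_sd, segment = NA_integer_) {
  s <- synthesize_three_pool(params, schedule)$values
  if (roi_noise_sd > 0) {
    n <- length(s)
    s <- s + complex(real = stats::rnorm(n, 0, roi_noise_sd),
                     imaginary = stats::rnorm(n, 0, roi_noise_sd))
  }
  roi_curves(schedule, Mod(s) / Mod(s)[1], fdm_from_complex(s, schedule),
             segment = segment)
}

clamp01 <- function(x, lo = 0.02, hi = 0.6) pmin(hi, pmax(lo, x))

#' Simulate the patient-control study (fast path: ROI curves directly)
#'
#' Draws the cohort (ages, groups, CAG repeats), true posterior-segment
#' tissue parameters per subject and visit, a synthetic executive score,
#' and the corresponding noisy ROI curves; all ground truth is recorded.
#' Deterministic under a fixed seed.
#'
#' @param spec A [study_spec()].
#' @param schedule A [te_schedule()].
#' @param seed Integer seed.
#' @return List with `table` (one row per subject x visit: `subject_id`,
#'   `group`, `age`, `cag`, `dbs`, `visit`, `exec_score`, true `f_m_true`,
#'   `delta_omega_true_hz`) and `curves` (list of [roi_curves()], one per
#'   row).
#' @export
simulate_study <- function(spec = study_spec(), schedule = default_schedule(),
                           seed = 1L) {
  stopifnot(inherits(spec, "study_spec"))
  with_seed(seed, {
    n <- spec$n_hd + spec$n_control
    group <- c(rep("hd", spec$n_hd), rep("control", spec$n_control))
    age <- c(stats::runif(spec$n_hd, spec$age_range_hd[1], spec$age_range_hd[2]),
             stats::runif(spec$n_control, spec$age_range_control[1],
                          spec$age_range_control[2]))
    cag <- ifelse(group == "hd",
                  pmin(spec$cag_range[2], pmax(spec$cag_range[1],
                       round(stats::rnorm(n, spec$cag_mean, spec$cag_sd)))),
                  NA_real_)
    gidx <- ifelse(group == "hd", "hd", "control")
    fm_subj <- spec$fm_mean[gidx] + spec$fm_slope[gidx] * (age - spec$age_center) +
      stats::rnorm(n, 0, spec$fm_subject_sd)
    dw_subj <- spec$dw_mean[gidx] + spec$dw_slope[gidx] * (age - spec$age_center) +
      stats::rnorm(n, 0, spec$dw_subject_sd)
    g01 <- as.integer(group == "hd")
    exec <- spec$exec_coef[["intercept"]] + spec$exec_coef[["group"]] * g01 +
      spec$exec_coef[["age"]] * age +
      spec$exec_coef[["interaction"]] * g01 * age +
      spec$exec_fm_coef * (fm_subj - mean(spec$fm_mean)) +
      stats::rnorm(n, 0, spec$exec_sd)
    rows <- list(); curves <- list(); r <- 0L
    for (i in seq_len(n)) for (v in seq_len(spec$n_visits)) {
      r <- r + 1L
      fm_true <- clamp01(fm_subj[i] + stats::rnorm(1, 0, spec$fm_visit_sd))
      dw_true <- max(5, dw_subj[i] + stats::rnorm(1, 0, spec$dw_visit_sd))
      wa <- stats::rnorm(1, spec$omega_a_mean_hz, spec$omega_a_sd_hz)
      p <- three_pool_params(fm_true, (1 - fm_true) / 2, (1 - fm_true) / 2,
                             omega_m_hz = wa + dw_true, omega_a_hz = wa,
                             r2s_m = 150, r2s_a = 0, r2s_e = 25)
      curves[[r]] <- noisy_roi_curves(p, schedule, spec$roi_noise_sd, segment = 3L)
      rows[[r]] <- data.frame(
        subject_id = sprintf("S%03d", i), group = group[i], age = age[i],
        cag = cag[i],
        dbs = if (group[i] == "hd") disease_burden_score(age[i], cag[i]) else NA_real_,
        visit = v, exec_score = exec[i],
        f_m_true = fm_true, delta_omega_true_hz = dw_true)
    }
    list(table = do.call(rbind, rows), curves = curves, seed = seed)
  })
}

#' Simulate the multi-visit reproducibility study
#'
#' Healthy test-retest design: `n_subjects` scanned `n_visits` times, all
#' three callosal segments per scan. Per-segment visit-to-visit parameter
#' noise defaults to the published test-retest SDs, which decrease from
#' anterior to posterior (the anterior segment is the least reproducible,
#' consistent with in-flow artefacts near the anterior cerebral artery
#' that the generator does not model mechanistically).
#'
#' @param n_subjects,n_visits Design size (defaults 6 subjects, 5 visits).
#' @param visit_sd List of per-segment visit SDs: `f_m` (fractions),
#'   `omega_a_hz`, `omega_m_hz` (Hz), each length 3 (anterior, mid,
#'   posterior).
#' @param subject_sd Between-subject SD of `f_m` (offsets scale alike).
#' @param roi_noise_sd Complex curve noise as in [study_spec()].
#' @param schedule A [te_schedule()].
#' @param seed Integer seed.
#' @return List with `table` (subject, visit, segment, true parameters)
#'   and `curves` (list of [roi_curves()] aligned with rows).
#' @export
simulate_repro_study <- function(n_subjects = 6L, n_visits = 5L,
                                 visit_sd = list(
                                   f_m = c(0.08, 0.04, 0.02),
                                   omega_a_hz = c(2.0, 1.1, 0.6),
                                   omega_m_hz = c(10.2, 4.4, 2.1)),
                                 subject_sd = 0.01,
                                 roi_noise_sd = 1.1e-4,
                                 schedule = default_schedule(), seed = 1L) {
  stopifnot(n_subjects >= 2L, n_visits >= 2L)
  with_seed(seed, {
    rows <- list(); curves <- list(); r <- 0L
    for (i in seq_len(n_subjects)) {
      subj_shift_fm <- stats::rnorm(1, 0, subject_sd)
      subj_shift_wa <- stats::rnorm(1, 0, 0.3)
      subj_shift_wm <- stats::rnorm(1, 0, 1.0)
      for (v in seq_len(n_visits)) for (s in 1:3) {
        r <- r + 1L
        mp <- segment_mean_params(s)
        mw <- omega_hz(mp)
        fm <- clamp01(mp$f_m + subj_shift_fm + stats::rnorm(1, 0, visit_sd$f_m[s]))
        wa <- mw[["omega_a_hz"]] + subj_shift_wa +
          stats::rnorm(1, 0, visit_sd$omega_a_hz[s])
        wm <- mw[["omega_m_hz"]] + subj_shift_wm +
          stats::rnorm(1, 0, visit_sd$omega_m_hz[s])
        wm <- max(wm, wa + 5)      # keep the myelin pool the fast, high-offset one
        p <- three_pool_params(fm, (1 - fm) / 2, (1 - fm) / 2,
                               omega_m_hz = min(wm, 49.9), omega_a_hz = max(wa, -29.9),
                               r2s_m = 150, r2s_a = 0, r2s_e = 25)
        curves[[r]] <- noisy_roi_curves(p, schedule, roi_noise_sd, segment = s)
        rows[[r]] <- data.frame(subject_id = sprintf("S%02d", i), visit = v,
                                segment = s, f_m_true = fm,
                                omega_a_true_hz = wa, omega_m_true_hz = wm,
                                delta_omega_true_hz = wm - wa)
      }
    }
    list(table = do.call(rbind, rows), curves = curves, seed = seed)
  })
}

#' Fit every curve of a simulated study
#'
#' Runs [fit_three_pool()] on each ROI curve of a [simulate_study()] or
#' [simulate_repro_study()] output and appends the fitted metrics
#' (sum-normalised `f_m`, pool offsets, `delta omega`) to the study table.
#'
#' @param sim Output of [simulate_study()] or [simulate_repro_study()].
#' @param config A [fit_config()].
#' @return The study table with columns `f_m`, `omega_a_hz`,
#'   `omega_m_hz`, `delta_omega_hz`, `converged` appended.
#' @export
fit_study_curves <- function(sim, config = fit_config()) {
  fits <- lapply(sim$curves, fit_three_pool, config = config)
  tab <- sim$table
  tab$f_m <- vapply(fits, function(f) f$fractions_normalized[["f_m"]], numeric(1))
  tab$omega_a_hz <- vapply(fits, function(f) omega_hz(f$params)[["omega_a_hz"]], numeric(1))
  tab$omega_m_hz <- vapply(fits, function(f) omega_hz(f$params)[["omega_m_hz"]], numeric(1))
  tab$delta_omega_hz <- vapply(fits, function(f) f$delta_omega_hz, numeric(1))
  tab$converged <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  tab
}

#' Reproducibility summary of a fitted multi-visit table
#'
#' Computes, per subject x segment x metric, the across-visit mean, SD and
#' CV%, then the per-segment summary CV (mean of per-subject CVs), and the
#' modified signed-likelihood ratio test comparing the three segments'
#' CVs for each metric (groups = pooled per-subject visit values after
#' per-subject mean-scaling is NOT applied; the test operates on the raw
#' per-subject visit series of the segment with subjects pooled via their
#' common segment distribution).
#'
#' @param fit_table Output of [fit_study_curves()] on a repro design.
#' @param metrics Character vector of metric columns to summarise.
#' @param nsim Bootstrap size for [mslrt_cv_equality()].
#' @return List with `cv_table` (per subject x segment x metric),
#'   `segment_cv` (per segment x metric mean CV%), `mslrt` (per metric
#'   test results).
#' @export
analyze_reproducibility <- function(fit_table,
                                    metrics = c("f_m", "omega_a_hz",
                                                "omega_m_hz", "delta_omega_hz"),
                                    nsim = 1000L) {
  stopifnot(all(c("subject_id", "visit", "segment") %in% names(fit_table)))
  rows <- list()
  for (m in metrics) for (s in sort(unique(fit_table$segment)))
    for (id in unique(fit_table$subject_id)) {
      v <- fit_table[[m]][fit_table$segment == s & fit_table$subject_id == id]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, segment = s, metric = m,
        mean = mean(v), sd = stats::sd(v), cv_pct = abs(cv_percent(v)))
    }
  cv_table <- do.call(rbind, rows)
  segment_cv <- stats::aggregate(cv_pct ~ segment + metric, cv_table, mean)
  mslrt <- lapply(stats::setNames(metrics, metrics), function(m) {
    groups <- lapply(sort(unique(fit_table$segment)), function(s) {
      x <- fit_table[[m]][fit_table$segment == s]
      if (mean(x) < 0) -x else x     # CV equality is scale-free; use positive means
    })
    mslrt_cv_equality(groups, nsim = nsim)
  })
  list(cv_table = cv_table, segment_cv = segment_cv, mslrt = mslrt)
}

#' Group-level inference on a fitted study table
#'
#' Runs the group-by-age regressions on posterior-segment `f_m` and
#' `delta omega`, and, within the patient group, Spearman correlations of
#' `f_m` with the executive score and with the disease burden score
#' (Bonferroni-corrected as a family of two), following up the executive
#' correlation with an age-controlled rank partial correlation.
#'
#' @param fit_table Output of [fit_study_curves()] on an HD-study design.
#' @param family_alpha Family-wise alpha for the correlation family.
#' @return List with `regression_f_m`, `regression_delta_omega`,
#'   `correlations` (data frame with raw/adjusted p-values) and
#'   `partial_exec_age` (age-controlled partial correlation).
#' @export
analyze_group_effects <- function(fit_table, family_alpha = 0.05) {
  reg_fm <- fit_group_age_model(fit_table, "f_m")
  reg_dw <- fit_group_age_model(fit_table, "delta_omega_hz")
  hd <- fit_table[fit_table$group == "hd", ]
  c_exec <- spearman_rho(hd$f_m, hd$exec_score)
  c_dbs <- spearman_rho(hd$f_m, hd$dbs)
  fam <- bonferroni_adjust(c(c_exec$p_value, c_dbs$p_value),
                           family_alpha = family_alpha)
  correlations <- cbind(data.frame(
    pair = c("f_m~exec_score", "f_m~dbs"),
    rho = c(c_exec$rho, c_dbs$rho), n = c(c_exec$n, c_dbs$n)), fam)
  partial <- partial_correlation(hd$f_m, hd$exec_score, hd$age)
  list(regression_f_m = reg_fm, regression_delta_omega = reg_dw,
       correlations = correlations, partial_exec_age = partial)
}
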