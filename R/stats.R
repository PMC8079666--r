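#' Disease burden score
#'
#' `DBS = age * (CAG - 35.5)`: an index of cumulative exposure to the
#' expanded huntingtin CAG repeat, higher values indicating closer
#' proximity to clinical onset.
#'
#' @param age Age in years (> 0); vectorised.
#' @param cag CAG repeat length; vectorised.
#' @return Numeric disease burden score(s).
#' @examples
#' disease_burden_score(40, 42)  # 260
#' @export
disease_burden_score <- function(age, cag) {
  if (!is.numeric(age) || !is.numeric(cag) || any(!is.finite(age)) ||
      any(!is.finite(cag)) || any(age <= 0))
    stop("`age` must be positive and `cag` finite", call. = FALSE)
  age * (cag - 35.5)
}

#' Group-by-age multiple regression on a fitted metric
#'
#' Ordinary least squares of an outcome on group (0 = control, 1 = HD),
#' age, and their interaction, with two-sided coefficient tests. Age is
#' left uncentred by default; centring changes the interpretation (and
#' power) of the group main effect when an interaction is present and is
#' exposed as an option.
#'
#' @param table Data frame with columns `group` ("control"/"hd"), `age`,
#'   and the outcome.
#' @param outcome Name of the outcome column.
#' @param center_age If `TRUE`, age is mean-centred before fitting.
#' @return List with `coefficients` (data frame: term, estimate, se,
#'   t, p_value), `r_squared`, `f_statistic`, `n`.
#' @export
fit_group_age_model <- function(table, outcome, center_age = FALSE) {
  stopifnot(is.data.frame(table), all(c("group", "age", outcome) %in% names(table)))
  g <- as.integer(table$group == "hd")
  if (length(unique(g)) < 2L) stop("both groups must be present", call. = FALSE)
  if (min(table(g)) < 5L) stop("need at least 5 rows per group", call. = FALSE)
  age <- if (center_age) table$age - mean(table$age) else table$age
  y <- table[[outcome]]
  fit <- stats::lm(y ~ g + age + g:age)
  sm <- summary(fit)
  if (any(is.na(stats::coef(fit)))) stop("singular design", call. = FALSE)
  co <- sm$coefficients
  list(coefficients = data.frame(
         term = c("intercept", "group", "age", "group_x_age"),
         estimate = unname(co[, 1L]), se = unname(co[, 2L]),
         t = unname(co[, 3L]), p_value = unname(co[, 4L])),
       r_squared = sm$r.squared,
       f_statistic = unname(sm$fstatistic),
       n = length(y))
}

#' Spearman rank correlation
#'
#' @param x,y Numeric vectors (>= 4 paired values, non-constant).
#' @return List with `rho`, `p_value` (two-sided, asymptotic), `n`.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Rank-based partial correlation controlling for one covariate
#'
#' Spearman-type partial correlation: `x`, `y` and the covariate are
#' ranked, the ranks of `x` and `y` are each residualised on the ranks of
#' the covariate by OLS, and the Pearson correlation of the residuals is
#' returned with a t-test on `n - 3` degrees of freedom. If the covariate
#' is constant it cannot mediate anything: the plain Spearman correlation
#' is returned with a warning.
#'
#' @param x,y Numeric vectors (>= 5 triples).
#' @param covariate Numeric vector of the controlling variable.
#' @return List with `rho`, `p_value`, `n`.
#' @export
partial_correlation <- function(x, y, covariate) {
  ok <- is.finite(x) & is.finite(y) & is.finite(covariate)
  x <- x[ok]; y <- y[ok]; covariate <- covariate[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 complete triples", call. = FALSE)
  if (stats::sd(covariate) == 0) {
    warning("constant covariate: falling back to the unadjusted Spearman correlation")
    return(spearman_rho(x, y))
  }
  rx <- rank(x); ry <- rank(y); rz <- rank(covariate)
  ex <- stats::residuals(stats::lm(rx ~ rz))
  ey <- stats::residuals(stats::lm(ry ~ rz))
  rho <- stats::cor(ex, ey)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 3) / (1 - rho^2))
    2 * stats::pt(abs(tval), df = n - 3, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Bonferroni correction over a declared family of tests
#'
#' Adjusted p-values are `min(1, m * p)` with `m` the family size;
#' decisions compare the adjusted value with the family-wise alpha.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size (defaults to `length(p_values)`).
#' @param family_alpha Family-wise error level (default 0.05).
#' @return Data frame with `p_raw`, `p_adjusted`, `significant`.
#' @examples
#' bonferroni_adjust(0.02, m = 2)  # adjusted 0.04
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values),
                              family_alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- pmin(1, m * p_values)
  data.frame(p_raw = p_values, p_adjusted = adj,
             significant = adj < family_alpha)
}
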