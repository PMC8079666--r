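#' Discrete Frechet distance between two polygonal curves
#'
#' The minimum, over order-preserving couplings of the two point
#' sequences, of the maximum pairwise Euclidean distance — the shortest
#' cord length joining a point travelling forward along `P` and one
#' travelling forward along `Q`. Computed by the standard dynamic
#' programme; symmetric, zero iff the sequences traverse identical point
#' sets in order, and bounded below by the larger endpoint distance.
#'
#' @param p,q Numeric matrices (n x 2), one point per row. For FDM curves
#'   the convention is x = TE in ms, y = frequency difference in Hz.
#' @param scale Length-2 multiplicative axis weights applied to both
#'   curves before computing distances (default `c(1, 1)`, i.e. ms and Hz
#'   enter untransformed).
#' @return The discrete Frechet distance (scalar).
#' @examples
#' discrete_frechet(cbind(0:1, c(0, 0)), cbind(0:1, c(1, 1)))  # 1
#' @export
discrete_frechet <- function(p, q, scale = c(1, 1)) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) == 0L || nrow(q) == 0L) stop("empty point sequence", call. = FALSE)
  stopifnot(ncol(p) == 2L, ncol(q) == 2L, length(scale) == 2L)
  p <- sweep(p, 2L, scale, "*"); q <- sweep(q, 2L, scale, "*")
  n <- nrow(p); m <- nrow(q)
  d <- sqrt(outer(p[, 1L], q[, 1L], "-")^2 + outer(p[, 2L], q[, 2L], "-")^2)
  ca <- matrix(0, n, m)
  ca[1L, 1L] <- d[1L, 1L]
  for (i in 2:max(2L, n)) if (n > 1L) ca[i, 1L] <- max(ca[i - 1L, 1L], d[i, 1L])
  for (j in 2:max(2L, m)) if (m > 1L) ca[1L, j] <- max(ca[1L, j - 1L], d[1L, j])
  if (n > 1L && m > 1L) {
    for (i in 2:n) for (j in 2:m)
      ca[i, j] <- max(min(ca[i - 1L, j], ca[i - 1L, j - 1L], ca[i, j - 1L]),
                      d[i, j])
  }
  ca[n, m]
}

#' Pairwise Frechet distance matrix across visits
#'
#' @param curves List of per-visit curves: [roi_curves()] objects (their
#'   `(TE, FDM)` points are used) or n x 2 point matrices.
#' @param scale Axis weights passed to [discrete_frechet()].
#' @return Symmetric visit-by-visit distance matrix with zero diagonal.
#' @export
frechet_matrix <- function(curves, scale = c(1, 1)) {
  if (length(curves) < 2L) stop("need at least 2 visits", call. = FALSE)
  pts <- lapply(curves, function(cv) {
    if (inherits(cv, "roi_curves")) cbind(cv$schedule$te_ms, cv$fdm_hz)
    else as.matrix(cv)
  })
  k <- length(pts)
  out <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    out[i, j] <- out[j, i] <- discrete_frechet(pts[[i]], pts[[j]], scale)
  out
}

#' Coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param values Numeric vector with at least 2 values and non-zero mean.
#' @return CV in percent.
#' @examples
#' cv_percent(c(10, 12, 14))  # 16.67
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

# profile negative log-likelihood under the common-CV null, vectorised
# over replicates: tau (B), xbar/m2 (B x k), nmat (B x k)
common_cv_nll <- function(tau, xbar, m2, nmat) {
  tt <- matrix(tau, nrow(xbar), ncol(xbar))
  mu <- (-xbar + sqrt(xbar^2 + 4 * tt^2 * m2)) / (2 * tt^2)
  ss <- m2 - 2 * mu * xbar + mu^2          # mean squared deviation about mu
  rowSums(nmat / 2 * log(2 * pi * tt^2 * mu^2) + nmat * ss / (2 * tt^2 * mu^2))
}

# maximised common-CV log-likelihood by golden-section search on log(tau);
# returns list(tau, loglik), vectorised over replicate rows
profile_common_cv <- function(xbar, m2, nmat, iters = 60L) {
  sig2 <- pmax(m2 - xbar^2, .Machine$double.xmin)
  tau0 <- rowSums(sqrt(sig2) / xbar) / ncol(xbar)
  a <- log(tau0) - log(50); b <- log(tau0) + log(50)
  gr <- (sqrt(5) - 1) / 2
  for (it in seq_len(iters)) {
    c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
    sel <- common_cv_nll(exp(c1), xbar, m2, nmat) <
           common_cv_nll(exp(d1), xbar, m2, nmat)
    b[sel] <- d1[sel]; a[!sel] <- c1[!sel]
  }
  tau <- exp((a + b) / 2)
  list(tau = tau, loglik = -common_cv_nll(tau, xbar, m2, nmat))
}

# signed root of the likelihood-ratio statistic for CV equality,
# vectorised: inputs are B x k sufficient-statistic matrices
lrt_root <- function(xbar, m2, nmat) {
  sig2 <- pmax(m2 - xbar^2, .Machine$double.xmin)     # ML variances
  l1 <- rowSums(-nmat / 2 * (log(2 * pi * sig2) + 1))
  l0 <- profile_common_cv(xbar, m2, nmat)$loglik
  sqrt(pmax(2 * (l1 - l0), 0))
}

#' Modified signed-likelihood ratio test for equality of CVs
#'
#' Tests whether `k >= 2` normal samples share a common coefficient of
#' variation. The likelihood ratio compares the unconstrained fit with the
#' common-CV null, whose constrained maximum is found by one-dimensional
#' numerical optimisation of the profile likelihood in the common CV (the
#' per-group means have a closed-form profile solution). Because the
#' chi-square approximation to the likelihood ratio is poor at the small
#' group sizes typical of test-retest designs, a small-sample correction
#' is applied to the signed root `r = sqrt(LRT)`: its null mean and
#' standard deviation are estimated by a seeded parametric bootstrap at
#' the fitted null, `r` is moment-matched to the chi distribution with
#' `k - 1` degrees of freedom, and the squared corrected root is referred
#' to the chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param groups List of numeric vectors, each with at least 2 values,
#'   positive mean and non-zero variance.
#' @param nsim Number of bootstrap replicates for the correction.
#' @return List with `statistic` (corrected chi-square statistic),
#'   `p_value`, `df`, `uncorrected` (raw LRT statistic), `tau_hat`
#'   (fitted common CV) and `method`.
#' @export
mslrt_cv_equality <- function(groups, nsim = 1000L) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("each group needs at least 2 values", call. = FALSE)
  xbar <- vapply(groups, mean, numeric(1))
  if (any(!is.finite(xbar)) || any(xbar <= 0))
    stop("each group must have a positive finite mean", call. = FALSE)
  s2 <- vapply(groups, function(g) mean((g - mean(g))^2), numeric(1))
  if (any(s2 == 0)) stop("degenerate group with zero variance", call. = FALSE)
  k <- length(groups)
  m2 <- vapply(groups, function(g) mean(g^2), numeric(1))
  xb <- matrix(xbar, 1L); mm <- matrix(m2, 1L); nm <- matrix(n, 1L)
  r_obs <- lrt_root(xb, mm, nm)
  prof <- profile_common_cv(xb, mm, nm)
  tau_hat <- prof$tau
  # parametric bootstrap of r under the fitted common-CV null
  mu0 <- as.numeric((-xbar + sqrt(xbar^2 + 4 * tau_hat^2 * m2)) / (2 * tau_hat^2))
  B <- as.integer(nsim)
  xbar_b <- m2_b <- matrix(0, B, k)
  for (i in seq_len(k)) {
    draws <- matrix(stats::rnorm(B * n[i], mu0[i], tau_hat * mu0[i]), B, n[i])
    xbar_b[, i] <- rowMeans(draws)
    m2_b[, i] <- rowMeans(draws^2)
  }
  ok <- rowSums(xbar_b <= 0) == 0
  r_b <- lrt_root(xbar_b[ok, , drop = FALSE], m2_b[ok, , drop = FALSE],
                  matrix(n, sum(ok), k, byrow = TRUE))
  df <- k - 1L
  mean_chi <- sqrt(2) * gamma(k / 2) / gamma((k - 1) / 2)
  sd_chi <- sqrt(df - mean_chi^2)
  r_star <- mean_chi + (r_obs - mean(r_b)) * sd_chi / stats::sd(r_b)
  stat <- max(r_star, 0)^2
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       df = df, uncorrected = r_obs^2, tau_hat = tau_hat,
       method = "modified signed-likelihood ratio test for equality of CVs")
}
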