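#' Temporal phase unwrapping
#'
#' Unwraps phase along the echo dimension only (no spatial unwrapping):
#' integer multiples of 2*pi are added so that every successive difference
#' lies in (-pi, pi]. Works on a vector (one series) or a matrix with one
#' series per row and echoes in columns.
#'
#' @param phase Numeric vector or matrix of phase values in radians.
#' @return Unwrapped phase with the same shape; the first echo is unchanged.
#' @examples
#' temporal_unwrap(c(3.0, -3.0))  # c(3.0, 3.2832)
#' @export
temporal_unwrap <- function(phase) {
  if (is.null(dim(phase))) {
    if (length(phase) < 1L) stop("empty phase series", call. = FALSE)
    if (length(phase) == 1L) return(phase)
    d <- diff(phase)
    d <- d - 2 * pi * ceiling((d - pi) / (2 * pi))  # wrap into (-pi, pi]
    return(phase[1L] + c(0, cumsum(d)))
  }
  ph <- phase
  ne <- ncol(ph)
  if (ne < 1L) stop("empty phase series", call. = FALSE)
  out <- ph
  if (ne > 1L) {
    for (j in 2:ne) {
      d <- ph[, j] - ph[, j - 1L]
      d <- d - 2 * pi * ceiling((d - pi) / (2 * pi))
      out[, j] <- out[, j - 1L] + d
    }
  }
  out
}

# Core FDM operator on unwrapped-able phase series (rows = series).
# phi_lin is the line through (TE1, phi1) and (TE2, phi2);
# FDM_n = (phi_n - phi_lin(TE_n)) / (2 pi (TE_n - TE_1)) for n >= 3,
# FDM_1 = FDM_2 = 0 by construction. TE in ms, output in Hz.
fdm_from_phase <- function(phase, te_ms) {
  te_s <- te_ms / 1000
  if (is.null(dim(phase))) {
    ne <- length(phase)
    if (ne < 3L) stop("frequency difference mapping needs at least 3 echoes",
                      call. = FALSE)
    if (length(te_ms) != ne) stop("TE grid does not match the phase series",
                                  call. = FALSE)
    uw <- temporal_unwrap(phase)
    slope <- (uw[2L] - uw[1L]) / (te_s[2L] - te_s[1L])
    dt <- te_s - te_s[1L]
    out <- c(0, 0, (uw[-(1:2)] - (uw[1L] + slope * dt[-(1:2)])) /
                   (2 * pi * dt[-(1:2)]))
    return(out)
  }
  ph <- phase
  ne <- ncol(ph)
  if (ne < 3L) stop("frequency difference mapping needs at least 3 echoes",
                    call. = FALSE)
  if (length(te_ms) != ne) stop("TE grid does not match the phase series",
                                call. = FALSE)
  uw <- temporal_unwrap(ph)
  slope <- (uw[, 2L] - uw[, 1L]) / (te_s[2L] - te_s[1L])
  out <- matrix(0, nrow(ph), ne)
  for (j in 3:ne) {
    lin <- uw[, 1L] + slope * (te_s[j] - te_s[1L])
    out[, j] <- (uw[, j] - lin) / (2 * pi * (te_s[j] - te_s[1L]))
  }
  out
}

#' Frequency-difference series of a complex signal curve
#'
#' Applies the frequency-difference operator to the phase of a complex
#' echo series: the phase is temporally unwrapped, the linear reference
#' through the first two echoes is subtracted, and the residual is
#' normalised by `2*pi*(TE_n - TE_1)`. The first two echoes are 0 by
#' construction. Adding any TE-independent phase or any linear-in-TE
#' (static frequency) phase to the input leaves the output unchanged.
#'
#' @param values Complex vector, one value per echo.
#' @param schedule A [te_schedule()] (or numeric TE vector in ms).
#' @return Numeric vector of frequency differences in Hz.
#' @export
fdm_from_complex <- function(values, schedule) {
  te_ms <- if (inherits(schedule, "te_schedule")) schedule$te_ms else schedule
  if (length(values) != length(te_ms))
    stop("curve length does not match the TE grid", call. = FALSE)
  fdm_from_phase(Arg(values), te_ms)
}

#' Frequency difference maps from a combined echo stack
#'
#' Converts the per-echo phase of a polarity-corrected, coil-combined
#' complex stack into per-echo frequency-difference maps (Hz), pixel by
#' pixel, using the same operator as [fdm_from_complex()]. TE-independent
#' phase offsets (RF-related) and static frequency maps (non-local B0
#' field) cancel exactly.
#'
#' @param combined A `combined_stack` (see [polarity_correct()] /
#'   [coil_combine()]) or a complex array `nx x ny x n_echoes` (then
#'   `schedule` and `valid` must be given).
#' @param schedule,valid TE schedule and logical validity mask, only for
#'   raw-array input.
#' @return An object of class `fdm_maps`: list with `maps` (array
#'   `nx x ny x n_echoes`, Hz; the first two echo maps are zero), `schedule`
#'   and logical `valid`.
#' @export
compute_fdm <- function(combined, schedule = NULL, valid = NULL) {
  if (inherits(combined, "combined_stack")) {
    arr <- combined$data; schedule <- combined$schedule
    if (is.null(valid)) valid <- combined$valid
  } else arr <- combined
  stopifnot(inherits(schedule, "te_schedule"), length(dim(arr)) == 3L)
  d <- dim(arr)
  if (d[3L] != schedule$n_echoes)
    stop("stack echo dimension does not match the schedule", call. = FALSE)
  if (d[3L] < 3L) stop("frequency difference mapping needs at least 3 echoes",
                       call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, d[1L], d[2L])
  ph <- matrix(Arg(arr), d[1L] * d[2L], d[3L])
  fdm <- fdm_from_phase(ph, schedule$te_ms)
  maps <- array(fdm, dim = d)
  maps[array(!valid, dim = d)] <- NA_real_
  structure(list(maps = maps, schedule = schedule, valid = valid),
            class = "fdm_maps")
}

# 2D polynomial design matrix of total degree <= degree on centred/scaled
# pixel coordinates; columns ordered by total degree then x-power.
poly2d_basis <- function(xs, ys, degree) {
  cols <- list()
  for (d in 0:degree) for (px in d:0) {
    py <- d - px
    cols[[length(cols) + 1L]] <- xs^px * ys^py
  }
  do.call(cbind, cols)
}

#' Spatial polynomial detrending of frequency difference maps
#'
#' Fits, per echo, an ordinary least-squares 2D polynomial of total degree
#' `degree` (default 3) over the valid pixels and subtracts it, removing
#' residual eddy-current structure. The operation is a linear projection:
#' applying it twice equals applying it once, and it annihilates any input
#' that is itself such a polynomial.
#'
#' The polynomial can optionally be estimated on the valid pixels
#' *outside* a structure-of-interest mask (`exclude`) and subtracted
#' everywhere: the instrumental residual is spatially global and smooth,
#' so estimating it from surrounding tissue avoids absorbing part of the
#' genuine frequency-difference signal of the structure being quantified.
#'
#' @param fdm An `fdm_maps` object from [compute_fdm()].
#' @param degree Total polynomial degree (default 3, 10 coefficients).
#' @param exclude Optional logical mask of pixels excluded from the
#'   polynomial estimation (still detrended).
#' @return An `fdm_maps` object with the per-echo polynomial removed.
#' @export
detrend_poly2d <- function(fdm, degree = 3L, exclude = NULL) {
  stopifnot(inherits(fdm, "fdm_maps"))
  d <- dim(fdm$maps)
  fit_mask <- fdm$valid
  if (!is.null(exclude)) fit_mask <- fit_mask & !exclude
  idx_fit <- which(fit_mask)
  idx <- which(fdm$valid)
  p <- (degree + 1) * (degree + 2) / 2
  if (length(idx_fit) < p)
    stop("too few valid pixels to fit a degree-", degree, " 2D polynomial",
         call. = FALSE)
  coord <- function(ii) {
    rows <- (ii - 1L) %% d[1L] + 1L
    cols <- (ii - 1L) %/% d[1L] + 1L
    # centred/scaled coordinates (common frame) for numerical stability
    cbind((cols - d[2L] / 2) / (d[2L] / 2), (rows - d[1L] / 2) / (d[1L] / 2))
  }
  cf <- coord(idx_fit)
  X <- poly2d_basis(cf[, 1L], cf[, 2L], degree)
  qrX <- qr(X)
  if (qrX$rank < p)
    stop("rank-deficient polynomial fit: valid-pixel geometry too degenerate",
         call. = FALSE)
  ca <- coord(idx)
  Xall <- poly2d_basis(ca[, 1L], ca[, 2L], degree)
  out <- fdm$maps
  for (j in seq_len(d[3L])) {
    z <- fdm$maps[, , j][idx_fit]
    beta <- qr.coef(qrX, z)
    plane <- out[, , j]
    plane[idx] <- plane[idx] - as.numeric(Xall %*% beta)
    out[, , j] <- plane
  }
  structure(list(maps = out, schedule = fdm$schedule, valid = fdm$valid),
            class = "fdm_maps")
}
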