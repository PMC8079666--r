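#' Specification of the mid-sagittal phantom slice
#'
#' Describes the digital phantom the generator draws: a head-sized
#' elliptical "tissue" region containing an arch-shaped corpus callosum
#' whose anterior/mid/posterior thirds are labelled 1/2/3. Geometry scales
#' with the grid; the default grid is 256 x 256 at 1 mm, matching the
#' emulated protocol's field of view.
#'
#' @param grid Integer vector `c(nx, ny)` image dimensions in pixels.
#' @param segment_params List of three [three_pool_params()] giving the
#'   mean tissue parameters of the anterior/mid/posterior segments
#'   (defaults: published segment means, [segment_mean_params()]).
#' @param background_params [three_pool_params()] for non-callosal tissue.
#'   The default carries no compartmental frequency offsets (its FDM is
#'   identically zero), emulating weakly myelinated surrounding tissue so
#'   the spatial detrend sees the callosum as a localized feature on a
#'   flat frequency-difference background.
#' @param pixel_sd Named list of between-pixel standard deviations for the
#'   parameter jitter inside the callosum: `f_m`, `rho` (intra/extra split
#'   ratio), `omega_m_hz`, `omega_a_hz`, `r2s_m`, `r2s_e`. Set all to 0 for
#'   a piecewise-constant phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(256L, 256L),
                         segment_params = lapply(1:3, segment_mean_params),
                         background_params = three_pool_params(
                           f_m = 0.03, f_a = 0.30, f_e = 0.67,
                           omega_m_hz = 0, omega_a_hz = 0,
                           r2s_m = 120, r2s_a = 0, r2s_e = 20),
                         pixel_sd = list(f_m = 0.02, rho = 0.02,
                                         omega_m_hz = 2, omega_a_hz = 0.6,
                                         r2s_m = 10, r2s_e = 3)) {
  stopifnot(length(grid) == 2L, all(grid >= 32))
  stopifnot(length(segment_params) == 3L)
  structure(list(grid = as.integer(grid), segment_params = segment_params,
                 background_params = background_params, pixel_sd = pixel_sd),
            class = "phantom_spec")
}

# geometry of the callosal arch and head ellipse for a given grid
phantom_geometry <- function(grid) {
  nx <- grid[1L]; ny <- grid[2L]
  s <- min(nx, ny)
  list(cx = 0.5 * nx, cy = 0.52 * ny,
       r_out = 0.20 * s, r_in = 0.20 * s - max(4, round(0.04 * s)),
       theta = c(20, 160) * pi / 180,
       head_a = 0.46 * nx, head_b = 0.46 * ny)
}

#' Generate per-pixel tissue parameter maps and masks
#'
#' Draws the phantom: callosal pixels receive three-pool parameters
#' scattered around their segment means (Gaussian between-pixel jitter,
#' clamped to physical ranges; fractions always sum to one), background
#' tissue pixels receive the background parameter set, and air outside the
#' head ellipse is empty. Deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return List with `param_maps` (named list of `nx x ny` matrices: `f_m`,
#'   `f_a`, `f_e`, `omega_m_hz`, `omega_a_hz`, `r2s_m`, `r2s_a`, `r2s_e`),
#'   and `masks` (list `head`, `cc` logical; `labels` integer 0-3).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$grid[1L]; ny <- spec$grid[2L]
  g <- phantom_geometry(spec$grid)
  if (g$r_in <= 0) stop("callosal geometry does not fit the grid", call. = FALSE)
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  head <- ((xs - g$cx) / g$head_a)^2 + ((ys - g$cy) / g$head_b)^2 <= 1
  r <- sqrt((xs - g$cx)^2 + (ys - g$cy)^2)
  ang <- atan2(g$cy - ys, xs - g$cx)   # y-up angle: arch opens downward
  cc <- head & r >= g$r_in & r <= g$r_out & ang >= g$theta[1L] & ang <= g$theta[2L]
  if (!any(cc)) stop("callosal geometry does not fit the grid", call. = FALSE)
  # anterior/mid/posterior thirds by equal column extent (anterior = low x)
  ccx <- xs[cc]
  lev <- sort(unique(ccx)); mlev <- length(lev)
  base <- mlev %/% 3L; rem <- mlev %% 3L
  sizes <- base + c(as.integer(rem >= 1L), as.integer(rem >= 2L), 0L)
  bin <- rep.int(1:3, sizes)
  labels <- matrix(0L, nx, ny)
  labels[cc] <- bin[match(ccx, lev)]

  pm <- list()
  fields <- c("f_m", "f_a", "f_e", "omega_m_hz", "omega_a_hz",
              "r2s_m", "r2s_a", "r2s_e")
  for (f in fields) pm[[f]] <- matrix(0, nx, ny)
  bg <- spec$background_params
  bgw <- omega_hz(bg)
  tissue <- head & !cc
  pm$f_m[tissue] <- bg$f_m; pm$f_a[tissue] <- bg$f_a; pm$f_e[tissue] <- bg$f_e
  pm$omega_m_hz[tissue] <- bgw[["omega_m_hz"]]
  pm$omega_a_hz[tissue] <- bgw[["omega_a_hz"]]
  pm$r2s_m[tissue] <- bg$r2s_m; pm$r2s_a[tissue] <- bg$r2s_a
  pm$r2s_e[tissue] <- bg$r2s_e

  sd <- spec$pixel_sd
  with_seed(seed, {
    for (s in 1:3) {
      sel <- labels == s
      n <- sum(sel)
      mp <- spec$segment_params[[s]]
      mw <- omega_hz(mp)
      f_m <- pmin(0.6, pmax(0.01, mp$f_m + stats::rnorm(n, 0, sd$f_m)))
      rho0 <- mp$f_a / (mp$f_a + mp$f_e)
      rho <- pmin(0.9, pmax(0.1, rho0 + stats::rnorm(n, 0, sd$rho)))
      pm$f_m[sel] <- f_m
      pm$f_a[sel] <- rho * (1 - f_m)
      pm$f_e[sel] <- (1 - rho) * (1 - f_m)
      pm$omega_m_hz[sel] <- mw[["omega_m_hz"]] + stats::rnorm(n, 0, sd$omega_m_hz)
      pm$omega_a_hz[sel] <- mw[["omega_a_hz"]] + stats::rnorm(n, 0, sd$omega_a_hz)
      pm$r2s_m[sel] <- pmax(50, mp$r2s_m + stats::rnorm(n, 0, sd$r2s_m))
      pm$r2s_a[sel] <- mp$r2s_a
      pm$r2s_e[sel] <- pmax(1, mp$r2s_e + stats::rnorm(n, 0, sd$r2s_e))
    }
  })
  list(param_maps = pm, masks = list(head = head, cc = cc, labels = labels))
}

#' Nuisance specification for the synthetic acquisition
#'
#' Amplitudes of the instrumental effects the preprocessing chain must
#' remove: a smooth (degree <= 3 polynomial) background frequency map, a
#' TE-independent smooth RF phase map, an eddy-current phase offset that
#' alternates sign with echo parity and inverts with read polarity, smooth
#' per-channel complex coil sensitivities, and complex Gaussian noise.
#'
#' @param field_hz_amplitude Peak-to-centre amplitude of the background
#'   frequency map (Hz).
#' @param rf_phase_amplitude Amplitude of the RF phase map (rad).
#' @param eddy_phase_rad Eddy-current alternating phase offset (rad).
#' @param n_channels Number of receive channels.
#' @param noise_sigma Complex Gaussian noise SD per channel, as a fraction
#'   of the mean first-echo callosal magnitude (0.01 = pixel SNR 100).
#' @param coil_variation If `FALSE`, all channels get unit sensitivity
#'   (used by the identity nuisance).
#' @return An object of class `nuisance_spec`.
#' @export
nuisance_spec <- function(field_hz_amplitude = 15, rf_phase_amplitude = 1,
                          eddy_phase_rad = 0.3, n_channels = 4L,
                          noise_sigma = 0.01, coil_variation = TRUE) {
  stopifnot(n_channels >= 1L, noise_sigma >= 0, eddy_phase_rad >= 0,
            eddy_phase_rad < pi / 2)
  structure(list(field_hz_amplitude = field_hz_amplitude,
                 rf_phase_amplitude = rf_phase_amplitude,
                 eddy_phase_rad = eddy_phase_rad,
                 n_channels = as.integer(n_channels),
                 noise_sigma = noise_sigma,
                 coil_variation = isTRUE(coil_variation)),
            class = "nuisance_spec")
}

#' Identity nuisance specification
#'
#' No field, RF or eddy phase, a single unit-sensitivity channel, no
#' noise: the raw stack then carries the tissue signal unmodified.
#'
#' @return A [nuisance_spec()].
#' @export
no_nuisance <- function() nuisance_spec(0, 0, 0, 1L, 0, coil_variation = FALSE)

# draw smooth maps for one realisation of the nuisance
realize_nuisance <- function(nuisance, grid) {
  nx <- grid[1L]; ny <- grid[2L]
  xs <- matrix(seq_len(nx), nx, ny); ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  xn <- (xs - (nx + 1) / 2) / (nx / 2); yn <- (ys - (ny + 1) / 2) / (ny / 2)
  rand_poly <- function(amp) {
    co <- stats::rnorm(10)            # degree-3 2D monomial coefficients
    z <- matrix(poly2d_basis(as.vector(xn), as.vector(yn), 3L) %*% co, nx, ny)
    if (max(abs(z)) == 0) z else amp * z / max(abs(z))
  }
  field_hz <- rand_poly(nuisance$field_hz_amplitude)
  rf_phase <- rand_poly(nuisance$rf_phase_amplitude)
  coil <- array(0i, dim = c(nx, ny, nuisance$n_channels))
  if (!isTRUE(nuisance$coil_variation)) {
    coil[] <- 1 + 0i
    return(list(field_hz = field_hz, rf_phase = rf_phase,
                eddy_phase_rad = nuisance$eddy_phase_rad, coil = coil))
  }
  for (c in seq_len(nuisance$n_channels)) {
    phi <- stats::runif(1, 0, 2 * pi)
    cxn <- 0.7 * cos(phi); cyn <- 0.7 * sin(phi)
    mag <- 0.4 + exp(-((xn - cxn)^2 + (yn - cyn)^2) / 0.8)
    ph <- rand_poly(0.5)
    coil[, , c] <- mag * exp(1i * ph)
  }
  list(field_hz = field_hz, rf_phase = rf_phase,
       eddy_phase_rad = nuisance$eddy_phase_rad, coil = coil)
}

# Eq.-style three-pool evaluation from parameter maps at a scalar TE (s)
pixel_signal_at <- function(pm, t_s) {
  pm$f_a * exp((2i * pi * pm$omega_a_hz - pm$r2s_a) * t_s) +
    pm$f_e * exp(-pm$r2s_e * t_s) +
    pm$f_m * exp((2i * pi * pm$omega_m_hz - pm$r2s_m) * t_s)
}

#' Simulate a raw multi-channel dual-polarity acquisition
#'
#' Builds the raw echo stacks the preprocessing chain consumes. Per pixel
#' and echo the signal is the three-pool value multiplied by
#' `exp(i (rf_phase + 2 pi field_hz t + polarity (-1)^echo eddy_phase))`
#' and by the channel's complex sensitivity, plus complex Gaussian noise;
#' the two read polarities are returned as separate stacks. Every
#' generated nuisance map is stored in the output (`truth`), so the clean
#' signal can be recovered analytically when noise is off.
#'
#' @param phantom Output of [generate_phantom()].
#' @param nuisance A [nuisance_spec()].
#' @param schedule A [te_schedule()].
#' @param seed Integer seed (nuisance realisation and noise).
#' @return An object of class `slice_stack`: list with `data` (complex
#'   array `nx x ny x n_echoes x n_channels x 2`, last index = polarity
#'   +1/-1), `schedule`, `masks`, `truth` (clean complex stack plus all
#'   nuisance maps), `nuisance`.
#' @export
simulate_acquisition <- function(phantom, nuisance = nuisance_spec(),
                                 schedule = default_schedule(), seed = 0L) {
  stopifnot(inherits(nuisance, "nuisance_spec"), inherits(schedule, "te_schedule"))
  pm <- phantom$param_maps
  grid <- dim(pm$f_m)
  nx <- grid[1L]; ny <- grid[2L]; ne <- schedule$n_echoes
  head <- phantom$masks$head
  with_seed(seed, {
    nz <- realize_nuisance(nuisance, grid)
    clean <- array(0i, dim = c(nx, ny, ne))
    for (j in seq_len(ne)) {
      s <- pixel_signal_at(pm, schedule$te_ms[j] / 1000)
      s[!head] <- 0i
      clean[, , j] <- s
    }
    sigma <- nuisance$noise_sigma * mean(Mod(clean[, , 1L])[phantom$masks$cc])
    data <- array(0i, dim = c(nx, ny, ne, nuisance$n_channels, 2L))
    for (j in seq_len(ne)) {
      t_s <- schedule$te_ms[j] / 1000
      base_phase <- nz$rf_phase + 2 * pi * nz$field_hz * t_s
      for (pol in 1:2) {
        polarity <- c(1, -1)[pol]
        eddy <- polarity * (-1)^j * nz$eddy_phase_rad
        mod <- exp(1i * (base_phase + eddy))
        for (c in seq_len(nuisance$n_channels)) {
          v <- clean[, , j] * mod * nz$coil[, , c]
          if (sigma > 0)
            v <- v + complex(real = stats::rnorm(nx * ny, 0, sigma),
                             imaginary = stats::rnorm(nx * ny, 0, sigma))
          data[, , j, c, pol] <- v
        }
      }
    }
    structure(list(data = data, schedule = schedule, masks = phantom$masks,
                   truth = c(nz, list(clean = clean, sigma = sigma)),
                   nuisance = nuisance),
              class = "slice_stack")
  })
}

#' Preprocess a simulated acquisition into ROI curves
#'
#' Runs the full preprocessing chain on a [simulate_acquisition()] output:
#' per-channel polarity correction, image-based coil-sensitivity
#' estimation and combination, frequency difference mapping, spatial
#' polynomial detrending, and per-segment ROI averaging.
#'
#' @param stack A `slice_stack`.
#' @param sigma_mm Sensitivity-smoothing width passed to
#'   [estimate_sensitivities()].
#' @param detrend_degree Spatial polynomial degree for [detrend_poly2d()].
#' @param labels Optional label matrix; defaults to [split_cc_three()] of
#'   the stack's callosal mask.
#' @return List with `curves` (list of three [roi_curves()]), `combined`
#'   (`combined_stack`), `fdm` (detrended `fdm_maps`) and `labels`.
#' @export
preprocess_stack <- function(stack, sigma_mm = 8, detrend_degree = 3L,
                             labels = NULL) {
  stopifnot(inherits(stack, "slice_stack"))
  d <- dim(stack$data)
  nch <- d[4L]
  pc <- array(0i, dim = d[1:4])
  for (c in seq_len(nch))
    pc[, , , c] <- polarity_correct(stack$data[, , , c, 1L], stack$data[, , , c, 2L])
  sens <- estimate_sensitivities(pc[, , 1L, , drop = TRUE], sigma_mm = sigma_mm)
  if (length(dim(sens)) == 2L) sens <- array(sens, dim = c(d[1:2], 1L))
  if (nch == 1L && length(dim(pc)) == 3L) dim(pc) <- c(d[1:3], 1L)
  combined <- coil_combine(pc, sens, stack$schedule, masks = stack$masks)
  combined$valid <- combined$valid & stack$masks$head
  fdm <- compute_fdm(combined)
  fdm <- detrend_poly2d(fdm, degree = detrend_degree, exclude = stack$masks$cc)
  if (is.null(labels)) labels <- split_cc_three(stack$masks$cc)
  curves <- lapply(1:3, function(s) roi_average(combined, fdm, labels, s))
  list(curves = curves, combined = combined, fdm = fdm, labels = labels)
}
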