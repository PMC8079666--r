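#' Three-pool signal parameters
#'
#' Parameter set of the three-pool white-matter model: signal fractions,
#' frequency offsets and effective transverse relaxation rates of the
#' myelin (`m`), intra-axonal (`a`) and extra-axonal (`e`) water pools.
#' The extra-axonal pool is the frequency reference (offset 0 by
#' convention). Offsets are accepted and reported in Hz (`omega/2*pi`) and
#' stored internally in rad/s; rates are in 1/s; TE is handled in ms at the
#' interface and converted to seconds inside the exponentials.
#'
#' Fractions are signal fractions and are not forced to sum to one here
#' (the fit does not impose a sum constraint); the synthetic generator
#' always produces fractions summing to one.
#'
#' @param f_m,f_a,f_e Signal fractions in `[0, 1]`.
#' @param omega_m_hz,omega_a_hz Frequency offsets of the myelin and
#'   intra-axonal pools relative to the extra-axonal pool, in Hz.
#' @param r2s_m,r2s_a,r2s_e Transverse relaxation rates R2* in 1/s (>= 0).
#'
#' @return An object of class `three_pool_params`.
#'
#' @examples
#' p <- three_pool_params(f_m = 0.16, f_a = 0.42, f_e = 0.42,
#'                        omega_m_hz = 27.3, omega_a_hz = -8.5,
#'                        r2s_m = 150, r2s_a = 0, r2s_e = 25)
#' delta_omega_hz(p)  # 35.8 Hz
#' @export
three_pool_params <- function(f_m, f_a, f_e, omega_m_hz, omega_a_hz,
                              r2s_m, r2s_a = 0, r2s_e) {
  check_fraction(f_m, "f_m"); check_fraction(f_a, "f_a"); check_fraction(f_e, "f_e")
  for (nm in c("omega_m_hz", "omega_a_hz")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  check_scalar_nonneg(r2s_m, "r2s_m")
  check_scalar_nonneg(r2s_a, "r2s_a")
  check_scalar_nonneg(r2s_e, "r2s_e")
  new_three_pool_params(f_m, f_a, f_e, omega_m_hz, omega_a_hz, r2s_m, r2s_a, r2s_e)
}

# fast path without validation, used inside optimisation loops
new_three_pool_params <- function(f_m, f_a, f_e, omega_m_hz, omega_a_hz,
                                  r2s_m, r2s_a, r2s_e) {
  structure(
    list(f_m = f_m, f_a = f_a, f_e = f_e,
         omega_m = 2 * pi * omega_m_hz, omega_a = 2 * pi * omega_a_hz,
         r2s_m = r2s_m, r2s_a = r2s_a, r2s_e = r2s_e),
    class = "three_pool_params"
  )
}

#' Frequency offsets in Hz
#'
#' @param params A [three_pool_params()] object.
#' @return Named vector `c(omega_m_hz, omega_a_hz)`.
#' @export
omega_hz <- function(params) {
  stopifnot(inherits(params, "three_pool_params"))
  c(omega_m_hz = params$omega_m / (2 * pi), omega_a_hz = params$omega_a / (2 * pi))
}

#' Myelin-axonal frequency-offset difference in Hz
#'
#' The derived quantity `delta_omega / 2*pi = omega_m/2*pi - omega_a/2*pi`,
#' sensitive to myelin susceptibility and the g-ratio.
#'
#' @param params A [three_pool_params()] object.
#' @return `delta omega / 2 pi` in Hz.
#' @export
delta_omega_hz <- function(params) {
  stopifnot(inherits(params, "three_pool_params"))
  (params$omega_m - params$omega_a) / (2 * pi)
}

#' @export
print.three_pool_params <- function(x, ...) {
  w <- omega_hz(x)
  cat(sprintf(paste0("<three_pool_params> f_m=%.4g f_a=%.4g f_e=%.4g | ",
                     "omega_m/2pi=%.4g Hz omega_a/2pi=%.4g Hz | ",
                     "R2*_m=%.4g R2*_a=%.4g R2*_e=%.4g 1/s\n"),
              x$f_m, x$f_a, x$f_e, w[["omega_m_hz"]], w[["omega_a_hz"]],
              x$r2s_m, x$r2s_a, x$r2s_e))
  invisible(x)
}

#' Serialize / deserialize three-pool parameters as flat JSON
#'
#' The record uses keys `f_m, f_a, f_e, omega_m_hz, omega_a_hz, r2s_m,
#' r2s_a, r2s_e` (offsets in Hz).
#'
#' @param params A [three_pool_params()] object.
#' @param json A JSON string as produced by `params_to_json()`.
#' @return `params_to_json()` returns a JSON string; `params_from_json()`
#'   returns a [three_pool_params()] object.
#' @export
params_to_json <- function(params) {
  stopifnot(inherits(params, "three_pool_params"))
  w <- omega_hz(params)
  jsonlite::toJSON(
    list(f_m = params$f_m, f_a = params$f_a, f_e = params$f_e,
         omega_m_hz = unname(w[["omega_m_hz"]]), omega_a_hz = unname(w[["omega_a_hz"]]),
         r2s_m = params$r2s_m, r2s_a = params$r2s_a, r2s_e = params$r2s_e),
    auto_unbox = TRUE, digits = NA)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  three_pool_params(f_m = x$f_m, f_a = x$f_a, f_e = x$f_e,
                    omega_m_hz = x$omega_m_hz, omega_a_hz = x$omega_a_hz,
                    r2s_m = x$r2s_m, r2s_a = x$r2s_a, r2s_e = x$r2s_e)
}

#' Segment mean parameter sets used as generator defaults
#'
#' Published test-retest mean values per callosal segment (anterior = 1,
#' mid = 2, posterior = 3): myelin fraction and pool frequency offsets per
#' segment, fractions split so they sum to one, relaxation rates at the
#' standard literature initial values (R2*_m 150/s, R2*_a 0, R2*_e 25/s).
#'
#' @param segment Callosal segment index (1 anterior, 2 mid, 3 posterior).
#' @return A [three_pool_params()] object.
#' @export
segment_mean_params <- function(segment = 3L) {
  stopifnot(segment %in% 1:3)
  f_m <- c(0.15, 0.15, 0.16)[segment]
  omega_a <- c(-8.5, -7.9, -8.5)[segment]
  omega_m <- c(31.4, 27.1, 27.3)[segment]
  three_pool_params(f_m = f_m, f_a = (1 - f_m) / 2, f_e = (1 - f_m) / 2,
                    omega_m_hz = omega_m, omega_a_hz = omega_a,
                    r2s_m = 150, r2s_a = 0, r2s_e = 25)
}
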