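#' Forward three-pool complex mGRE signal
#'
#' Evaluates the three-pool superposition at every echo of a schedule:
#' \deqn{S(t) = f_a e^{(i\omega_a - R2^*_a) t} + f_e e^{-R2^*_e t} +
#'       f_m e^{(i\omega_m - R2^*_m) t}}
#' with `t` the echo time in seconds. The extra-axonal pool carries no
#' frequency offset (it is the frequency reference).
#'
#' @param params A [three_pool_params()] object.
#' @param schedule A [te_schedule()].
#' @return An object of class `complex_signal_curve`: list with `schedule`
#'   and a complex vector `values`, one value per echo.
#' @examples
#' s <- synthesize_three_pool(segment_mean_params(3), default_schedule())
#' Mod(s$values[1])
#' @export
synthesize_three_pool <- function(params, schedule) {
  stopifnot(inherits(params, "three_pool_params"), inherits(schedule, "te_schedule"))
  t_s <- schedule$te_ms / 1000
  v <- params$f_a * exp((1i * params$omega_a - params$r2s_a) * t_s) +
       params$f_e * exp(-params$r2s_e * t_s) +
       params$f_m * exp((1i * params$omega_m - params$r2s_m) * t_s)
  structure(list(schedule = schedule, values = v), class = "complex_signal_curve")
}

#' ROI-style magnitude and frequency-difference curves
#'
#' Container for the two curves the three-pool fit consumes: the
#' first-echo-normalised magnitude and the frequency-difference series in
#' Hz, both sampled on one TE schedule.
#'
#' @param schedule A [te_schedule()].
#' @param magnitude Non-negative magnitude values, one per echo;
#'   normalised so the first echo equals 1.
#' @param fdm_hz Frequency-difference values in Hz, one per echo.
#' @param segment Optional segment label carried through for bookkeeping.
#' @return An object of class `roi_curves`.
#' @export
roi_curves <- function(schedule, magnitude, fdm_hz, segment = NA_integer_) {
  stopifnot(inherits(schedule, "te_schedule"))
  n <- schedule$n_echoes
  if (length(magnitude) != n || length(fdm_hz) != n)
    stop("curve lengths must equal the number of echoes", call. = FALSE)
  if (!all(is.finite(magnitude)) || !all(is.finite(fdm_hz)))
    stop("curves must be finite", call. = FALSE)
  if (any(magnitude < 0))
    stop("magnitude must be non-negative", call. = FALSE)
  if (abs(magnitude[1] - 1) > 1e-8)
    stop("magnitude must be normalised to the first echo (magnitude[1] == 1)",
         call. = FALSE)
  structure(list(schedule = schedule, magnitude = as.numeric(magnitude),
                 fdm_hz = as.numeric(fdm_hz), segment = segment),
            class = "roi_curves")
}

#' @export
as.data.frame.roi_curves <- function(x, ...) {
  data.frame(echo_index = seq_len(x$schedule$n_echoes),
             te_ms = x$schedule$te_ms,
             magnitude_norm = x$magnitude,
             fdm_hz = x$fdm_hz,
             segment = x$segment)
}

#' Model-predicted ROI curves
#'
#' Computes the noiseless magnitude and frequency-difference curves the
#' three-pool model predicts for one parameter set. The magnitude is
#' `|S(t)|` normalised to the first echo; the FDM series is obtained by
#' applying the package's frequency-difference operator
#' ([fdm_from_complex()]) to the model curve, i.e. the model and data paths
#' share a single FDM implementation.
#'
#' @inheritParams synthesize_three_pool
#' @return An [roi_curves()] object.
#' @export
model_roi_curves <- function(params, schedule) {
  s <- synthesize_three_pool(params, schedule)$values
  roi_curves(schedule,
             magnitude = Mod(s) / Mod(s)[1],
             fdm_hz = fdm_from_complex(s, schedule))
}
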