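#' Echo-time schedule for a multi-echo gradient-echo acquisition
#'
#' Builds the arithmetic TE grid on which every signal curve in the package
#' is sampled: `TE_n = te1_ms + (n - 1) * delta_te_ms`.
#'
#' @param te1_ms First echo time in milliseconds (> 0).
#' @param delta_te_ms Echo spacing in milliseconds (> 0).
#' @param n_echoes Number of echoes (>= 3; frequency-difference mapping
#'   needs at least three echoes).
#'
#' @return An object of class `te_schedule`: a list with elements `te1_ms`,
#'   `delta_te_ms`, `n_echoes` and the derived vector `te_ms`.
#'
#' @examples
#' sched <- te_schedule(1.62, 1.23, 25)
#' max(sched$te_ms)  # 31.14 ms
#' @export
te_schedule <- function(te1_ms, delta_te_ms, n_echoes) {
  check_scalar_pos(te1_ms, "te1_ms")
  check_scalar_pos(delta_te_ms, "delta_te_ms")
  if (!is.numeric(n_echoes) || length(n_echoes) != 1L || !is.finite(n_echoes) ||
      n_echoes != round(n_echoes) || n_echoes < 3)
    stop("`n_echoes` must be a single integer >= 3", call. = FALSE)
  n_echoes <- as.integer(n_echoes)
  structure(
    list(te1_ms = te1_ms, delta_te_ms = delta_te_ms, n_echoes = n_echoes,
         te_ms = te1_ms + (seq_len(n_echoes) - 1) * delta_te_ms),
    class = "te_schedule"
  )
}

#' Default 25-echo bipolar protocol schedule
#'
#' TE1/dTE = 1.62/1.23 ms with 25 echoes (maximum TE 31.14 ms), the
#' single-slice 7 T protocol emulated by the synthetic generator.
#'
#' @return A [te_schedule()].
#' @export
default_schedule <- function() te_schedule(1.62, 1.23, 25L)

#' @export
print.te_schedule <- function(x, ...) {
  cat(sprintf("<te_schedule> %d echoes, TE1 = %g ms, dTE = %g ms, max TE = %g ms\n",
              x$n_echoes, x$te1_ms, x$delta_te_ms, max(x$te_ms)))
  invisible(x)
}

#' Total scan duration of a repeated single-slice acquisition
#'
#' Duration is `n_phase_encodes * tr_ms * n_repeats`, returned in seconds.
#' For the emulated protocol (256 phase encodes, TR 100 ms, 20 repeats)
#' this is 512 s, i.e. 8 min 32 s.
#'
#' @param n_phase_encodes Number of phase-encoding steps (positive integer).
#' @param tr_ms Repetition time in milliseconds.
#' @param n_repeats Number of repeats of the full acquisition.
#'
#' @return Scan duration in seconds.
#' @export
scan_duration_s <- function(n_phase_encodes, tr_ms, n_repeats) {
  for (nm in c("n_phase_encodes", "n_repeats")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v != round(v) || v < 1)
      stop("`", nm, "` must be a single positive integer", call. = FALSE)
  }
  check_scalar_pos(tr_ms, "tr_ms")
  n_phase_encodes * tr_ms * n_repeats / 1000
}
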