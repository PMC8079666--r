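#' Combined complex echo stack
#'
#' Light container for a single-channel, polarity-corrected per-echo
#' complex image series plus its schedule and masks.
#'
#' @param data Complex array `nx x ny x n_echoes`.
#' @param schedule A [te_schedule()].
#' @param valid Logical `nx x ny` validity mask (default all `TRUE`).
#' @param masks Optional list of masks (e.g. `cc`, `labels`).
#' @return An object of class `combined_stack`.
#' @export
combined_stack <- function(data, schedule, valid = NULL, masks = list()) {
  stopifnot(is.complex(data) || is.numeric(data), length(dim(data)) == 3L,
            inherits(schedule, "te_schedule"))
  d <- dim(data)
  if (d[3L] != schedule$n_echoes)
    stop("echo dimension does not match the schedule", call. = FALSE)
  if (is.null(valid)) valid <- matrix(TRUE, d[1L], d[2L])
  stopifnot(identical(dim(valid), d[1:2]))
  structure(list(data = data, schedule = schedule, valid = valid, masks = masks),
            class = "combined_stack")
}

#' Remove read-polarity phase shifts by complex multiplication
#'
#' Combines the two read-gradient-polarity groups: per pixel and echo the
#' output magnitude is `sqrt(|S+| |S-|)` and the output phase is
#' `angle(S+ S-)/2`, so any phase term with opposite sign in the two
#' groups (the echo-parity alternating eddy-current phase) cancels
#' exactly. The half-angle branch ambiguity (+/- pi) is resolved by taking
#' the branch closer, circularly, to the phase of `S+`.
#'
#' @param stack_pos,stack_neg Complex arrays of identical shape (any
#'   dimensionality; typically `nx x ny x n_echoes` or with a trailing
#'   channel dimension), or `combined_stack`-like lists with `$data`.
#' @param schedule Optional [te_schedule()] carried into the output when
#'   array input is given.
#' @return If the inputs carry a schedule, a `combined_stack`; otherwise a
#'   complex array of the same shape.
#' @export
polarity_correct <- function(stack_pos, stack_neg, schedule = NULL) {
  meta <- NULL
  if (inherits(stack_pos, "combined_stack")) {
    if (!inherits(stack_neg, "combined_stack") ||
        !identical(stack_pos$schedule$te_ms, stack_neg$schedule$te_ms))
      stop("polarity groups must share one schedule", call. = FALSE)
    meta <- stack_pos
    schedule <- stack_pos$schedule
    stack_pos <- stack_pos$data; stack_neg <- stack_neg$data
  }
  if (!identical(dim(stack_pos), dim(stack_neg)))
    stop("polarity groups must share one grid", call. = FALSE)
  prod <- stack_pos * stack_neg
  half <- Arg(prod) / 2
  # branch choice: half or half + pi, whichever is circularly closer to Arg(S+)
  flip <- abs(Arg(exp(1i * (Arg(stack_pos) - half)))) > pi / 2
  half[flip] <- half[flip] + pi
  out <- sqrt(Mod(stack_pos) * Mod(stack_neg)) * exp(1i * half)
  if (!is.null(meta))
    return(combined_stack(out, schedule, valid = meta$valid, masks = meta$masks))
  if (!is.null(schedule) && length(dim(out)) == 3L)
    return(combined_stack(out, schedule))
  out
}

# separable Gaussian smoothing of a matrix (complex allowed); kernel
# truncated at 3 sigma and renormalised at the edges
smooth_gaussian2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  smat <- function(n) {
    i <- seq_len(n)
    W <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
    W[abs(outer(i, i, "-")) > ceiling(3 * sigma)] <- 0
    W / rowSums(W)
  }
  Sr <- smat(nrow(mat)); Sc <- smat(ncol(mat))
  if (is.complex(mat)) {
    (Sr %*% Re(mat) %*% t(Sc)) + 1i * (Sr %*% Im(mat) %*% t(Sc))
  } else Sr %*% mat %*% t(Sc)
}

#' Image-based coil sensitivity estimation
#'
#' Estimates smooth per-channel complex sensitivity maps from the
#' first-echo image of each channel: each channel image is smoothed with a
#' 2D Gaussian (default width 8 mm at 1 mm pixels) and the set is
#' normalised so the root-sum-of-squares magnitude is 1 everywhere it is
#' positive.
#'
#' @param first_echo_per_channel Complex array `nx x ny x n_channels` (or a
#'   list of `nx x ny` complex matrices).
#' @param sigma_mm Gaussian smoothing width in mm (pixels at 1 mm).
#' @return Complex array `nx x ny x n_channels` of unit-RSS sensitivities.
#' @export
estimate_sensitivities <- function(first_echo_per_channel, sigma_mm = 8) {
  x <- first_echo_per_channel
  if (is.list(x)) x <- array(unlist(x), dim = c(dim(x[[1]]), length(x)))
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  nch <- dim(x)[3L]
  sm <- array(0i, dim = dim(x))
  for (c in seq_len(nch)) {
    ch <- x[, , c]
    if (all(Mod(ch) == 0)) stop("channel ", c, " is identically zero", call. = FALSE)
    sm[, , c] <- smooth_gaussian2d(ch, sigma_mm)
  }
  rss <- sqrt(apply(Mod(sm)^2, c(1, 2), sum))
  rss[rss == 0] <- 1
  for (c in seq_len(nch)) sm[, , c] <- sm[, , c] / rss
  sm
}

#' SENSE-style coil combination
#'
#' Combines per-channel echo stacks with complex sensitivity maps:
#' `combined = sum_c conj(s_c) S_c / sum_c |s_c|^2`. With the true
#' sensitivities this returns the object signal exactly; pixels with zero
#' denominator are flagged invalid.
#'
#' @param stacks_per_channel Complex array `nx x ny x n_echoes x n_channels`.
#' @param sensitivities Complex array `nx x ny x n_channels`.
#' @param schedule A [te_schedule()].
#' @param masks Optional mask list carried into the output.
#' @return A `combined_stack`; its `valid` mask is `FALSE` where the
#'   sensitivity denominator vanishes.
#' @export
coil_combine <- function(stacks_per_channel, sensitivities, schedule,
                         masks = list()) {
  d <- dim(stacks_per_channel)
  stopifnot(length(d) == 4L, length(dim(sensitivities)) == 3L)
  if (!identical(d[c(1, 2, 4)], dim(sensitivities)[c(1, 2, 3)]))
    stop("channels and sensitivities do not align", call. = FALSE)
  den <- apply(Mod(sensitivities)^2, c(1, 2), sum)
  num <- array(0i, dim = d[1:3])
  for (c in seq_len(d[4L])) {
    s <- Conj(sensitivities[, , c])
    for (j in seq_len(d[3L]))
      num[, , j] <- num[, , j] + s * stacks_per_channel[, , j, c]
  }
  valid <- den > 0
  den[!valid] <- 1
  for (j in seq_len(d[3L])) num[, , j] <- num[, , j] / den
  combined_stack(num, schedule, valid = valid, masks = masks)
}

#' Split a corpus-callosum mask into three equal segments
#'
#' Partitions a 2D mask into anterior (1), mid (2) and posterior (3)
#' thirds of equal extent along the structure's anterior-posterior axis.
#' The axis is the principal axis of the mask's pixel coordinates; pixels
#' are grouped by their projected position (rounded to the pixel grid) and
#' the ordered positions are split into three contiguous runs of equal
#' length, any remainder going to the anterior bin. Anterior is the end of
#' the axis with the smaller image column index.
#'
#' @param cc_mask Logical (or 0/1) matrix; `TRUE` marks callosal pixels.
#' @return Integer matrix of the same size with labels 0 (background),
#'   1 (anterior), 2 (mid), 3 (posterior).
#' @export
split_cc_three <- function(cc_mask) {
  m <- cc_mask != 0
  idx <- which(m)
  if (length(idx) == 0L) stop("empty corpus-callosum mask", call. = FALSE)
  nr <- nrow(m)
  ys <- (idx - 1L) %% nr + 1L        # row
  xs <- (idx - 1L) %/% nr + 1L       # column = anterior-posterior direction
  co <- cbind(xs, ys)
  v <- eigen(stats::cov(cbind(xs - mean(xs), ys - mean(ys))), symmetric = TRUE)$vectors[, 1L]
  if (v[1L] < 0 || (v[1L] == 0 && v[2L] < 0)) v <- -v
  u <- co %*% v
  pos <- round(u - min(u))           # integer positions along the axis
  lev <- sort(unique(pos))
  mlev <- length(lev)
  base <- mlev %/% 3L; rem <- mlev %% 3L
  sizes <- base + c(as.integer(rem >= 1L), as.integer(rem >= 2L), 0L)
  bin <- rep.int(1:3, sizes)
  labels_by_lev <- bin[match(pos, lev)]
  out <- matrix(0L, nrow(m), ncol(m))
  out[idx] <- labels_by_lev
  out
}

#' Average magnitude and FDM curves over one callosal segment
#'
#' Per echo, the magnitude curve is the mean of `|S|` over the segment's
#' pixels, normalised to the first echo; the FDM curve is the mean of the
#' frequency-difference map over the same pixels.
#'
#' @param combined A `combined_stack`.
#' @param fdm An `fdm_maps` object on the same grid/schedule.
#' @param labels Integer label matrix (1/2/3) from [split_cc_three()].
#' @param segment_id Which segment to average (1, 2 or 3).
#' @return An [roi_curves()] object with the segment recorded.
#' @export
roi_average <- function(combined, fdm, labels, segment_id) {
  stopifnot(inherits(combined, "combined_stack"), inherits(fdm, "fdm_maps"))
  idx <- which(labels == segment_id & combined$valid & fdm$valid)
  if (length(idx) == 0L)
    stop("segment ", segment_id, " is empty", call. = FALSE)
  ne <- combined$schedule$n_echoes
  npix <- prod(dim(combined$data)[1:2])
  magm <- matrix(Mod(combined$data), npix, ne)
  fdmm <- matrix(fdm$maps, npix, ne)
  mag <- colMeans(magm[idx, , drop = FALSE])
  f <- colMeans(fdmm[idx, , drop = FALSE])
  roi_curves(combined$schedule, magnitude = mag / mag[1], fdm_hz = f,
             segment = as.integer(segment_id))
}
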