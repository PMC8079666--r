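#' Write a raw slice stack as NIfTI magnitude/phase pairs
#'
#' One file per echo x channel x polarity, magnitude and phase separately
#' (phase in radians in `[-pi, pi]`); masks are written as integer NIfTI.
#'
#' @param stack A `slice_stack` from [simulate_acquisition()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_slice_stack <- function(stack, dir, prefix = "mgre") {
  stopifnot(inherits(stack, "slice_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$data)
  files <- character(0)
  for (j in seq_len(d[3L])) for (c in seq_len(d[4L])) for (pol in 1:2) {
    base <- sprintf("%s_e%02d_c%02d_p%d", prefix, j, c, pol)
    v <- stack$data[, , j, c, pol]
    fm <- file.path(dir, paste0(base, "_mag.nii.gz"))
    fp <- file.path(dir, paste0(base, "_phase.nii.gz"))
    RNifti::writeNifti(Mod(v), fm)
    RNifti::writeNifti(Arg(v), fp)
    files <- c(files, fm, fp)
  }
  fmask <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  RNifti::writeNifti(stack$masks$labels + 0L, fmask)
  invisible(c(files, fmask))
}

#' Read a slice stack written by [write_slice_stack()]
#'
#' @param dir Directory containing the NIfTI files.
#' @param prefix Filename prefix used when writing.
#' @param schedule The acquisition [te_schedule()].
#' @param n_channels Number of receive channels.
#' @return A `slice_stack`-like list with `data`, `schedule`, `masks`
#'   (labels only; `cc` derived as labels > 0).
#' @export
read_slice_stack <- function(dir, prefix, schedule, n_channels) {
  ne <- schedule$n_echoes
  first <- RNifti::readNifti(file.path(dir, sprintf("%s_e01_c01_p1_mag.nii.gz", prefix)))
  grid <- dim(first)[1:2]
  data <- array(0i, dim = c(grid, ne, n_channels, 2L))
  for (j in seq_len(ne)) for (c in seq_len(n_channels)) for (pol in 1:2) {
    base <- sprintf("%s_e%02d_c%02d_p%d", prefix, j, c, pol)
    m <- as.array(RNifti::readNifti(file.path(dir, paste0(base, "_mag.nii.gz"))))
    p <- as.array(RNifti::readNifti(file.path(dir, paste0(base, "_phase.nii.gz"))))
    data[, , j, c, pol] <- m * exp(1i * p)
  }
  labels <- as.array(RNifti::readNifti(file.path(dir, paste0(prefix, "_labels.nii.gz"))))
  labels <- matrix(as.integer(round(labels)), grid[1L], grid[2L])
  structure(list(data = data, schedule = schedule,
                 masks = list(labels = labels, cc = labels > 0L,
                              head = matrix(TRUE, grid[1L], grid[2L]))),
            class = "slice_stack")
}

#' Write frequency difference maps as per-echo NIfTI (units Hz)
#'
#' @param fdm An `fdm_maps` object.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return Invisibly, the files written.
#' @export
write_fdm_maps <- function(fdm, dir, prefix = "fdm") {
  stopifnot(inherits(fdm, "fdm_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (j in seq_len(dim(fdm$maps)[3L])) {
    f <- file.path(dir, sprintf("%s_e%02d_hz.nii.gz", prefix, j))
    m <- fdm$maps[, , j]
    m[!fdm$valid] <- 0
    RNifti::writeNifti(m, f)
    files <- c(files, f)
  }
  fv <- file.path(dir, paste0(prefix, "_valid.nii.gz"))
  RNifti::writeNifti(fdm$valid + 0L, fv)
  invisible(c(files, fv))
}

#' Write ROI curves as CSV
#'
#' Columns: `echo_index`, `te_ms`, `magnitude_norm`, `fdm_hz`, `segment`.
#'
#' @param curves A single [roi_curves()] object or a list of them.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_roi_curves_csv <- function(curves, path) {
  if (inherits(curves, "roi_curves")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read ROI curves from CSV
#'
#' @param path CSV written by [write_roi_curves_csv()].
#' @param schedule Optional [te_schedule()]; reconstructed from the
#'   `te_ms` column when omitted.
#' @return List of [roi_curves()], one per segment present in the file.
#' @export
read_roi_curves_csv <- function(path, schedule = NULL) {
  df <- utils::read.csv(path)
  lapply(split(df, df$segment), function(d) {
    d <- d[order(d$echo_index), ]
    sch <- schedule
    if (is.null(sch)) {
      dte <- diff(d$te_ms)
      sch <- te_schedule(d$te_ms[1], mean(dte), nrow(d))
    }
    roi_curves(sch, d$magnitude_norm, d$fdm_hz, segment = d$segment[1])
  })
}
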