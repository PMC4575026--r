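#' Write a dual-echo volume and label map as NIfTI-1
#'
#' One file per echo plus the label map, with voxel size recorded in the
#' header, and a JSON sidecar carrying the echo times.
#'
#' @param vol A [dual_echo_volume()].
#' @param labelmap Optional [label_map()] on the same grid.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_dual_echo_nifti <- function(vol, labelmap = NULL, dir = ".",
                                  prefix = "phantom") {
  stopifnot(inherits(vol, "dual_echo_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (echo in 1:2) {
    img <- RNifti::asNifti(if (echo == 1) vol$si_te1 else vol$si_te2)
    RNifti::pixdim(img) <- vol$voxel_size
    p <- file.path(dir, sprintf("%s_echo%d.nii", prefix, echo))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  if (!is.null(labelmap)) {
    p <- file.path(dir, sprintf("%s_labels.nii", prefix))
    lab <- RNifti::asNifti(labelmap$labels)
    RNifti::pixdim(lab) <- labelmap$voxel_size
    RNifti::writeNifti(lab, p)
    paths <- c(paths, p)
  }
  side <- file.path(dir, sprintf("%s_acquisition.json", prefix))
  jsonlite::write_json(
    list(te_ms = c(vol$te1, vol$te2), voxel_size_mm = vol$voxel_size,
         slice_axis = vol$slice_axis),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}

#' Read a dual-echo volume from two NIfTI files
#'
#' @param echo1,echo2 Paths to the per-echo magnitude NIfTI volumes.
#' @param te1,te2 Echo times in ms.
#' @param slice_axis Slice axis index (default 3).
#' @return A [dual_echo_volume()]; voxel size is taken from the header of
#'   the first echo.
#' @export
read_dual_echo_nifti <- function(echo1, echo2, te1 = 14, te2 = 40,
                                 slice_axis = 3L) {
  i1 <- RNifti::readNifti(echo1)
  i2 <- RNifti::readNifti(echo2)
  vx <- RNifti::pixdim(i1)[1:3]
  dual_echo_volume(array(as.numeric(i1), dim(i1)),
                   array(as.numeric(i2), dim(i2)),
                   te1, te2, voxel_size = vx, slice_axis = slice_axis)
}

#' Read an integer label map from NIfTI
#'
#' @param path NIfTI file of integer labels.
#' @param code_table Optional code table (label, name, parent).
#' @param slice_axis Slice axis index.
#' @return A [label_map()] with voxel size from the header.
#' @export
read_labelmap_nifti <- function(path, code_table = NULL, slice_axis = 3L) {
  img <- RNifti::readNifti(path)
  label_map(array(as.integer(round(img)), dim(img)),
            voxel_size = RNifti::pixdim(img)[1:3],
            slice_axis = slice_axis, code_table = code_table)
}

#' Write a T2 map (values + validity mask) as NIfTI
#' @param map A [t2_map()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the two paths written.
#' @export
write_t2_map_nifti <- function(map, dir = ".", prefix = "t2map") {
  stopifnot(inherits(map, "t2_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t2 <- map$t2
  t2[!map$valid] <- 0  # NIfTI has no NA; invalid pixels also in the mask
  p1 <- file.path(dir, paste0(prefix, ".nii"))
  p2 <- file.path(dir, paste0(prefix, "_valid.nii"))
  t2img <- RNifti::asNifti(t2)
  RNifti::pixdim(t2img) <- map$voxel_size
  RNifti::writeNifti(t2img, p1)
  vimg <- RNifti::asNifti(array(as.integer(map$valid), dim(map$valid)))
  RNifti::pixdim(vimg) <- map$voxel_size
  RNifti::writeNifti(vimg, p2)
  invisible(c(p1, p2))
}

#' Write / read a decay curve as CSV
#'
#' Columns `te_ms`, `real`, `imag`, `magnitude`; real-valued curves are
#' written with `imag = 0`.
#'
#' @param curve A [decay_curve()].
#' @param path CSV path.
#' @return `write_decay_csv`: invisibly, the path. `read_decay_csv`: a
#'   [decay_curve()] (complex when any `imag` is non-zero).
#' @export
write_decay_csv <- function(curve, path) {
  stopifnot(inherits(curve, "decay_curve"))
  df <- data.frame(te_ms = curve$te, real = Re(curve$signal),
                   imag = Im(curve$signal), magnitude = curve$magnitude)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("te_ms", "magnitude") %in% names(df)))
    stop("decay CSV needs te_ms and magnitude (or real/imag) columns")
  sig <- if (all(c("real", "imag") %in% names(df))) {
    if (any(df$imag != 0)) complex(real = df$real, imaginary = df$imag)
    else df$real
  } else df$magnitude
  decay_curve(df$te_ms, sig)
}

#' Write / read a cohort table as CSV
#' @param table Long-format cohort data frame.
#' @param path CSV path.
#' @return `write_cohort_csv`: invisibly, the path. `read_cohort_csv`:
#'   the data frame.
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path)
  need <- c("animal", "group", "measurement", "value")
  if (!all(need %in% names(df)))
    stop("cohort CSV needs columns ", paste(need, collapse = ", "))
  df
}
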