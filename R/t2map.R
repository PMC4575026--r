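#' Pixel-wise two-echo T2 estimate
#'
#' For a spin echo at long TR the signal decays as
#' \eqn{S(TE) = S_0 \exp(-TE/T_2)}, so two echoes determine T2 exactly:
#' \deqn{T_2 = (TE_2 - TE_1) / \ln(SI_1 / SI_2).}
#' At the study's echo times of 14 and 40 ms the numerator is the printed
#' 26 ms. A pixel is estimable only when `si1 > si2 > 0`; anything else
#' (equal echoes, zero or noise-floor signal) is returned as `NA` rather
#' than raising an error, so that whole images can be mapped in one call.
#'
#' @param si1,si2 Pixel intensities (scalars or arrays of equal shape) at
#'   the first and second echo. Must be non-negative.
#' @param te1,te2 Echo times in ms with `te2 > te1 > 0`.
#' @return T2 in ms, same shape as the input, `NA` where inestimable.
#' @examples
#' two_echo_t2(exp(1), 1, 14, 40)    # exactly 26 ms
#' two_echo_t2(200, 100, 14, 40)     # 26 / log(2)
#' @export
two_echo_t2 <- function(si1, si2, te1 = 14, te2 = 40) {
  if (!(te2 > te1 && te1 > 0)) stop("need te2 > te1 > 0")
  if (any(si1 < 0, na.rm = TRUE) || any(si2 < 0, na.rm = TRUE))
    stop("input error: negative pixel intensities")
  ok <- is.finite(si1) & is.finite(si2) & si2 > 0 & si1 > si2
  out <- si1 + NA_real_  # preserve shape
  out[ok] <- (te2 - te1) / log(si1[ok] / si2[ok])
  out
}

#' T2 map container
#'
#' Per-pixel T2 in ms with a validity mask; invalid pixels carry no value.
#'
#' @param t2 Numeric array of T2 values (NA where invalid).
#' @param valid Logical array, same shape.
#' @param te_delta Echo-time difference in ms.
#' @param voxel_size Voxel size in mm per axis.
#' @param slice_axis Slice axis index.
#' @return An object of class `t2_map`.
#' @export
t2_map <- function(t2, valid, te_delta, voxel_size = c(1, 1, 1),
                   slice_axis = 3L) {
  stopifnot(identical(dim(t2), dim(valid)), is.logical(valid))
  if (any(valid & (!is.finite(t2) | t2 <= 0), na.rm = TRUE))
    stop("valid pixels must carry finite positive T2")
  structure(
    list(t2 = t2, valid = valid, te_delta = te_delta,
         voxel_size = as.numeric(voxel_size),
         slice_axis = as.integer(slice_axis)),
    class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  cat(sprintf("<t2_map> %s voxels, %d valid (%.1f%%)\n",
              paste(dim(x$t2), collapse = " x "), sum(x$valid),
              100 * mean(x$valid)))
  if (any(x$valid))
    cat(sprintf("  T2 range %.2f-%.2f ms\n",
                min(x$t2[x$valid]), max(x$t2[x$valid])))
  invisible(x)
}

#' Compute a T2 map over selected labels
#'
#' Applies [two_echo_t2()] to every pixel whose label is in `labels`;
#' all other pixels are invalid. Pixels where the estimator is undefined
#' (si1 <= si2 or zero signal) are also marked invalid and excluded from
#' downstream ROI statistics.
#'
#' @param vol A [dual_echo_volume()].
#' @param mask A [label_map()] on the same grid.
#' @param labels Integer label codes defining the ROI (e.g. `2` for the
#'   posterior compartment, `c(1, 2)` for both, `c(2, 3)` to include
#'   lesion pixels carved from the posterior compartment).
#' @return A [t2_map()].
#' @export
make_t2_map <- function(vol, mask, labels) {
  stopifnot(inherits(vol, "dual_echo_volume"), inherits(mask, "label_map"))
  if (!identical(dim(vol$si_te1), dim(mask$labels)))
    stop("grid mismatch between volume and label map")
  sel <- array(mask$labels %in% as.integer(labels), dim(mask$labels))
  t2 <- array(NA_real_, dim(mask$labels))
  if (any(sel))
    t2[sel] <- two_echo_t2(vol$si_te1[sel], vol$si_te2[sel],
                           vol$te1, vol$te2)
  valid <- sel & !is.na(t2)
  t2[!valid] <- NA_real_
  t2_map(t2, valid, te_delta = vol$te2 - vol$te1,
         voxel_size = vol$voxel_size, slice_axis = vol$slice_axis)
}

#' Select the middle k slices of a stack
#'
#' Muscle T2 is summarized over the middle slices of the acquisition
#' (6 to 8 of them in the emulated protocol; the default elsewhere in the
#' package is 7). The window of k slices is centred on the stack; when
#' parity forces a choice the window shifts toward the lower index.
#'
#' @param n_slices Total number of slices.
#' @param k Number of middle slices to select (`1 <= k <= n_slices`).
#' @return Integer vector of k slice indices (1-based).
#' @examples
#' select_middle_slices(10, 6)  # 3:8
#' select_middle_slices(8, 1)   # 4
#' @export
select_middle_slices <- function(n_slices, k) {
  stopifnot(n_slices >= 1, k >= 1)
  if (k > n_slices) stop("k must not exceed n_slices")
  start <- floor((n_slices - k) / 2) + 1L
  seq.int(start, start + k - 1L)
}

#' ROI mean T2 over selected slices
#'
#' Arithmetic mean and sample standard deviation of all valid pixels in
#' the selected slices, pooled across slices (pixel-by-pixel analysis, not
#' a mean of per-slice means).
#'
#' @param map A [t2_map()].
#' @param slices Slice indices to include; NULL (default) uses all slices.
#' @return List with `mean` (ms), `sd` (ms, sample SD; NA for a single
#'   pixel), and `n_pixels`.
#' @export
roi_mean_t2 <- function(map, slices = NULL) {
  stopifnot(inherits(map, "t2_map"))
  vals <- roi_values(map, slices)
  if (length(vals) == 0L) stop("empty-ROI error: no valid pixels selected")
  list(mean = mean(vals), sd = if (length(vals) > 1L) sd(vals) else 0,
       n_pixels = length(vals))
}

# valid T2 values of a map restricted to slices (NULL = all)
roi_values <- function(map, slices = NULL) {
  t2 <- map$t2; valid <- map$valid
  if (!is.null(slices)) {
    n <- dim(t2)[map$slice_axis]
    if (any(slices < 1 | slices > n)) stop("slice index out of range")
    t2 <- slice_subset(t2, map$slice_axis, slices)
    valid <- slice_subset(valid, map$slice_axis, slices)
  }
  t2[valid]
}
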