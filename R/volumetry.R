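#' Compartment volume from a label map
#'
#' Volume of a labelled compartment as voxel count times voxel volume
#' (voxel centres, no partial-volume weighting — the counting a manual
#' outline implies). When `include_children = TRUE` (default), labels
#' whose `parent` in the code table is the requested label are counted
#' too, so a compartment's volume includes lesion voxels carved out of it.
#'
#' @param mask A [label_map()].
#' @param label Label code to measure; must be present in the code table.
#' @param include_children Include labels parented to `label`.
#' @return Volume in mm^3.
#' @examples
#' lm <- build_labelmap(phantom_spec(grid = c(48, 48, 6)))
#' compartment_volume(lm, 2)
#' @export
compartment_volume <- function(mask, label, include_children = TRUE) {
  stopifnot(inherits(mask, "label_map"))
  label <- as.integer(label)
  if (!label %in% mask$code_table$label)
    stop("unknown label ", label)
  want <- label
  if (include_children) {
    kids <- mask$code_table$label[!is.na(mask$code_table$parent) &
                                    mask$code_table$parent == label]
    want <- c(want, kids)
  }
  sum(mask$labels %in% want) * prod(mask$voxel_size)
}

#' Cross-sectional area of a compartment at one axial slice
#'
#' In-plane voxel count times in-plane pixel area at the given slice.
#' The default slice is the middle of the stack (the study does not state
#' which slice its CSA used).
#'
#' @param mask A [label_map()].
#' @param label Label code to measure.
#' @param slice_index Axial slice index (1-based); default middle slice.
#' @param include_children Include labels parented to `label`.
#' @return Area in mm^2.
#' @export
cross_sectional_area <- function(mask, label, slice_index = NULL,
                                 include_children = TRUE) {
  stopifnot(inherits(mask, "label_map"))
  label <- as.integer(label)
  if (!label %in% mask$code_table$label)
    stop("unknown label ", label)
  n <- dim(mask$labels)[mask$slice_axis]
  if (is.null(slice_index))
    slice_index <- select_middle_slices(n, 1L)
  if (slice_index < 1 || slice_index > n)
    stop("slice index out of range")
  want <- label
  if (include_children) {
    kids <- mask$code_table$label[!is.na(mask$code_table$parent) &
                                    mask$code_table$parent == label]
    want <- c(want, kids)
  }
  plane <- slice_subset(mask$labels, mask$slice_axis, slice_index)
  pixel_area <- prod(mask$voxel_size[-mask$slice_axis])
  sum(plane %in% want) * pixel_area
}
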