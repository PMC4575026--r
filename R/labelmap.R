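#' Label map container
#'
#' An integer segmentation volume on the image grid. Code 0 is background;
#' the code table maps codes to names and, optionally, to a parent
#' compartment (lesion voxels carved out of a muscle compartment keep a
#' pointer to it so whole-compartment volumes can include them).
#'
#' @param labels 3D integer array of label codes (>= 0).
#' @param voxel_size Voxel size in mm per axis (length 3).
#' @param slice_axis Axis index of the slice (axial) direction.
#' @param code_table `data.frame` with columns `label`, `name` and
#'   optionally `parent` (NA when a code has no enclosing compartment).
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, voxel_size, slice_axis = 3L,
                      code_table = NULL) {
  stopifnot(length(dim(labels)) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0), slice_axis %in% 1:3)
  if (any(labels < 0) || any(labels != as.integer(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  if (is.null(code_table)) {
    codes <- sort(unique(as.integer(labels[labels > 0])))
    code_table <- data.frame(label = codes,
                             name = paste0("label_", codes),
                             parent = NA_integer_)
  }
  if (!"parent" %in% names(code_table)) code_table$parent <- NA_integer_
  structure(
    list(labels = labels, voxel_size = as.numeric(voxel_size),
         slice_axis = as.integer(slice_axis), code_table = code_table),
    class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  tab <- table(x$labels)
  for (i in seq_len(nrow(x$code_table))) {
    lab <- x$code_table$label[i]
    cat(sprintf("  %d %-18s %s voxels\n", lab, x$code_table$name[i],
                format(if (as.character(lab) %in% names(tab))
                  tab[[as.character(lab)]] else 0L)))
  }
  invisible(x)
}

#' Build the phantom label map
#'
#' Paints the elliptical compartments of a [phantom_spec()] onto the voxel
#' grid (a voxel belongs to a region when its centre falls inside the
#' ellipse), then replaces the requested fraction of muscle voxels
#' (codes 1 and 2) with lesion code 3. Lesion voxels are drawn uniformly at
#' random inside muscle, or as clustered in-plane blobs when
#' `lesion_cluster_radius > 0`. The label coding is
#' 0 background, 1 anterior, 2 posterior, 3 lesion, 4 bone.
#'
#' @param spec A [phantom_spec()].
#' @return A [label_map()]. The achieved lesion voxel count is
#'   `round(lesion_fraction * n_muscle)`.
#' @examples
#' lm <- build_labelmap(phantom_spec(grid = c(32, 32, 4)))
#' table(lm$labels)
#' @export
build_labelmap <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  vx <- spec$voxel_size
  # voxel-centre coordinates in mm
  x <- (seq_len(g[1]) - 0.5) * vx[1]
  y <- (seq_len(g[2]) - 0.5) * vx[2]
  plane <- matrix(0L, g[1], g[2])
  for (cp in spec$compartments) {
    if (any(cp$center - cp$semi_axes < 0) ||
        any(cp$center + cp$semi_axes > spec$fov))
      stop("geometry error: compartment '", cp$name, "' exceeds the grid")
    inside <- outer((x - cp$center[1])^2 / cp$semi_axes[1]^2,
                    (y - cp$center[2])^2 / cp$semi_axes[2]^2, `+`) <= 1
    if (any(plane[inside] != 0L))
      stop("geometry error: compartment '", cp$name,
           "' overlaps another region")
    plane[inside] <- cp$label
  }
  labels <- array(plane, dim = g)

  muscle_idx <- which(labels == 1L | labels == 2L)
  n_lesion <- round(spec$lesion_fraction * length(muscle_idx))
  if (n_lesion > 0) {
    parent_of_lesion <- unique(labels[muscle_idx])
    chosen <- with_seed(spec$seed, {
      if (spec$lesion_cluster_radius <= 0) {
        sample(muscle_idx, n_lesion)
      } else {
        pick_clustered_lesions(labels, muscle_idx, n_lesion,
                               spec$lesion_cluster_radius, vx)
      }
    })
    labels[chosen] <- 3L
  }

  ct <- data.frame(
    label = c(1L, 2L, 3L, 4L),
    name = c("anterior", "posterior", "lesion", "bone"),
    parent = NA_integer_)
  if (n_lesion > 0) {
    # parent is recorded only when every lesion voxel sits in one compartment
    comp_of_lesion <- unique(array(plane, g)[chosen])
    if (length(comp_of_lesion) == 1L)
      ct$parent[ct$label == 3L] <- comp_of_lesion
  }
  label_map(labels, vx, slice_axis = 3L, code_table = ct)
}

# greedy clustered placement: sample in-plane seed voxels and grow discs of
# the given radius inside muscle until the requested count is reached.
pick_clustered_lesions <- function(labels, muscle_idx, n_lesion,
                                   radius, voxel_size) {
  g <- dim(labels)
  coord <- arrayInd(muscle_idx, g)
  chosen <- integer(0)
  remaining <- seq_along(muscle_idx)
  while (length(chosen) < n_lesion && length(remaining) > 0) {
    s <- sample(remaining, 1L)
    sc <- coord[s, ]
    d2 <- ((coord[remaining, 1] - sc[1]) * voxel_size[1])^2 +
      ((coord[remaining, 2] - sc[2]) * voxel_size[2])^2
    same_slice <- coord[remaining, 3] == sc[3]
    blob <- remaining[same_slice & d2 <= radius^2]
    chosen <- c(chosen, blob)
    remaining <- setdiff(remaining, blob)
  }
  muscle_idx[chosen[seq_len(min(n_lesion, length(chosen)))]]
}
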