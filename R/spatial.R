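# Cohort heat maps of detection classes in a common template space.
#
# For each image, the voxels belonging to a detection class are collected
# into a binary class mask; averaging these masks over a cohort yields a
# heat map whose value at a voxel is the fraction of images in which that
# class occurred there (1 = the class occurs at that voxel in every
# cohort member).

#' Binary mask of one detection class's voxels
#'
#' Collects the voxels of every match group with the given class.  By
#' default the spatial footprint of a group is the union of both sides'
#' member objects; this is the only support rule that gives the
#' disagreement classes (0-1, 1-0) nonempty support symmetrically.
#' Reference-only or algorithm-only footprints are selectable.
#'
#' @param report a [evaluate_pair()] result.
#' @param class_code one of the six class codes (see
#'   [detection_classes()]).
#' @param support \code{"both"} (default), \code{"reference"} (side_b
#'   members only) or \code{"algorithm"} (side_a members only).
#' @return a [binary_mask()]; empty if the class does not occur.
#' @export
class_voxel_mask <- function(report, class_code,
                             support = c("both", "reference", "algorithm")) {
  stopifnot(inherits(report, "lesion_eval"))
  support <- match.arg(support)
  if (!class_code %in% .class_codes)
    stop("unknown class code: ", class_code, call. = FALSE)
  rows <- which(report$groups$class == class_code)
  fg <- array(FALSE, dim = dim(report$objset_a$labels))
  if (length(rows)) {
    if (support %in% c("both", "algorithm")) {
      ids <- unlist(report$groups$a_members[rows], use.names = FALSE)
      if (length(ids)) fg <- fg | report$objset_a$labels %in% ids
    }
    if (support %in% c("both", "reference")) {
      ids <- unlist(report$groups$b_members[rows], use.names = FALSE)
      if (length(ids)) fg <- fg | report$objset_b$labels %in% ids
    }
    dim(fg) <- dim(report$objset_a$labels)
  }
  binary_mask(fg, spacing = report$objset_a$spacing,
              space_tag = report$objset_a$space_tag,
              source_id = paste0("class-", class_code))
}

#' Cohort heat map of a detection class
#'
#' Voxelwise mean of per-image binary class masks over a cohort in a
#' common space.  Values lie on the grid {0, 1/n, ..., 1} for cohort
#' size n.
#'
#' @param masks list of comparable [binary_mask()] objects (one per
#'   cohort image), e.g. from [class_voxel_mask()].
#' @param class_code class code recorded on the map (optional).
#' @return object of class \code{class_heat_map}: list with the real
#'   \code{grid} in [0, 1], \code{n_images}, \code{spacing},
#'   \code{space_tag}, \code{class}, \code{display_threshold} (0 until
#'   thresholded).
#' @export
heat_map <- function(masks, class_code = NA_character_) {
  if (!length(masks))
    stop("insufficient data: empty mask list", call. = FALSE)
  for (m in masks[-1L]) assert_comparable(masks[[1L]], m)
  acc <- Reduce(`+`, lapply(masks, function(m) m$grid * 1))
  structure(list(grid = acc / length(masks), n_images = length(masks),
                 spacing = masks[[1L]]$spacing,
                 space_tag = masks[[1L]]$space_tag,
                 class = class_code, display_threshold = 0),
            class = "class_heat_map")
}

#' @export
print.class_heat_map <- function(x, ...) {
  cat("<class_heat_map>",
      if (!is.na(x$class)) paste0(" class ", x$class),
      " over ", x$n_images, " image(s), ",
      paste(dim(x$grid), collapse = " x "), " grid\n", sep = "")
  cat("  max value: ", format(max(x$grid)),
      "   display threshold: ", x$display_threshold, "\n", sep = "")
  invisible(x)
}

#' Threshold a heat map for display
#'
#' Values below the threshold are zeroed; values at or above it are kept
#' unchanged.  This is a display operation (it suppresses low-instance
#' voxels so rarer occurrences remain visible), not a statistic.
#'
#' @param map a [heat_map()] result.
#' @param threshold display threshold in [0, 1] (0.15 by default).
#' @return the thresholded \code{class_heat_map}.
#' @export
display_threshold <- function(map, threshold = 0.15) {
  stopifnot(inherits(map, "class_heat_map"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  map$grid[map$grid < threshold] <- 0
  map$display_threshold <- threshold
  map
}

#' Axial maximum intensity projection
#'
#' Per-(x, y) maximum over the axial (third storage) axis.
#'
#' @param map a \code{class_heat_map}, a [binary_mask()], or a 3D array.
#' @return 2D numeric matrix.
#' @export
axial_mip <- function(map) {
  g <- if (inherits(map, "class_heat_map")) map$grid
       else if (inherits(map, "binary_mask")) map$grid * 1
       else map
  if (length(dim(g)) != 3L)
    stop("axial MIP requires a 3D volume", call. = FALSE)
  apply(g, c(1L, 2L), max)
}

#' Write a heat map as a NIfTI volume
#'
#' @param map a \code{class_heat_map}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_heat_map <- function(map, path) {
  stopifnot(inherits(map, "class_heat_map"))
  img <- RNifti::asNifti(map$grid)
  RNifti::pixdim(img) <- map$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
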