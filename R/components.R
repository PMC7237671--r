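# Connected-component extraction for binary masks.
#
# Lesion-wise analysis starts by decomposing each segmentation into its
# connected components ("objects", i.e. individual lesions).  Default
# adjacency is 6-connected in 3D (4-connected in 2D): voxels are neighbors
# only through shared faces.  18 and 26 (8 in 2D) are available for
# connectivity sensitivity analyses; coarser connectivity can only merge
# objects, never split them.

# positive half-space neighbor offsets for each connectivity model
.neighbor_offsets <- function(ndim, connectivity) {
  if (ndim == 3L) {
    face <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    edge <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                  c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
    corner <- rbind(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
    switch(as.character(connectivity),
           "6"  = face,
           "18" = rbind(face, edge),
           "26" = rbind(face, edge, corner),
           stop("connectivity must be 6, 18 or 26 for 3D grids",
                call. = FALSE))
  } else {
    face <- rbind(c(1, 0), c(0, 1))
    diag <- rbind(c(1, 1), c(1, -1))
    switch(as.character(connectivity),
           "4" = face,
           "8" = rbind(face, diag),
           stop("connectivity must be 4 or 8 for 2D grids", call. = FALSE))
  }
}

# all pairs of adjacent foreground voxels (linear indices), vectorized by
# shifting the grid along each neighbor offset
.adjacency_pairs <- function(grid, offsets) {
  d <- dim(grid)
  lin <- array(seq_len(prod(d)), dim = d)
  out <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    o <- offsets[k, ]
    rng <- lapply(seq_along(d), function(i)
      seq.int(max(1L, 1L - o[i]), min(d[i], d[i] - o[i])))
    if (any(vapply(rng, length, 1L) == 0L)) next
    shifted <- lapply(seq_along(d), function(i) rng[[i]] + o[i])
    src <- do.call(`[`, c(list(grid), rng, list(drop = FALSE)))
    dst <- do.call(`[`, c(list(grid), shifted, list(drop = FALSE)))
    hit <- src & dst
    if (!any(hit)) next
    isrc <- do.call(`[`, c(list(lin), rng, list(drop = FALSE)))[hit]
    idst <- do.call(`[`, c(list(lin), shifted, list(drop = FALSE)))[hit]
    out[[k]] <- cbind(isrc, idst)
  }
  do.call(rbind, c(out, list(matrix(integer(0), ncol = 2))))
}

#' Label the connected components of a binary mask
#'
#' Partitions the mask foreground into maximal connected components under
#' the requested adjacency model.  Object ids are assigned 1..K in the
#' scan order of each object's first voxel (column-major array order), so
#' labelings are reproducible.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces, edges,
#'   corners) for 3D grids; 4 or 8 for 2D.  Default 6 in 3D, 4 in 2D.
#' @return an object of class \code{object_set}: a list with the integer
#'   label array \code{labels} (0 = background), the grid metadata, the
#'   \code{connectivity} used, and \code{objects}, a data frame with one
#'   row per component (\code{object_id}, \code{voxel_count},
#'   \code{volume_mm3}).
#' @export
label_components <- function(mask, connectivity = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  ndim <- length(dim(mask$grid))
  if (is.null(connectivity)) connectivity <- if (ndim == 3L) 6L else 4L
  offsets <- .neighbor_offsets(ndim, connectivity)

  fg <- which(mask$grid)
  labels <- array(0L, dim = dim(mask$grid))
  if (length(fg)) {
    vid <- integer(prod(dim(mask$grid)))
    vid[fg] <- seq_along(fg)
    pairs <- .adjacency_pairs(mask$grid, offsets)
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
    if (nrow(pairs))
      g <- igraph::add_edges(g, rbind(vid[pairs[, 1L]], vid[pairs[, 2L]]))
    memb <- igraph::components(g)$membership
    # relabel components by raster order of their first voxel
    first <- vapply(split(fg, memb), min, numeric(1))
    relabel <- integer(length(first))
    relabel[order(first)] <- seq_along(first)
    labels[fg] <- relabel[memb]
  }
  counts <- if (any(labels > 0L)) tabulate(labels[labels > 0L]) else integer(0)
  objects <- data.frame(object_id = seq_along(counts),
                        voxel_count = counts,
                        volume_mm3 = counts * prod(mask$spacing))
  structure(list(labels = labels, spacing = mask$spacing,
                 space_tag = mask$space_tag, source_id = mask$source_id,
                 connectivity = as.integer(connectivity), objects = objects),
            class = "object_set")
}

#' @export
print.object_set <- function(x, ...) {
  cat("<object_set> ", nrow(x$objects), " object(s), ",
      x$connectivity, "-connectivity, ",
      paste(dim(x$labels), collapse = " x "), " grid\n", sep = "")
  if (nrow(x$objects)) {
    v <- x$objects$volume_mm3
    cat("  volumes (mm^3): min ", format(min(v)), ", median ",
        format(stats::median(v)), ", max ", format(max(v)), "\n", sep = "")
  }
  invisible(x)
}

#' Voxel indices of each object
#'
#' @param objset an \code{object_set}.
#' @return named list mapping object id to the sorted linear voxel indices
#'   of that object.
#' @export
object_voxels <- function(objset) {
  fg <- which(objset$labels > 0L)
  if (!length(fg)) return(structure(list(), names = character(0)))
  lapply(split(fg, objset$labels[fg]), sort)
}

#' Remove small objects
#'
#' Retains exactly the objects whose volume is strictly greater than the
#' threshold; an object of exactly the threshold volume is removed (so a
#' 1 mm^3 threshold on a 1 mm isotropic grid removes all single-voxel
#' lesions).  Surviving objects keep their original ids.
#'
#' @param objset an \code{object_set}.
#' @param threshold_mm3 non-negative volume threshold in mm^3; 0 retains
#'   everything.
#' @return an \code{object_set} with the small objects removed.
#' @export
suppress_small <- function(objset, threshold_mm3) {
  stopifnot(inherits(objset, "object_set"))
  if (!is.numeric(threshold_mm3) || length(threshold_mm3) != 1L ||
      is.na(threshold_mm3) || threshold_mm3 < 0)
    stop("threshold_mm3 must be a single non-negative number", call. = FALSE)
  keep <- objset$objects$volume_mm3 > threshold_mm3
  out <- objset
  if (!all(keep)) {
    drop_ids <- objset$objects$object_id[!keep]
    out$labels[out$labels %in% drop_ids] <- 0L
    out$objects <- objset$objects[keep, , drop = FALSE]
    rownames(out$objects) <- NULL
  }
  out
}

#' Rebuild a binary mask from an object set
#'
#' The returned mask's foreground is the union of the objects' voxels;
#' \code{rebuild_mask(label_components(m))} reproduces \code{m}.
#'
#' @param objset an \code{object_set}.
#' @return a [binary_mask()].
#' @export
rebuild_mask <- function(objset) {
  stopifnot(inherits(objset, "object_set"))
  binary_mask(objset$labels > 0L, spacing = objset$spacing,
              space_tag = objset$space_tag, source_id = objset$source_id)
}
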