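# Object correspondence between two segmentations.
#
# Objects from the two sides are matched through voxel overlap: an
# algorithm object u_i corresponds to every reference object v_j it shares
# at least one voxel with.  The connected components of this bipartite
# overlap graph ("match groups"), together with one singleton group per
# unmatched object, partition all objects of both segmentations; the
# (M, N) cardinalities of each group determine its detection class.
#
# Convention throughout: side_a is the algorithm (or second-listed rater),
# side_b is the manual / reference segmentation, and class codes are
# written algorithm-first, so 0-1 means the reference saw a lesion that
# the algorithm missed.

.class_codes <- c("1-1", "1-N", "M-1", "M-N", "0-1", "1-0")

.class_labels <- data.frame(
  code = .class_codes,
  algorithm_context = c("Correct Detection", "Merge", "Split", "Split-Merge",
                        "Detection Failure", "False Alarm"),
  manual_context = c("Expert Agreement", "Ambiguous Masks", "Ambiguous Masks",
                     "Ambiguous Masks", "Expert Disagreement",
                     "Expert Disagreement"))

#' Detection-class codes and labels
#'
#' The six-class taxonomy of object correspondences.  Codes are written
#' algorithm-first: \code{"1-N"} means one algorithm object overlaps N
#' reference objects (a merge), \code{"M-1"} the reverse (a split),
#' \code{"0-1"} a lesion only the reference saw (detection failure) and
#' \code{"1-0"} one only the algorithm saw (false alarm).  In a
#' rater-vs-rater comparison the same codes read as expert agreement
#' (1-1), ambiguous masks (1-N, M-1, M-N) and expert disagreement
#' (0-1, 1-0).
#'
#' @return data frame with columns \code{code}, \code{algorithm_context},
#'   \code{manual_context}.
#' @export
detection_classes <- function() .class_labels

#' Classify a match group from its cardinalities
#'
#' @param m number of algorithm-side (side_a) objects in the group.
#' @param n number of reference-side (side_b) objects in the group.
#'   Both vectorized.
#' @return character vector of class codes (see [detection_classes()]).
#' @export
detection_class <- function(m, n) {
  if (length(m) != length(n))
    stop("m and n must have equal length", call. = FALSE)
  if (any(m == 0 & n == 0))
    stop("internal consistency error: empty match group (M = N = 0)",
         call. = FALSE)
  ifelse(m == 0L, "0-1",
  ifelse(n == 0L, "1-0",
  ifelse(m == 1L & n == 1L, "1-1",
  ifelse(m == 1L, "1-N",
  ifelse(n == 1L, "M-1", "M-N")))))
}

.assert_same_grid <- function(side_a, side_b) {
  if (!identical(dim(side_a$labels), dim(side_b$labels)))
    stop("grid mismatch: shapes differ", call. = FALSE)
  if (!isTRUE(all.equal(side_a$spacing, side_b$spacing, tolerance = 1e-6)))
    stop("grid mismatch: voxel spacing differs", call. = FALSE)
  if (!identical(side_a$space_tag, side_b$space_tag))
    stop("grid mismatch: space_tag differs", call. = FALSE)
  invisible(TRUE)
}

#' Build the voxel-overlap graph between two object sets
#'
#' An edge joins object \code{a_id} of \code{side_a} and object
#' \code{b_id} of \code{side_b} exactly when the two objects share at
#' least one voxel, and carries the exact intersection size.
#'
#' @param side_a,side_b \code{object_set}s on the same grid
#'   (\code{side_a} = algorithm, \code{side_b} = reference by convention).
#' @return an object of class \code{overlap_graph}: a list with
#'   \code{edges} (data frame \code{a_id}, \code{b_id},
#'   \code{overlap_voxels}) and the two object sets.
#' @export
build_overlap_graph <- function(side_a, side_b) {
  stopifnot(inherits(side_a, "object_set"), inherits(side_b, "object_set"))
  .assert_same_grid(side_a, side_b)
  both <- side_a$labels > 0L & side_b$labels > 0L
  if (any(both)) {
    la <- side_a$labels[both]
    lb <- side_b$labels[both]
    o <- order(la, lb)
    la <- la[o]; lb <- lb[o]
    new <- c(TRUE, la[-1L] != la[-length(la)] | lb[-1L] != lb[-length(lb)])
    edges <- data.frame(a_id = la[new], b_id = lb[new],
                        overlap_voxels = tabulate(cumsum(new)))
  } else {
    edges <- data.frame(a_id = integer(0), b_id = integer(0),
                        overlap_voxels = integer(0))
  }
  structure(list(edges = edges, side_a = side_a, side_b = side_b),
            class = "overlap_graph")
}

#' Group corresponding objects and classify each group
#'
#' Match groups are the connected components of the bipartite overlap
#' graph, plus one singleton group per unmatched object on either side;
#' every object of both segmentations lands in exactly one group.  Each
#' group is classified from its cardinalities (see [detection_class()])
#' and scored with the group Sorensen-Dice index
#' \deqn{2 |U_a \cap U_b| / (|U_a| + |U_b|)}
#' where \eqn{U_a}, \eqn{U_b} are the unions of the group's member
#' objects on each side (exactly 0 for 0-1 and 1-0 groups).  The group's
#' reference volume is the summed volume of its side_b (reference)
#' members; for 1-0 groups, which have no reference member, the side_a
#' volume is used instead.
#'
#' @param graph an [build_overlap_graph()] result.
#' @return data frame of class \code{match_groups} with one row per group:
#'   \code{group_id}, \code{class}, \code{M}, \code{N},
#'   \code{overlap_voxels}, \code{group_sdi}, \code{ref_volume_mm3}, and
#'   list columns \code{a_members}, \code{b_members} of member object ids.
#' @export
match_groups <- function(graph) {
  stopifnot(inherits(graph, "overlap_graph"))
  a_ids <- graph$side_a$objects$object_id
  b_ids <- graph$side_b$objects$object_id
  na <- length(a_ids)
  nb <- length(b_ids)
  if (na + nb == 0L) {
    out <- data.frame(group_id = integer(0), class = character(0),
                      M = integer(0), N = integer(0),
                      overlap_voxels = integer(0), group_sdi = numeric(0),
                      ref_volume_mm3 = numeric(0))
    out$a_members <- list()
    out$b_members <- list()
    class(out) <- c("match_groups", "data.frame")
    return(out)
  }
  # vertices 1..na are side_a objects (by table position), then side_b
  g <- igraph::make_empty_graph(n = na + nb, directed = FALSE)
  e <- graph$edges
  va <- match(e$a_id, a_ids)
  vb <- na + match(e$b_id, b_ids)
  if (nrow(e))
    g <- igraph::add_edges(g, rbind(va, vb))
  memb <- igraph::components(g)$membership
  grp_of_a <- memb[seq_len(na)]
  grp_of_b <- memb[na + seq_len(nb)]

  lev <- seq_len(max(memb))
  a_members <- split(a_ids, factor(grp_of_a, levels = lev))
  b_members <- split(b_ids, factor(grp_of_b, levels = lev))
  keep <- which(lengths(a_members) + lengths(b_members) > 0L)
  a_members <- a_members[keep]
  b_members <- b_members[keep]

  M <- lengths(a_members)
  N <- lengths(b_members)
  cls <- detection_class(M, N)

  ov <- numeric(length(keep))
  if (nrow(e)) {
    grp_of_edge <- match(memb[va], keep)
    sums <- tapply(e$overlap_voxels, grp_of_edge, sum)
    ov[as.integer(names(sums))] <- sums
  }
  vox_a <- vapply(a_members, function(id)
    sum(graph$side_a$objects$voxel_count[match(id, graph$side_a$objects$object_id)]),
    numeric(1))
  vox_b <- vapply(b_members, function(id)
    sum(graph$side_b$objects$voxel_count[match(id, graph$side_b$objects$object_id)]),
    numeric(1))
  sdi <- ifelse(vox_a + vox_b > 0, 2 * ov / (vox_a + vox_b), 0)

  vol_b <- vapply(b_members, function(id)
    sum(graph$side_b$objects$volume_mm3[match(id, graph$side_b$objects$object_id)]),
    numeric(1))
  vol_a <- vapply(a_members, function(id)
    sum(graph$side_a$objects$volume_mm3[match(id, graph$side_a$objects$object_id)]),
    numeric(1))
  ref_vol <- ifelse(N > 0L, vol_b, vol_a)

  out <- data.frame(group_id = seq_along(keep), class = cls,
                    M = as.integer(M), N = as.integer(N),
                    overlap_voxels = ov, group_sdi = sdi,
                    ref_volume_mm3 = ref_vol,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$a_members <- unname(a_members)
  out$b_members <- unname(b_members)
  class(out) <- c("match_groups", "data.frame")
  out
}
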