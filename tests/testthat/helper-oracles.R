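# Independent oracles, coded from first principles so they share no logic
# with the package internals they check.

# all neighbor offsets (both directions) derived from the Chebyshev /
# city-block characterization of the connectivity models
oracle_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6"  = g[rowSums(abs(g)) == 1, , drop = FALSE],
         "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "26" = g)
}

# breadth-first flood fill over voxel coordinates
oracle_flood_fill <- function(grid, connectivity = 6) {
  d <- dim(grid)
  offs <- oracle_offsets(connectivity)
  labels <- array(0L, dim = d)
  nextlab <- 0L
  for (start in which(grid)) {
    if (labels[start] > 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    labels[start] <- nextlab
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      co <- arrayInd(v, d)
      nb <- offs + matrix(co, nrow(offs), 3L, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
            nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      hit <- lin[grid[lin] & labels[lin] == 0L]
      labels[hit] <- nextlab
      queue <- c(queue, hit)
    }
  }
  labels
}

# all-pairs voxel-set intersections between two labelings
oracle_overlap_edges <- function(lab_a, lab_b) {
  ids_a <- setdiff(sort(unique(as.vector(lab_a))), 0L)
  ids_b <- setdiff(sort(unique(as.vector(lab_b))), 0L)
  out <- list()
  for (i in ids_a) {
    vi <- which(lab_a == i)
    for (j in ids_b) {
      ov <- length(intersect(vi, which(lab_b == j)))
      if (ov > 0)
        out[[length(out) + 1L]] <- data.frame(a_id = i, b_id = j,
                                              overlap_voxels = ov)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(a_id = integer(0), b_id = integer(0),
               overlap_voxels = integer(0))
}

# classic union-find grouping of the bipartite overlap graph; returns for
# each a- and b-object the id of its group root
oracle_group_objects <- function(edges, ids_a, ids_b) {
  n <- length(ids_a) + length(ids_b)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$a_id[k], ids_a)
    j <- length(ids_a) + match(edges$b_id[k], ids_b)
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), find, integer(1))
  list(a = roots[seq_along(ids_a)],
       b = roots[length(ids_a) + seq_along(ids_b)])
}

# exact two-sided signed-rank p-value by enumeration of all sign vectors
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(1, p)
}

random_mask <- function(dim3, density = 0.2, seed = 1, spacing = c(1, 1, 1),
                        space_tag = "test") {
  set.seed(seed)
  binary_mask(array(runif(prod(dim3)) < density, dim = dim3),
              spacing = spacing, space_tag = space_tag)
}

# mask with objects of given voxel volumes on a 1 mm isotropic grid,
# placed as separated x-runs
mask_with_volumes <- function(volumes, dim3 = c(32, 32, 32)) {
  g <- array(FALSE, dim = dim3)
  z <- 1
  for (i in seq_along(volumes)) {
    v <- volumes[i]
    g[seq_len(min(v, dim3[1])), 2 * i, z] <- TRUE
    stopifnot(v <= dim3[1])
  }
  binary_mask(g, space_tag = "test")
}
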