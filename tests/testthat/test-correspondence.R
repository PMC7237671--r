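objsets <- function(pair, connectivity = 6) {
  list(a = label_components(pair$side_a, connectivity),
       b = label_components(pair$side_b, connectivity))
}

test_that("overlap edges are exactly the nonempty voxel intersections", {
  # disjoint single objects -> no edges
  a <- mask_with_volumes(4)
  gb <- array(FALSE, dim(a$grid))
  gb[1:4, 10, 1] <- TRUE
  b <- binary_mask(gb, space_tag = "test")
  g <- build_overlap_graph(label_components(a), label_components(b))
  expect_identical(nrow(g$edges), 0L)

  # identical 7-voxel objects -> single edge with overlap 7
  m <- mask_with_volumes(7)
  g2 <- build_overlap_graph(label_components(m), label_components(m))
  expect_identical(g2$edges$overlap_voxels, 7L)

  for (seed in 1:6) {
    pa <- random_mask(c(15, 15, 15), density = 0.15, seed = seed)
    pb <- random_mask(c(15, 15, 15), density = 0.15, seed = seed + 50)
    os <- list(a = label_components(pa), b = label_components(pb))
    got <- build_overlap_graph(os$a, os$b)$edges
    want <- oracle_overlap_edges(os$a$labels, os$b$labels)
    got <- got[order(got$a_id, got$b_id), ]
    want <- want[order(want$a_id, want$b_id), ]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("grouping equals the union-find oracle on random pairs", {
  for (seed in 1:6) {
    pa <- random_mask(c(15, 15, 15), density = 0.18, seed = 200 + seed)
    pb <- random_mask(c(15, 15, 15), density = 0.18, seed = 300 + seed)
    oa <- label_components(pa)
    ob <- label_components(pb)
    g <- build_overlap_graph(oa, ob)
    groups <- match_groups(g)

    ids_a <- oa$objects$object_id
    ids_b <- ob$objects$object_id
    want <- oracle_group_objects(g$edges, ids_a, ids_b)
    # membership maps induced by the package grouping
    grp_a <- integer(length(ids_a))
    grp_b <- integer(length(ids_b))
    for (k in seq_len(nrow(groups))) {
      grp_a[match(groups$a_members[[k]], ids_a)] <- k
      grp_b[match(groups$b_members[[k]], ids_b)] <- k
    }
    # same partition of the union of objects
    joint_got <- c(grp_a, grp_b)
    joint_want <- c(want$a, want$b)
    expect_identical(length(unique(paste(joint_got, joint_want))),
                     length(unique(joint_want)))
    expect_identical(length(unique(joint_got)), length(unique(joint_want)))
  }
})

test_that("cardinalities map to the six-class taxonomy", {
  expect_identical(detection_class(1, 1), "1-1")
  expect_identical(detection_class(1, 3), "1-N")
  expect_identical(detection_class(2, 1), "M-1")
  expect_identical(detection_class(4, 3), "M-N")
  expect_identical(detection_class(0, 1), "0-1")
  expect_identical(detection_class(1, 0), "1-0")
  expect_error(detection_class(0, 0), "consistency")

  labels <- detection_classes()
  expect_identical(labels$algorithm_context[labels$code == "1-0"],
                   "False Alarm")
  expect_identical(labels$algorithm_context[labels$code == "0-1"],
                   "Detection Failure")
  expect_identical(labels$algorithm_context[labels$code == "M-1"], "Split")
  expect_identical(labels$manual_context[labels$code == "1-1"],
                   "Expert Agreement")
  expect_identical(unique(labels$manual_context[labels$code %in%
                                                c("1-N", "M-1", "M-N")]),
                   "Ambiguous Masks")
})

test_that("group SDI matches the worked boundary-disagreement example", {
  # one voxel vs two voxels with one voxel overlap -> SDI 2/3
  g <- array(FALSE, c(5, 3, 3))
  a <- binary_mask(`[<-`(g, cbind(2, 2, 2), TRUE))
  b <- binary_mask(`[<-`(g, rbind(c(2, 2, 2), c(3, 2, 2)), TRUE))
  ev <- evaluate_pair(a, b)
  expect_identical(ev$groups$class, "1-1")
  expect_equal(ev$groups$group_sdi, 2 / 3)

  # identical unions -> 1; one-sided groups -> exactly 0
  evb <- evaluate_pair(b, b)
  expect_identical(evb$groups$group_sdi, 1)
  ev0 <- evaluate_pair(binary_mask(g), b)
  expect_identical(ev0$groups$class, "0-1")
  expect_identical(ev0$groups$group_sdi, 0)
})

test_that("every object lands in exactly one group (partition conservation)", {
  for (seed in 1:5) {
    gp <- generate_pair(pair_spec(seed = 400 + seed))
    os <- objsets(gp)
    groups <- match_groups(build_overlap_graph(os$a, os$b))
    expect_identical(sum(groups$M), nrow(os$a$objects))
    expect_identical(sum(groups$N), nrow(os$b$objects))
    expect_identical(sort(unlist(groups$a_members)),
                     os$a$objects$object_id)
    expect_identical(sort(unlist(groups$b_members)),
                     os$b$objects$object_id)
    expect_true(all(groups$class %in% detection_classes()$code))
  }
})

test_that("swapping sides transposes the class codes and keeps group SDI", {
  gp <- generate_pair(pair_spec(seed = 77))
  os <- objsets(gp)
  fwd <- match_groups(build_overlap_graph(os$a, os$b))
  rev <- match_groups(build_overlap_graph(os$b, os$a))
  transpose <- c("1-1" = "1-1", "1-N" = "M-1", "M-1" = "1-N",
                 "M-N" = "M-N", "0-1" = "1-0", "1-0" = "0-1")
  expect_identical(sort(unname(transpose[fwd$class])), sort(rev$class))
  expect_equal(sort(fwd$group_sdi), sort(rev$group_sdi))
})

test_that("group reference volume follows the reference-side rule", {
  gp <- generate_pair(pair_spec(counts = c("1-1" = 1, "1-0" = 1, "0-1" = 1),
                                seed = 3))
  os <- objsets(gp)
  groups <- match_groups(build_overlap_graph(os$a, os$b))
  g10 <- groups[groups$class == "1-0", ]
  truth10 <- gp$truth[gp$truth$class == "1-0", ]
  expect_equal(g10$ref_volume_mm3, truth10$a_volume_mm3)
  g11 <- groups[groups$class == "1-1", ]
  truth11 <- gp$truth[gp$truth$class == "1-1", ]
  expect_equal(g11$ref_volume_mm3, truth11$b_volume_mm3)
})

test_that("grid mismatch is rejected", {
  a <- label_components(binary_mask(array(FALSE, c(4, 4, 4))))
  b <- label_components(binary_mask(array(FALSE, c(5, 5, 5))))
  expect_error(build_overlap_graph(a, b), "mismatch")
})
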