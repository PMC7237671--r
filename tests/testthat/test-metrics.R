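test_that("global SDI follows the set formula and its worked examples", {
  m <- random_mask(c(12, 12, 12), density = 0.2, seed = 1)
  expect_identical(global_sdi(m, m), 1)

  # one voxel vs two with one overlapping -> 2/3, and the same for any r
  for (r in c(1, 5, 100)) {
    g <- array(FALSE, c(210, 2, 2))
    a <- binary_mask(`[<-`(g, cbind(seq_len(r), 1, 1), TRUE))
    b <- binary_mask(`[<-`(g, cbind(seq_len(2 * r), 1, 1), TRUE))
    expect_equal(global_sdi(a, b), 2 / 3)
    # the raters disagree on half of the union's voxels
    disagree <- sum(xor(a$grid, b$grid)) / sum(a$grid | b$grid)
    expect_equal(disagree, 0.5)
  }

  empty <- binary_mask(array(FALSE, dim(m$grid)), space_tag = "test")
  expect_true(is.na(global_sdi(empty, empty)))
  expect_identical(global_sdi(empty, m), 0)
  expect_error(global_sdi(m, binary_mask(array(FALSE, c(5, 5, 5)))),
               "mismatch")
})

test_that("global SDI is symmetric, bounded and decomposes over groups", {
  for (seed in 1:6) {
    gp <- generate_pair(pair_spec(seed = 500 + seed))
    s_ab <- global_sdi(gp$side_a, gp$side_b)
    expect_identical(s_ab, global_sdi(gp$side_b, gp$side_a))
    expect_gte(s_ab, 0)
    expect_lte(s_ab, 1)
    ev <- evaluate_pair(gp$side_a, gp$side_b)
    decomp <- 2 * sum(ev$groups$overlap_voxels) /
      (sum(gp$side_a$grid) + sum(gp$side_b$grid))
    expect_equal(ev$global_sdi, decomp, tolerance = 1e-12)
    expect_equal(s_ab, decomp, tolerance = 1e-12)
  }
})

test_that("voxel subdivision leaves SDI exactly unchanged", {
  gp <- generate_pair(pair_spec(seed = 9))
  refine <- function(m) {
    d <- dim(m$grid)
    binary_mask(m$grid[rep(seq_len(d[1]), each = 2),
                       rep(seq_len(d[2]), each = 2),
                       rep(seq_len(d[3]), each = 2)],
                spacing = m$spacing / 2, space_tag = m$space_tag)
  }
  expect_identical(global_sdi(gp$side_a, gp$side_b),
                   global_sdi(refine(gp$side_a), refine(gp$side_b)))
})

test_that("evaluate_pair reports composition, counts and percentages", {
  gp <- generate_pair(pair_spec(counts = c("1-1" = 2, "M-1" = 1, "1-0" = 1),
                                multiplicity = c(2, 2), seed = 21))
  ev <- evaluate_pair(gp$side_a, gp$side_b)
  cc <- setNames(ev$class_counts$count, ev$class_counts$class)
  expect_identical(cc[["1-1"]], 2L)
  expect_identical(cc[["M-1"]], 1L)
  expect_identical(cc[["1-0"]], 1L)
  expect_identical(sum(cc), 4L)
  expect_equal(sum(ev$class_counts$percentage), 100)
  expect_identical(nrow(ev$per_lesion), nrow(ev$groups))

  # identical masks with separated objects: all 1-1, SDI 1
  m <- mask_with_volumes(c(3, 5, 9))
  ev2 <- evaluate_pair(m, m)
  expect_identical(unique(ev2$groups$class), "1-1")
  expect_identical(nrow(ev2$groups), 3L)
  expect_identical(ev2$global_sdi, 1)

  # empty algorithm side: every reference lesion is a detection failure
  ev3 <- evaluate_pair(binary_mask(array(FALSE, dim(m$grid)),
                                   space_tag = "test"), m)
  expect_identical(unique(ev3$groups$class), "0-1")
  expect_identical(nrow(ev3$groups), 3L)
  expect_identical(ev3$global_sdi, 0)
})

test_that("threshold sweep equals evaluation of pre-suppressed masks", {
  gp <- generate_pair(pair_spec(seed = 31))
  sw <- threshold_sweep(gp$side_a, gp$side_b, c(0, 5, 25))
  expect_identical(sw$threshold_mm3, c(0, 5, 25))

  # threshold 0 reproduces the plain evaluation
  ev0 <- evaluate_pair(gp$side_a, gp$side_b)
  expect_equal(sw$global_sdi[1], ev0$global_sdi)
  expect_identical(sw$n_groups[1], nrow(ev0$groups))

  # each row equals evaluating masks pre-filtered at that threshold
  for (i in 2:3) {
    t <- sw$threshold_mm3[i]
    pa <- rebuild_mask(suppress_small(label_components(gp$side_a), t))
    pb <- rebuild_mask(suppress_small(label_components(gp$side_b), t))
    ev <- evaluate_pair(pa, pb)
    expect_equal(sw$global_sdi[i], ev$global_sdi)
    expect_identical(sw$n_groups[i], nrow(ev$groups))
  }
  expect_error(threshold_sweep(gp$side_a, gp$side_b, c(5, 0)), "ascending")
})

test_that("suppressing small disagreement lesions raises agreement", {
  # a pair agreeing on two large lesions whose only disagreements are
  # small (<= 10 mm^3) lesions unique to one side
  mk <- function(vols, rows) {
    g <- array(FALSE, c(64, 24, 4))
    for (i in seq_along(vols)) g[seq_len(vols[i]), rows[i], 2] <- TRUE
    binary_mask(g, space_tag = "test")
  }
  a <- mk(c(40, 50, 3, 2), c(2, 4, 6, 8))     # two shared + two small extra
  b <- mk(c(40, 50, 4), c(2, 4, 10))          # two shared + one small extra
  sw <- threshold_sweep(a, b, c(0, 10))
  disagreement <- sw$n_0_1 + sw$n_1_0
  expect_gt(disagreement[1], 0)
  expect_identical(disagreement[2], 0L)
  expect_gte(sw$global_sdi[2], sw$global_sdi[1])
})

test_that("summarize_sdi matches direct arithmetic and handles NA", {
  s <- summarize_sdi(c(0.5, 0.6, 0.7))
  expect_equal(s$mean, 0.6)
  expect_equal(s$min, 0.5)
  expect_equal(s$max, 0.7)

  sall <- summarize_sdi(rep(0.4, 5))
  expect_identical(sall$sd, 0)
  expect_identical(diff(sall$ci), 0)

  set.seed(99)
  v <- runif(61)
  s2 <- summarize_sdi(v)
  z <- qnorm(0.975)
  expect_equal(s2$mean, sum(v) / 61, tolerance = 1e-12)
  expect_equal(s2$sd, sqrt(sum((v - mean(v))^2) / 60), tolerance = 1e-12)
  expect_equal(s2$ci, mean(v) + c(-1, 1) * z * sd(v) / sqrt(61),
               tolerance = 1e-12)

  s3 <- summarize_sdi(c(0.5, NA, 0.7, NA))
  expect_identical(s3$n_excluded, 2L)
  expect_identical(s3$n, 2L)
  expect_error(summarize_sdi(c(0.5, NA)), "at least 2")
})
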