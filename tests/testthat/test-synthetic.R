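test_that("requested composition is recovered exactly by evaluation", {
  gp <- generate_pair(pair_spec(counts = c("1-1" = 3, "0-1" = 2), seed = 1))
  ev <- evaluate_pair(gp$side_a, gp$side_b)
  cc <- setNames(ev$class_counts$count, ev$class_counts$class)
  expect_identical(cc[["1-1"]], 3L)
  expect_identical(cc[["0-1"]], 2L)
  expect_identical(sum(cc), 5L)
})

test_that("generated truth and classification agree for every class mix", {
  for (seed in 1:10) {
    gp <- generate_pair(pair_spec(seed = 600 + seed))
    ev <- evaluate_pair(gp$side_a, gp$side_b)
    got <- table(factor(ev$groups$class, levels = detection_classes()$code))
    want <- table(factor(gp$truth$class, levels = detection_classes()$code))
    expect_identical(as.vector(got), as.vector(want))
    # cardinalities survive as well
    expect_identical(sort(paste(ev$groups$M, ev$groups$N)),
                     sort(paste(gp$truth$M, gp$truth$N)))
  }
})

test_that("split multiplicity is honored", {
  gp <- generate_pair(pair_spec(counts = c("M-1" = 1),
                                multiplicity = c(2, 2), seed = 2))
  ev <- evaluate_pair(gp$side_a, gp$side_b)
  expect_identical(ev$groups$M, 2L)
  expect_identical(ev$groups$N, 1L)
})

test_that("all-zero counts produce two empty masks", {
  gp <- generate_pair(pair_spec(counts = c("1-1" = 0), seed = 3))
  expect_identical(sum(gp$side_a$grid), 0L)
  expect_identical(sum(gp$side_b$grid), 0L)
  expect_identical(nrow(gp$truth), 0L)
})

test_that("generation is a deterministic function of the spec", {
  sp <- pair_spec(seed = 4)
  expect_identical(generate_pair(sp)$side_a$grid,
                   generate_pair(sp)$side_a$grid)
  es <- ensemble_spec(n_subjects = 2, timepoints = 2, seed = 5)
  e1 <- generate_ensemble(es)
  e2 <- generate_ensemble(es)
  expect_identical(e1$algorithms$A1[[1]]$grid, e2$algorithms$A1[[1]]$grid)
  expect_identical(e1$truth, e2$truth)
})

test_that("realized 1-1 overlap tracks the requested target", {
  gp <- generate_pair(pair_spec(counts = c("1-1" = 10),
                                volume_range = c(20, 200), seed = 6))
  ev <- evaluate_pair(gp$side_a, gp$side_b)
  expect_equal(sort(ev$groups$group_sdi), sort(gp$truth$realized_sdi),
               tolerance = 1e-12)
  expect_true(all(abs(gp$truth$realized_sdi - 0.65) < 0.06))
})

test_that("an exact-copy profile reproduces the reference masks", {
  es <- ensemble_spec(n_subjects = 2, timepoints = 1,
                      grid_dim = c(24, 24, 24), lesions_per_image = 3,
                      profiles = list(copy = function(v) rep(1, length(v))),
                      noise_sd = 0, seed = 7)
  en <- generate_ensemble(es)
  for (id in names(en$reference))
    expect_identical(en$algorithms$copy[[id]]$grid, en$reference[[id]]$grid)
})

test_that("rendered ensemble SDI tracks the per-volume profile", {
  es <- ensemble_spec(n_subjects = 6, timepoints = 2, seed = 8)
  en <- generate_ensemble(es)
  for (a in c("A1", "A2")) {
    tr <- en$truth[en$truth$algorithm == a & en$truth$rendered, ]
    prof <- es$profiles[[a]](tr$ref_volume_mm3)
    below <- tr$ref_volume_mm3 <= 50
    expect_lt(abs(mean(tr$realized_sdi[below]) - mean(prof[below])), 0.05)
    expect_lt(abs(mean(tr$realized_sdi[!below]) - mean(prof[!below])), 0.05)
  }
  # realized SDI agrees with what evaluation measures
  id <- names(en$reference)[1]
  ev <- evaluate_pair(en$algorithms$A1[[id]], en$reference[[id]])
  tr1 <- en$truth[en$truth$algorithm == "A1" & en$truth$image_id == id, ]
  expect_equal(sort(ev$groups$group_sdi[ev$groups$class == "1-1"]),
               sort(tr1$realized_sdi[tr1$rendered]), tolerance = 1e-12)
})

test_that("false alarms and detection failures are injected at the stated rates", {
  es <- ensemble_spec(n_subjects = 6, timepoints = 2,
                      grid_dim = c(40, 40, 40), lesions_per_image = 3,
                      volume_range = c(5, 40), false_alarm_rate = 1.5,
                      detection_failure_rate = 0.3, seed = 9)
  en <- generate_ensemble(es)
  miss_rate <- mean(!en$truth$rendered)
  expect_lt(abs(miss_rate - 0.3), 0.1)
  expect_gt(nrow(en$false_alarms), 0)

  # evaluation sees exactly the injected disagreements per image
  id <- names(en$reference)[2]
  for (a in names(en$algorithms)) {
    ev <- evaluate_pair(en$algorithms[[a]][[id]], en$reference[[id]])
    n10 <- sum(ev$groups$class == "1-0")
    n01 <- sum(ev$groups$class == "0-1")
    want10 <- sum(en$false_alarms$image_id == id &
                  en$false_alarms$algorithm == a)
    want01 <- sum(en$truth$image_id == id & en$truth$algorithm == a &
                  !en$truth$rendered)
    expect_identical(n10, want10)
    expect_identical(n01, want01)
  }
})

test_that("an infeasible packing raises a capacity error", {
  expect_error(generate_pair(pair_spec(grid_dim = c(10, 10, 10),
                                       counts = c("1-1" = 50),
                                       volume_range = c(50, 100),
                                       seed = 10)),
               "capacity")
})
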