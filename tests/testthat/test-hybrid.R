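# per-lesion data frame with a designed correct-detection profile
profile_rows <- function(n, profile, noise_sd = 0.05, seed = 1,
                         vrange = c(10, 250)) {
  set.seed(seed)
  v <- 10^runif(n, log10(vrange[1]), log10(vrange[2]))
  sdi <- pmin(0.99, pmax(0.01, profile(v) + rnorm(n, 0, noise_sd)))
  data.frame(ref_volume_mm3 = v, group_sdi = sdi, class = "1-1")
}

test_that("a uniformly dominant algorithm yields a single stratum", {
  reports <- list(
    good = profile_rows(120, function(v) rep(0.8, length(v)), seed = 1),
    poor = profile_rows(120, function(v) rep(0.4, length(v)), seed = 2))
  m <- learn_model(reports)
  expect_identical(length(m$assignments), 1L)
  expect_identical(m$assignments, "good")
  expect_identical(m$thresholds, c(0, Inf))
})

test_that("exact ties go to the lexicographically first algorithm", {
  rows <- profile_rows(80, function(v) rep(0.6, length(v)), noise_sd = 0,
                       seed = 3)
  m <- learn_model(list(zeta = rows, alpha = rows))
  expect_identical(m$assignments, "alpha")
})

test_that("a designed crossover is recovered near the true volume", {
  reports <- list(
    A1 = profile_rows(400, function(v) ifelse(v <= 50, 0.8, 0.4), seed = 4),
    A2 = profile_rows(400, function(v) ifelse(v <= 50, 0.4, 0.8), seed = 5))
  m <- learn_model(reports)
  expect_identical(length(m$assignments), 2L)
  expect_identical(m$assignments, c("A1", "A2"))
  t1 <- m$thresholds[2]
  expect_lt(abs(log10(t1) - log10(50)), 0.15)
  # consecutive strata never repeat an algorithm
  expect_true(all(diff(match(m$assignments,
                             unique(m$assignments))) != 0))
})

test_that("learned threshold converges toward the crossover as n grows", {
  err <- vapply(c(100, 400, 1600), function(n) {
    reports <- list(
      A1 = profile_rows(n, function(v) ifelse(v <= 50, 0.8, 0.4),
                        seed = 6),
      A2 = profile_rows(n, function(v) ifelse(v <= 50, 0.4, 0.8),
                        seed = 7))
    m <- learn_model(reports)
    abs(log10(m$thresholds[2]) - log10(50))
  }, numeric(1))
  expect_lt(err[3], err[1] + 0.05)
  expect_lt(err[3], 0.1)
})

test_that("algorithms without enough correct detections are excluded", {
  rows <- profile_rows(100, function(v) rep(0.7, length(v)), seed = 8)
  sparse <- rows[1:3, ]
  expect_warning(m <- learn_model(list(A = rows, B = sparse, C = rows)),
                 "excluded")
  expect_identical(m$provenance$excluded, "B")
  expect_error(suppressWarnings(
    learn_model(list(A = sparse, B = sparse))), "insufficient")
  expect_error(learn_model(list(A = rows)), "at least 2")
})

test_that("apply_model selects lesions by their own volume per stratum", {
  model <- structure(list(thresholds = c(0, 10, Inf),
                          assignments = c("A1", "A2"),
                          curves = list(), grid_log10_volumes = numeric(0),
                          provenance = list()), class = "hybrid_model")
  masks <- list(A1 = mask_with_volumes(c(5, 20)),
                A2 = mask_with_volumes(c(4, 30)))
  h <- apply_model(model, masks)
  os <- label_components(h)
  expect_setequal(os$objects$volume_mm3, c(5, 30))
  expect_identical(attr(h, "n_contributed"), 2L)
  expect_identical(attr(h, "n_merged"), 0L)
  # H is a subset of the union of candidate foregrounds
  expect_true(all(h$grid <= (masks$A1$grid | masks$A2$grid)))

  # a lesion of volume exactly t_i belongs to the lower stratum
  masks2 <- list(A1 = mask_with_volumes(10), A2 = mask_with_volumes(10))
  h2 <- apply_model(model, masks2)
  expect_identical(sum(h2$grid & masks2$A1$grid), 10L)

  # missing assigned algorithm is an error
  expect_error(apply_model(model, masks["A1"]), "missing")

  # single-stratum model returns the assigned algorithm's full mask
  m1 <- structure(list(thresholds = c(0, Inf), assignments = "A2",
                       curves = list(), grid_log10_volumes = numeric(0),
                       provenance = list()), class = "hybrid_model")
  expect_identical(apply_model(m1, masks)$grid, masks$A2$grid)

  # deterministic
  expect_identical(apply_model(model, masks)$grid, h$grid)
})

test_that("fold plans keep subjects together and cover everyone", {
  subs <- rep(sprintf("S%02d", 1:7), each = 3)
  fp <- make_folds(subs, 3)
  expect_identical(sort(unique(unname(fp))), 1:3)
  expect_identical(length(fp), 7L)
  expect_error(make_folds(c("a", "b"), 3), "fewer subjects")
  expect_identical(make_folds(subs, 3, seed = 5),
                   make_folds(subs, 3, seed = 5))
})

test_that("cross-validation with perfect candidates reproduces the reference", {
  es <- ensemble_spec(n_subjects = 4, timepoints = 2,
                      grid_dim = c(24, 24, 24), lesions_per_image = 3,
                      volume_range = c(10, 80), seed = 19)
  en <- generate_ensemble(es)
  perfect <- list(P1 = en$reference, P2 = en$reference)
  cv <- cross_validate(perfect, en$reference, en$image_subjects, folds = 2)
  expect_true(all(cv$sdi == 1))
  expect_identical(sort(names(cv$sdi)), sort(names(en$reference)))
})

test_that("fused segmentations beat both individuals on a crossover ensemble", {
  es <- ensemble_spec(n_subjects = 6, timepoints = 2,
                      grid_dim = c(28, 28, 28), lesions_per_image = 4,
                      seed = 23)
  en <- generate_ensemble(es)
  cv <- cross_validate(en$algorithms, en$reference, en$image_subjects,
                       folds = 2)
  expect_gte(mean(cv$sdi), max(colMeans(cv$per_algorithm_sdi)))
  # every fused component comes from some candidate
  union_fg <- en$algorithms$A1[[1]]$grid | en$algorithms$A2[[1]]$grid
  expect_true(all(cv$fused_masks[[1]]$grid <= union_fg))
})
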