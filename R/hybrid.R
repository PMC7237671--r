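# Hybrid fusion of candidate segmentations by lesion-volume stratum.
#
# The correct-detection (1-1) LOESS curves of the candidate algorithms
# are compared on a shared log10-volume grid; the algorithm with the
# highest smoothed SDI "owns" each grid point.  Runs of ownership define
# volume strata (t_{i-1}, t_i] and the fused segmentation H is the union,
# over strata, of the owning algorithm's own lesions whose volume falls
# in the stratum.

#' Learn a volume-stratified hybrid model
#'
#' Pools each algorithm's correct-detection (1-1) per-lesion rows, fits a
#' tricube LOESS curve of SDI on log10(volume) per algorithm (see
#' [sdi_trend()]), evaluates all curves on a 100-point grid over the
#' common volume support, and assigns every grid point to the curve with
#' the highest fitted SDI.  Stratum boundaries are the volume midpoints
#' (in log10) where the winning algorithm changes.  Exact ties go to the
#' lexicographically first algorithm name; runs of ownership narrower
#' than \code{min_run} grid points are absorbed into the wider neighbor
#' to suppress argmax chatter from noise.
#'
#' @param per_algorithm_reports named list: algorithm name -> either a
#'   list of [evaluate_pair()] results or a pooled per-lesion data frame
#'   (columns \code{ref_volume_mm3}, \code{group_sdi}, \code{class}).
#' @param span,degree LOESS parameters (see [sdi_trend()]).
#' @param n_grid grid size over the common support (default 100).
#' @param min_run minimum stratum width in grid points (default 3).
#' @return object of class \code{hybrid_model}: list with
#'   \code{thresholds} (ascending, \code{0 = t_0 < t_1 < ... < Inf}, in
#'   mm^3), \code{assignments} (one algorithm per stratum;
#'   consecutive strata never repeat an algorithm), the fitted
#'   \code{curves}, and \code{provenance} (parameters, n of 1-1 rows per
#'   algorithm, excluded algorithms).
#' @export
learn_model <- function(per_algorithm_reports, span = 0.75, degree = 2,
                        n_grid = 100L, min_run = 3L) {
  stopifnot(is.list(per_algorithm_reports),
            !is.null(names(per_algorithm_reports)))
  if (length(per_algorithm_reports) < 2L)
    stop("need at least 2 algorithms to learn a hybrid model",
         call. = FALSE)
  algs <- sort(names(per_algorithm_reports))   # lexicographic tie-break
  rows <- lapply(per_algorithm_reports[algs], pool_per_lesion)
  need <- max(degree + 2L, 5L)

  curves <- list()
  excluded <- character(0)
  for (a in algs) {
    cd <- rows[[a]][rows[[a]]$class == "1-1" & rows[[a]]$ref_volume_mm3 > 0, ]
    if (nrow(cd) < need) {
      warning("algorithm ", a, " excluded: only ", nrow(cd),
              " correct-detection lesion(s)", call. = FALSE)
      excluded <- c(excluded, a)
      next
    }
    curves[[a]] <- sdi_trend(cd$ref_volume_mm3, cd$group_sdi,
                             span = span, degree = degree)
  }
  if (!length(curves))
    stop("insufficient data: no algorithm has enough correct detections",
         call. = FALSE)

  lo <- max(vapply(curves, function(cu) min(cu$x), numeric(1)))
  hi <- min(vapply(curves, function(cu) max(cu$x), numeric(1)))
  if (!(lo < hi))
    stop("algorithms have no common lesion-volume support", call. = FALSE)
  gx <- seq(lo, hi, length.out = n_grid)

  fit <- vapply(curves, function(cu) predict(cu, 10^gx), numeric(n_grid))
  fit <- matrix(fit, nrow = n_grid,
                dimnames = list(NULL, names(curves)))
  win <- max.col(fit, ties.method = "first")   # columns already sorted

  # absorb ownership runs narrower than min_run into the wider neighbor
  r <- rle(win)
  while (length(r$lengths) > 1L && min(r$lengths) < min_run) {
    k <- which.min(r$lengths)
    nbr_len <- c(if (k > 1L) r$lengths[k - 1L] else -1L,
                 if (k < length(r$lengths)) r$lengths[k + 1L] else -1L)
    into <- if (nbr_len[1L] >= nbr_len[2L]) k - 1L else k + 1L
    r$values[k] <- r$values[into]
    r <- rle(inverse.rle(r))
  }
  win <- inverse.rle(r)
  r <- rle(win)

  ends <- cumsum(r$lengths)
  cuts <- ends[-length(ends)]
  thr_log10 <- (gx[cuts] + gx[cuts + 1L]) / 2
  thresholds <- c(0, 10^thr_log10, Inf)
  assignments <- names(curves)[r$values]

  structure(list(thresholds = thresholds, assignments = assignments,
                 curves = curves, grid_log10_volumes = gx,
                 provenance = list(span = span, degree = degree,
                                   n_grid = n_grid, min_run = min_run,
                                   algorithms = names(curves),
                                   excluded = excluded,
                                   n_rows = vapply(curves, function(cu)
                                     cu$n_points, integer(1)))),
            class = "hybrid_model")
}

# pool per-lesion rows from a lesion_eval, a list of them, or a data frame
#' Pool per-lesion rows from one or more evaluations
#'
#' @param reports a \code{lesion_eval}, a list of them, or a per-lesion
#'   data frame (passed through).
#' @return data frame of per-lesion rows.
#' @export
pool_per_lesion <- function(reports) {
  if (inherits(reports, "lesion_eval")) return(reports$per_lesion)
  if (is.data.frame(reports)) return(reports)
  do.call(rbind, lapply(reports, function(r)
    if (inherits(r, "lesion_eval")) r$per_lesion else r))
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat("Hybrid fusion model:", length(x$assignments), "volume strata\n")
  K <- length(x$assignments)
  lo <- x$thresholds[seq_len(K)]
  hi <- x$thresholds[seq_len(K) + 1L]
  for (i in seq_len(K))
    cat(sprintf("  (%s, %s] mm^3  ->  %s\n",
                format(signif(lo[i], 4)),
                if (is.finite(hi[i])) format(signif(hi[i], 4)) else "Inf",
                x$assignments[i]))
  cat("  LOESS span ", x$provenance$span, ", degree ",
      x$provenance$degree, "; ", x$provenance$n_grid,
      "-point grid\n", sep = "")
  invisible(x)
}

#' @export
plot.hybrid_model <- function(x, ...) {
  algs <- names(x$curves)
  cols <- grDevices::hcl.colors(max(3L, length(algs)), "Dark 3")
  gx <- x$grid_log10_volumes
  graphics::plot(NULL, xlim = range(gx), ylim = c(0, 1),
                 xlab = "log10 lesion volume (mm^3)",
                 ylab = "correct-detection SDI (LOESS)", ...)
  for (i in seq_along(algs)) {
    cu <- x$curves[[i]]
    graphics::lines(cu$grid_log10_volumes, cu$fitted_sdi, col = cols[i],
                    lwd = 2)
    graphics::polygon(c(cu$grid_log10_volumes, rev(cu$grid_log10_volumes)),
                      c(cu$band_low, rev(cu$band_high)),
                      col = grDevices::adjustcolor(cols[i], 0.15),
                      border = NA)
  }
  thr <- x$thresholds[is.finite(x$thresholds) & x$thresholds > 0]
  if (length(thr)) graphics::abline(v = log10(thr), lty = 2, col = "grey40")
  graphics::legend("bottomright", legend = algs, col = cols[seq_along(algs)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Fuse candidate segmentations with a hybrid model
#'
#' For each stratum \eqn{(t_{i-1}, t_i]}, the connected components of the
#' assigned algorithm's own mask whose own volume falls in the stratum
#' are selected; the fused segmentation is the voxel union of all
#' selected lesions.  A lesion of volume exactly \eqn{t_i} belongs to the
#' lower stratum (strata are closed on the right).  Components
#' contributed by different algorithms that happen to touch are left
#' merged in the output; the number of such merges is recorded in
#' \code{attr(, "n_merged")}.
#'
#' @param model a [learn_model()] result.
#' @param candidate_masks named list of comparable [binary_mask()]s,
#'   containing every algorithm the model assigns.
#' @param connectivity adjacency model for component extraction.
#' @return a [binary_mask()] (the fused segmentation) with attributes
#'   \code{n_contributed} (lesions selected across strata) and
#'   \code{n_merged} (touching cross-algorithm merges).
#' @export
apply_model <- function(model, candidate_masks, connectivity = NULL) {
  stopifnot(inherits(model, "hybrid_model"), is.list(candidate_masks))
  missing_algs <- setdiff(unique(model$assignments), names(candidate_masks))
  if (length(missing_algs))
    stop("candidate_masks is missing assigned algorithm(s): ",
         paste(missing_algs, collapse = ", "), call. = FALSE)
  nm <- names(candidate_masks)
  for (m in candidate_masks[-1L])
    assert_comparable(candidate_masks[[1L]], m)

  labeled <- list()
  tmpl <- candidate_masks[[1L]]
  fg <- array(FALSE, dim = dim(tmpl$grid))
  n_contributed <- 0L
  K <- length(model$assignments)
  for (i in seq_len(K)) {
    alg <- model$assignments[i]
    if (is.null(labeled[[alg]]))
      labeled[[alg]] <- label_components(candidate_masks[[alg]], connectivity)
    os <- labeled[[alg]]
    sel <- os$objects$object_id[os$objects$volume_mm3 > model$thresholds[i] &
                                os$objects$volume_mm3 <= model$thresholds[i + 1L]]
    if (length(sel)) {
      fg <- fg | array(os$labels %in% sel, dim = dim(fg))
      n_contributed <- n_contributed + length(sel)
    }
  }
  out <- binary_mask(fg, spacing = tmpl$spacing, space_tag = tmpl$space_tag,
                     source_id = "hybrid")
  n_final <- nrow(label_components(out, connectivity)$objects)
  attr(out, "n_contributed") <- n_contributed
  attr(out, "n_merged") <- n_contributed - n_final
  out
}

#' @export
predict.hybrid_model <- function(object, candidate_masks,
                                 connectivity = NULL, ...) {
  apply_model(object, candidate_masks, connectivity = connectivity)
}

#' Subject-level fold plan
#'
#' Assigns every subject to one fold (round-robin over the sorted subject
#' ids, or a seeded random permutation), so that all time-points of a
#' subject land in the same fold.
#'
#' @param subject_ids character vector of subject ids (duplicates
#'   allowed).
#' @param n_folds number of folds (>= 2).
#' @param seed optional integer; when given, subjects are permuted
#'   reproducibly before the round-robin assignment.
#' @return object of class \code{fold_plan}: named integer vector mapping
#'   subject id to fold index.
#' @export
make_folds <- function(subject_ids, n_folds = 2L, seed = NULL) {
  subs <- sort(unique(as.character(subject_ids)))
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  if (length(subs) < n_folds)
    stop("fewer subjects than folds", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    subs <- sample(subs)
  }
  folds <- rep_len(seq_len(n_folds), length(subs))
  structure(stats::setNames(folds, subs), class = "fold_plan")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cross-validated hybrid fusion
#'
#' For each fold, learns a hybrid model from the evaluations of the
#' training subjects' images and applies it to the held-out images; the
#' fused masks and their global SDI against the reference are pooled
#' across folds.
#'
#' @param per_algorithm_masks named list: algorithm -> named list of
#'   [binary_mask()]s keyed by image id.
#' @param reference_masks named list of reference [binary_mask()]s keyed
#'   by the same image ids.
#' @param image_subjects named character vector mapping image id to
#'   subject id.
#' @param folds a [make_folds()] plan over those subjects (or an integer
#'   number of folds, in which case a round-robin plan is built).
#' @param connectivity,span,degree,threshold_mm3 evaluation and smoothing
#'   parameters (see [evaluate_pair()], [learn_model()]).
#' @return object of class \code{hybrid_cv}: list with
#'   \code{fused_masks}, \code{sdi} (named per-image fused SDI),
#'   \code{per_algorithm_sdi} (image x algorithm matrix),
#'   \code{models} (one per fold), \code{fold_of_image}, \code{folds}.
#' @export
cross_validate <- function(per_algorithm_masks, reference_masks,
                           image_subjects, folds = 2L, connectivity = NULL,
                           span = 0.75, degree = 2, threshold_mm3 = 0) {
  algs <- names(per_algorithm_masks)
  imgs <- names(reference_masks)
  stopifnot(length(algs) >= 2L, length(imgs) >= 2L)
  for (a in algs)
    if (!setequal(names(per_algorithm_masks[[a]]), imgs))
      stop("image ids of algorithm ", a,
           " do not match the reference set", call. = FALSE)
  if (is.null(names(image_subjects)) ||
      !all(imgs %in% names(image_subjects)))
    stop("image_subjects must name a subject for every image",
         call. = FALSE)
  if (!inherits(folds, "fold_plan"))
    folds <- make_folds(image_subjects[imgs], n_folds = folds)
  fold_of_image <- unname(folds[as.character(image_subjects[imgs])])
  names(fold_of_image) <- imgs
  if (any(is.na(fold_of_image)))
    stop("fold plan does not cover all subjects", call. = FALSE)

  # evaluate every (algorithm, image) pair once, reuse across folds
  evals <- lapply(per_algorithm_masks, function(masks)
    lapply(imgs, function(id)
      evaluate_pair(masks[[id]], reference_masks[[id]],
                    connectivity = connectivity,
                    threshold_mm3 = threshold_mm3, image_id = id)))
  for (a in algs) names(evals[[a]]) <- imgs

  fused <- vector("list", length(imgs))
  names(fused) <- imgs
  models <- list()
  for (f in sort(unique(fold_of_image))) {
    train <- imgs[fold_of_image != f]
    test <- imgs[fold_of_image == f]
    if (!length(train))
      stop("fold ", f, " has no training subjects", call. = FALSE)
    reports <- lapply(evals, function(ev) pool_per_lesion(ev[train]))
    model <- learn_model(reports, span = span, degree = degree)
    models[[as.character(f)]] <- model
    for (id in test)
      fused[[id]] <- apply_model(
        model, lapply(per_algorithm_masks, `[[`, id),
        connectivity = connectivity)
  }

  sdi <- vapply(imgs, function(id)
    global_sdi(fused[[id]], reference_masks[[id]]), numeric(1))
  per_alg <- vapply(algs, function(a)
    vapply(imgs, function(id) evals[[a]][[id]]$global_sdi, numeric(1)),
    numeric(length(imgs)))
  per_alg <- matrix(per_alg, nrow = length(imgs),
                    dimnames = list(imgs, algs))

  structure(list(fused_masks = fused, sdi = sdi,
                 per_algorithm_sdi = per_alg, models = models,
                 fold_of_image = fold_of_image, folds = folds),
            class = "hybrid_cv")
}

#' @export
print.hybrid_cv <- function(x, ...) {
  cat("Cross-validated hybrid fusion over", length(x$sdi), "image(s),",
      length(x$models), "fold(s)\n")
  s <- summarize_sdi(x$sdi)
  cat(sprintf("  fused SDI: mean %.4f (SD %.4f), range [%.4f, %.4f]\n",
              s$mean, s$sd, s$min, s$max))
  for (a in colnames(x$per_algorithm_sdi)) {
    v <- x$per_algorithm_sdi[, a]
    cat(sprintf("  %-12s mean %.4f\n", paste0(a, ":"),
                mean(v, na.rm = TRUE)))
  }
  invisible(x)
}
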