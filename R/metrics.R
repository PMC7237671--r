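#' Global Sorensen-Dice index of two masks
#'
#' \deqn{SDI(A, B) = 2|A \cap B| / (|A| + |B|)}
#' computed on whole-mask voxel counts.  When both masks are empty the
#' index is undefined and \code{NA} is returned (a lesion-free pair
#' carries no overlap information; reporting 0 or 1 would bias cohort
#' means).
#'
#' @param a,b comparable [binary_mask()] objects.
#' @return a number in [0, 1], or \code{NA} if both masks are empty.
#' @export
global_sdi <- function(a, b) {
  assert_comparable(a, b)
  na <- sum(a$grid)
  nb <- sum(b$grid)
  if (na + nb == 0L) return(NA_real_)
  2 * sum(a$grid & b$grid) / (na + nb)
}

#' Lesion-wise evaluation of a segmentation pair
#'
#' The main entry point of the package.  Both masks are decomposed into
#' connected components, objects at or below the volume threshold are
#' removed, the remaining objects are matched through voxel overlap and
#' every match group is classified into the six-class detection taxonomy
#' and scored with its group Sorensen-Dice index (see [match_groups()]).
#'
#' @param a the algorithm (or second-listed rater) mask — side_a.
#' @param b the manual / reference mask — side_b.
#' @param connectivity adjacency model for component extraction
#'   (default 6 in 3D; see [label_components()]).
#' @param threshold_mm3 lesion volume threshold in mm^3 applied to both
#'   sides before matching; objects of exactly this volume are removed
#'   (default 0 = keep everything).
#' @param image_id identifier carried into per-lesion rows (defaults to
#'   the two masks' source ids).
#' @return an object of class \code{lesion_eval} with components
#'   \code{global_sdi} (on the thresholded masks; \code{NA} if both are
#'   empty), \code{groups} (the [match_groups()] table),
#'   \code{class_counts} (count and percentage of match groups per class
#'   code), \code{per_lesion} (one row per group: reference volume, group
#'   SDI, class, image id), the thresholded \code{object_set}s
#'   \code{objset_a}, \code{objset_b}, and the parameters used.
#' @examples
#' ref <- binary_mask(array(0, c(8, 8, 8)))
#' ref$grid[2:4, 2:4, 2:4] <- TRUE
#' seg <- ref
#' seg$grid[5, 2:4, 2:4] <- TRUE       # slightly larger rendition
#' ev <- evaluate_pair(seg, ref)
#' ev$global_sdi
#' ev$class_counts
#' @export
evaluate_pair <- function(a, b, connectivity = NULL, threshold_mm3 = 0,
                          image_id = NULL) {
  assert_comparable(a, b)
  oa <- suppress_small(label_components(a, connectivity), threshold_mm3)
  ob <- suppress_small(label_components(b, connectivity), threshold_mm3)
  graph <- build_overlap_graph(oa, ob)
  groups <- match_groups(graph)

  fa <- oa$labels > 0L
  fb <- ob$labels > 0L
  gsdi <- if (sum(fa) + sum(fb) == 0L) NA_real_ else
    2 * sum(fa & fb) / (sum(fa) + sum(fb))

  counts <- table(factor(groups$class, levels = .class_codes))
  class_counts <- data.frame(class = .class_codes,
                             count = as.integer(counts),
                             percentage = if (nrow(groups))
                               100 * as.integer(counts) / nrow(groups)
                             else rep(0, length(.class_codes)))

  if (is.null(image_id))
    image_id <- paste(a$source_id, b$source_id, sep = "-vs-")
  per_lesion <- data.frame(ref_volume_mm3 = groups$ref_volume_mm3,
                           group_sdi = groups$group_sdi,
                           class = groups$class,
                           image_id = rep(image_id, nrow(groups)),
                           stringsAsFactors = FALSE)

  structure(list(global_sdi = gsdi, groups = groups,
                 class_counts = class_counts, per_lesion = per_lesion,
                 objset_a = oa, objset_b = ob,
                 connectivity = oa$connectivity,
                 threshold_mm3 = threshold_mm3, image_id = image_id),
            class = "lesion_eval")
}

#' @export
print.lesion_eval <- function(x, ...) {
  cat("Lesion-wise segmentation evaluation (", x$image_id, ")\n", sep = "")
  cat("  connectivity: ", x$connectivity,
      "   volume threshold: ", x$threshold_mm3, " mm^3\n", sep = "")
  cat("  global SDI: ",
      if (is.na(x$global_sdi)) "undefined (both masks empty)"
      else format(round(x$global_sdi, 4)), "\n", sep = "")
  cat("  match groups: ", nrow(x$groups), "\n", sep = "")
  invisible(x)
}

#' @export
summary.lesion_eval <- function(object, ...) {
  structure(list(eval = object), class = "summary.lesion_eval")
}

#' @export
print.summary.lesion_eval <- function(x, ...) {
  ev <- x$eval
  print(ev)
  cc <- ev$class_counts
  cc$percentage <- round(cc$percentage, 2)
  cat("\nDetection classes (groups = lesion events):\n")
  print(cc, row.names = FALSE)
  ones <- ev$per_lesion[ev$per_lesion$class == "1-1", ]
  if (nrow(ones))
    cat("\nCorrect-detection (1-1) group SDI: mean ",
        format(round(mean(ones$group_sdi), 4)), " over ", nrow(ones),
        " lesion(s)\n", sep = "")
  invisible(x)
}

#' Per-lesion scatter of a lesion evaluation
#'
#' Plots group SDI against reference lesion volume (log10 axis), color
#' coded by detection class, optionally with LOESS trend curves per class.
#'
#' @param x a \code{lesion_eval}.
#' @param trends add per-class trend curves where enough lesions exist?
#' @param span,degree smoothing parameters passed to [sdi_trend()].
#' @param ... further arguments passed to \code{plot}.
#' @return invisibly \code{x}.
#' @export
plot.lesion_eval <- function(x, trends = TRUE, span = 0.75, degree = 2, ...) {
  pl <- x$per_lesion[x$per_lesion$ref_volume_mm3 > 0, ]
  if (!nrow(pl)) {
    warning("nothing to plot: no match groups")
    return(invisible(x))
  }
  cls <- sort(unique(pl$class))
  cols <- grDevices::hcl.colors(max(3L, length(cls)), "Dark 3")[seq_along(cls)]
  graphics::plot(log10(pl$ref_volume_mm3), pl$group_sdi,
                 col = cols[match(pl$class, cls)], pch = 16, ylim = c(0, 1),
                 xlab = "log10 lesion volume (mm^3)", ylab = "per-lesion SDI",
                 ...)
  if (trends) {
    tr <- try(class_trends(x, classes = cls, span = span, degree = degree),
              silent = TRUE)
    if (!inherits(tr, "try-error"))
      for (cu in tr)
        graphics::lines(cu$grid_log10_volumes, cu$fitted_sdi,
                        col = cols[match(cu$class, cls)], lwd = 2)
  }
  graphics::legend("bottomright", legend = cls, col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Volume-threshold sensitivity sweep
#'
#' Re-evaluates a mask pair at each lesion volume threshold.  Each
#' evaluation re-thresholds the original masks (thresholds are not
#' cumulative), reproducing the threshold analysis used to study how
#' small-lesion suppression changes agreement.
#'
#' @param a,b comparable [binary_mask()] objects (see [evaluate_pair()]).
#' @param thresholds ascending numeric vector of thresholds in mm^3;
#'   0 corresponds to the original data.
#' @param connectivity adjacency model (see [label_components()]).
#' @return an object of class \code{threshold_sweep}: a data frame with
#'   one row per threshold (\code{threshold_mm3}, \code{global_sdi},
#'   \code{n_groups}, one count column per class code), with the full
#'   \code{lesion_eval} objects in \code{attr(, "reports")}.
#' @export
threshold_sweep <- function(a, b, thresholds, connectivity = NULL) {
  thresholds <- as.numeric(thresholds)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending", call. = FALSE)
  reports <- lapply(thresholds, function(t)
    evaluate_pair(a, b, connectivity = connectivity, threshold_mm3 = t))
  counts <- t(vapply(reports, function(r) r$class_counts$count,
                     integer(length(.class_codes))))
  colnames(counts) <- paste0("n_", gsub("-", "_", .class_codes))
  out <- data.frame(threshold_mm3 = thresholds,
                    global_sdi = vapply(reports, `[[`, numeric(1),
                                        "global_sdi"),
                    n_groups = vapply(reports, function(r) nrow(r$groups),
                                      integer(1)))
  out <- cbind(out, counts)
  attr(out, "reports") <- reports
  class(out) <- c("threshold_sweep", "data.frame")
  out
}

#' Summarize per-image SDI values
#'
#' Mean, sample standard deviation, range and normal-approximation
#' confidence interval of a collection of per-image SDI values, as used
#' for cohort-level reporting.  Undefined values (\code{NA}, from
#' lesion-free pairs) are excluded and counted.
#'
#' @param values numeric vector of SDI values, possibly with \code{NA}s.
#' @param level confidence level for the interval (default 0.95, i.e.
#'   mean +/- 1.96 SD / sqrt(n)).
#' @return object of class \code{sdi_summary}: list with \code{mean},
#'   \code{sd}, \code{min}, \code{max}, \code{ci} (length-2), \code{n},
#'   \code{n_excluded}, \code{level}.
#' @export
summarize_sdi <- function(values, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  n_excluded <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) < 2L)
    stop("need at least 2 defined SDI values to summarize", call. = FALSE)
  m <- mean(v)
  s <- stats::sd(v)
  z <- stats::qnorm((1 + level) / 2)
  structure(list(mean = m, sd = s, min = min(v), max = max(v),
                 ci = c(m - z * s / sqrt(length(v)),
                        m + z * s / sqrt(length(v))),
                 n = length(v), n_excluded = n_excluded, level = level),
            class = "sdi_summary")
}

#' @export
print.sdi_summary <- function(x, ...) {
  cat("SDI over ", x$n, " image(s)",
      if (x$n_excluded) paste0(" (", x$n_excluded,
                               " undefined value(s) excluded)"),
      ":\n", sep = "")
  cat(sprintf("  mean %.4f (SD %.4f), range [%.4f, %.4f]\n",
              x$mean, x$sd, x$min, x$max))
  cat(sprintf("  %d%% CI of the mean: [%.4f, %.4f]\n",
              round(100 * x$level), x$ci[1], x$ci[2]))
  invisible(x)
}
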