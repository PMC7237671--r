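# End-to-end workflows: single-pair evaluation and cohort analysis.
# These drive the package's two standard studies (rater-vs-rater /
# algorithm-vs-reference evaluation, and multi-algorithm cohort analysis
# with heat maps and hybrid fusion) and write plain-text reports; the
# exec/lesionqc script dispatches to them.

.as_mask <- function(x, space_tag = "unspecified") {
  if (inherits(x, "binary_mask")) x else read_mask(x, space_tag = space_tag)
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

.flatten_groups <- function(groups) {
  out <- groups[, c("group_id", "class", "M", "N", "overlap_voxels",
                    "group_sdi", "ref_volume_mm3")]
  out$a_members <- vapply(groups$a_members, paste, "", collapse = ";")
  out$b_members <- vapply(groups$b_members, paste, "", collapse = ";")
  out
}

#' Evaluate one segmentation against a reference and write reports
#'
#' Runs [evaluate_pair()] and writes the match-group table, per-lesion
#' rows, class counts, per-class trend curves and a JSON summary into
#' \code{out_dir}, plus a per-lesion scatter figure.
#'
#' @param seg,ref [binary_mask()]s or NIfTI paths (segmentation under
#'   test and reference).
#' @param out_dir output directory (created if needed).
#' @param connectivity,threshold_mm3 see [evaluate_pair()].
#' @param span,degree trend parameters, see [sdi_trend()].
#' @param space_tag template-space tag used when reading from paths.
#' @return the \code{lesion_eval}, invisibly.
#' @export
run_evaluate <- function(seg, ref, out_dir, connectivity = NULL,
                         threshold_mm3 = 0, span = 0.75, degree = 2,
                         space_tag = "unspecified") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seg <- .as_mask(seg, space_tag)
  ref <- .as_mask(ref, space_tag)
  ev <- evaluate_pair(seg, ref, connectivity = connectivity,
                      threshold_mm3 = threshold_mm3)

  utils::write.csv(.flatten_groups(ev$groups),
                   file.path(out_dir, "groups.csv"), row.names = FALSE)
  utils::write.csv(ev$per_lesion, file.path(out_dir, "per_lesion.csv"),
                   row.names = FALSE)
  utils::write.csv(ev$class_counts, file.path(out_dir, "class_counts.csv"),
                   row.names = FALSE)

  trends <- suppressWarnings(class_trends(ev, span = span, degree = degree))
  if (length(trends)) {
    tl <- do.call(rbind, lapply(trends, function(cu)
      data.frame(class = cu$class, volume_mm3 = cu$grid_volumes,
                 fitted_sdi = cu$fitted_sdi, band_low = cu$band_low,
                 band_high = cu$band_high)))
    utils::write.csv(tl, file.path(out_dir, "trend_curves.csv"),
                     row.names = FALSE)
  }

  grDevices::png(file.path(out_dir, "per_lesion_sdi.png"),
                 width = 800, height = 600)
  try(suppressWarnings(plot(ev, span = span, degree = degree)),
      silent = TRUE)
  grDevices::dev.off()

  .write_json(list(
    global_sdi = ev$global_sdi, n_groups = nrow(ev$groups),
    connectivity = ev$connectivity, threshold_mm3 = threshold_mm3,
    span = span, degree = degree,
    package_version = as.character(utils::packageVersion("lesionqc")),
    r_version = R.version.string),
    file.path(out_dir, "summary.json"))
  invisible(ev)
}

.read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest))
      stop("manifest not found: ", manifest, call. = FALSE)
    sep <- if (grepl(",", readLines(manifest, n = 1L))) "," else ""
    manifest <- utils::read.csv(manifest, sep = sep, stringsAsFactors = FALSE,
                                strip.white = TRUE)
  }
  req <- c("image_id", "subject_id", "source_id", "path")
  if (!all(req %in% names(manifest)))
    stop("manifest must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!nrow(manifest))
    stop("insufficient data: manifest is empty", call. = FALSE)
  manifest
}

#' Cohort analysis: per-image reports, heat maps and hybrid fusion
#'
#' Evaluates every non-reference source in the manifest against the
#' reference source on every image, writes pooled per-lesion tables,
#' cohort SDI summaries with pairwise Wilcoxon comparisons, per-class
#' heat maps with axial MIPs, and (when at least two candidate sources
#' and \code{hybrid_folds} are given) cross-validated hybrid fusion
#' results.
#'
#' @param manifest data frame or path to a whitespace/comma-delimited
#'   file with columns \code{image_id}, \code{subject_id},
#'   \code{source_id}, \code{path}.  The rows whose source equals
#'   \code{reference_source} define the reference masks.
#' @param out_dir output directory.
#' @param reference_source source_id of the reference (default
#'   \code{"reference"}).
#' @param connectivity,threshold_mm3,span,degree analysis parameters.
#' @param heat_threshold display threshold for heat maps (default 0.15).
#' @param hybrid_folds fold count(s) for hybrid cross-validation, e.g.
#'   \code{c(2, 3)}; \code{NULL} skips fusion.
#' @param alpha significance level quoted in the comparison table.
#' @param space_tag template-space tag for masks read from disk.
#' @return invisibly, a list with per-source evaluations, SDI summaries,
#'   heat maps and hybrid results.
#' @export
run_cohort <- function(manifest, out_dir, reference_source = "reference",
                       connectivity = NULL, threshold_mm3 = 0,
                       span = 0.75, degree = 2, heat_threshold = 0.15,
                       hybrid_folds = NULL, alpha = 0.01,
                       space_tag = "unspecified") {
  manifest <- .read_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing))
    stop("manifest entry file(s) not found: ",
         paste(missing, collapse = ", "), call. = FALSE)

  refs_tab <- manifest[manifest$source_id == reference_source, ]
  if (!nrow(refs_tab))
    stop("no rows with reference source '", reference_source, "'",
         call. = FALSE)
  imgs <- sort(unique(refs_tab$image_id))
  reference <- lapply(stats::setNames(imgs, imgs), function(id)
    read_mask(refs_tab$path[refs_tab$image_id == id][1L], space_tag,
              source_id = reference_source))
  image_subjects <- stats::setNames(
    refs_tab$subject_id[match(imgs, refs_tab$image_id)], imgs)

  sources <- setdiff(sort(unique(manifest$source_id)), reference_source)
  if (!length(sources))
    stop("insufficient data: no candidate sources in manifest",
         call. = FALSE)

  evals <- list()
  masks <- list()
  for (src in sources) {
    tab <- manifest[manifest$source_id == src, ]
    if (!setequal(tab$image_id, imgs))
      stop("source ", src, " does not cover the reference image set",
           call. = FALSE)
    masks[[src]] <- lapply(stats::setNames(imgs, imgs), function(id)
      read_mask(tab$path[tab$image_id == id][1L], space_tag,
                source_id = src))
    evals[[src]] <- lapply(imgs, function(id)
      evaluate_pair(masks[[src]][[id]], reference[[id]],
                    connectivity = connectivity,
                    threshold_mm3 = threshold_mm3, image_id = id))
    names(evals[[src]]) <- imgs
    utils::write.csv(pool_per_lesion(evals[[src]]),
                     file.path(out_dir, paste0("per_lesion_", src, ".csv")),
                     row.names = FALSE)
  }

  sdi_by_source <- lapply(evals, function(ev)
    vapply(ev, `[[`, numeric(1), "global_sdi"))
  summaries <- lapply(sdi_by_source, function(v)
    if (sum(!is.na(v)) >= 2L) unclass(summarize_sdi(v)) else NULL)
  comparisons <- if (length(sources) >= 2L) compare_sdi(sdi_by_source)
                 else NULL
  if (!is.null(comparisons))
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)

  heat_maps <- list()
  for (src in sources) {
    heat_maps[[src]] <- list()
    for (cl in .class_codes) {
      cms <- lapply(evals[[src]], class_voxel_mask, class_code = cl)
      hm <- display_threshold(heat_map(cms, class_code = cl),
                              heat_threshold)
      heat_maps[[src]][[cl]] <- hm
      if (any(hm$grid > 0)) {
        base <- file.path(out_dir, paste0("heatmap_", src, "_",
                                          gsub("-", "_", cl)))
        write_heat_map(hm, paste0(base, ".nii.gz"))
        grDevices::png(paste0(base, "_mip.png"), width = 480, height = 480)
        graphics::image(axial_mip(hm), col = grDevices::hcl.colors(64),
                        axes = FALSE, main = paste(src, cl, "axial MIP"))
        grDevices::dev.off()
      }
    }
  }

  hybrid <- list()
  if (!is.null(hybrid_folds) && length(sources) >= 2L) {
    for (nf in hybrid_folds) {
      cv <- cross_validate(masks, reference, image_subjects, folds = nf,
                           connectivity = connectivity, span = span,
                           degree = degree, threshold_mm3 = threshold_mm3)
      hybrid[[paste0("folds_", nf)]] <- cv
      utils::write.csv(
        data.frame(image_id = names(cv$sdi), fused_sdi = cv$sdi,
                   cv$per_algorithm_sdi, check.names = FALSE),
        file.path(out_dir, paste0("hybrid_", nf, "fold_sdi.csv")),
        row.names = FALSE)
    }
  }

  .write_json(list(
    images = length(imgs), sources = sources,
    connectivity = if (is.null(connectivity)) 6L else connectivity,
    threshold_mm3 = threshold_mm3, span = span, degree = degree,
    heat_threshold = heat_threshold, alpha = alpha,
    sdi_summaries = summaries,
    hybrid_mean_sdi = lapply(hybrid, function(cv) mean(cv$sdi, na.rm = TRUE)),
    package_version = as.character(utils::packageVersion("lesionqc")),
    r_version = R.version.string),
    file.path(out_dir, "cohort_summary.json"))

  invisible(list(evals = evals, sdi = sdi_by_source, summaries = summaries,
                 comparisons = comparisons, heat_maps = heat_maps,
                 hybrid = hybrid))
}

#' Write a synthetic pair or ensemble to disk
#'
#' Materializes generated masks as NIfTI files plus the ground-truth
#' tables (and, for ensembles, a cohort manifest usable with
#' [run_cohort()]) as delimited text.
#'
#' @param x a \code{synthetic_pair} or \code{synthetic_ensemble}.
#' @param out_dir output directory.
#' @return the manifest path (ensembles) or \code{out_dir} (pairs),
#'   invisibly.
#' @export
write_synthetic <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "synthetic_pair")) {
    write_mask(x$side_a, file.path(out_dir, "side_a.nii.gz"))
    write_mask(x$side_b, file.path(out_dir, "side_b.nii.gz"))
    utils::write.csv(x$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    return(invisible(out_dir))
  }
  stopifnot(inherits(x, "synthetic_ensemble"))
  rows <- list()
  for (id in names(x$reference)) {
    p <- file.path(out_dir, paste0("ref_", id, ".nii.gz"))
    write_mask(x$reference[[id]], p)
    rows[[length(rows) + 1L]] <- data.frame(
      image_id = id, subject_id = x$image_subjects[[id]],
      source_id = "reference", path = p)
  }
  for (a in names(x$algorithms))
    for (id in names(x$algorithms[[a]])) {
      p <- file.path(out_dir, paste0(a, "_", id, ".nii.gz"))
      write_mask(x$algorithms[[a]][[id]], p)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, subject_id = x$image_subjects[[id]],
        source_id = a, path = p)
    }
  manifest <- do.call(rbind, rows)
  mp <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(mp)
}
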