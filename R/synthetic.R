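# Synthetic masks and ensembles with known ground truth.
#
# Objects are axis-aligned boxes: their volume, overlap and adjacency are
# exactly controllable, which is what the test oracles need (morphological
# realism is a non-goal).  Groups of different detection classes are
# placed with at least 2 empty voxels between them so no unintended
# adjacency or overlap can arise under any connectivity model.  A 1-1
# pair with target SDI p is rendered by keeping the first
# o = round(p V / (2 - p)) voxels (scan order) of the reference box, so
# the realized SDI 2o/(V + o) matches the target to within 1/V.
#
# Split (M-1), merge (1-N) and split-merge (M-N) groups carve one box
# into separated sub-boxes on one side (1-voxel gaps keep the pieces
# 6-disconnected while every piece still overlaps the other side).

.box_dims <- function(V) {
  dx <- max(1L, as.integer(round(V^(1 / 3))))
  dy <- max(1L, as.integer(round(sqrt(V / dx))))
  dz <- max(1L, as.integer(round(V / (dx * dy))))
  c(dx, dy, dz)
}

# all voxel coordinates of a box, column-major scan order
.box_coords <- function(d) {
  as.matrix(expand.grid(x = seq_len(d[1L]), y = seq_len(d[2L]),
                        z = seq_len(d[3L]), KEEP.OUT.ATTRS = FALSE))
}

# split the x-extent (or axis `axis`) into n sub-ranges with 1-voxel gaps
.carve <- function(extent, n) {
  avail <- extent - (n - 1L)
  lens <- rep(avail %/% n, n)
  if (avail %% n) lens[seq_len(avail %% n)] <- lens[seq_len(avail %% n)] + 1L
  starts <- cumsum(c(1L, lens[-n] + 1L))
  Map(function(s, l) seq.int(s, s + l - 1L), starts, lens)
}

.subset_prefix <- function(p, V) max(1L, min(V, as.integer(round(p * V / (2 - p)))))

# one match group in bbox-local coordinates
.make_group <- function(class, V, p, mult) {
  switch(class,
    "1-1" = {
      d <- .box_dims(V)
      cb <- .box_coords(d)
      o <- .subset_prefix(p, nrow(cb))
      list(a = list(cb[seq_len(o), , drop = FALSE]), b = list(cb), bbox = d,
           target_sdi = p, realized_sdi = 2 * o / (nrow(cb) + o))
    },
    "0-1" = {
      d <- .box_dims(V)
      list(a = list(), b = list(.box_coords(d)), bbox = d,
           target_sdi = 0, realized_sdi = 0)
    },
    "1-0" = {
      d <- .box_dims(V)
      list(a = list(.box_coords(d)), b = list(), bbox = d,
           target_sdi = 0, realized_sdi = 0)
    },
    "1-N" = ,
    "M-1" = {
      d <- .box_dims(V)
      d[1L] <- max(d[1L], 2L * mult - 1L)
      full <- .box_coords(d)
      parts <- lapply(.carve(d[1L], mult), function(xs)
        full[full[, 1L] %in% xs, , drop = FALSE])
      if (class == "1-N")
        list(a = list(full), b = parts, bbox = d,
             target_sdi = NA_real_, realized_sdi = NA_real_)
      else
        list(a = parts, b = list(full), bbox = d,
             target_sdi = NA_real_, realized_sdi = NA_real_)
    },
    "M-N" = {
      d <- .box_dims(V)
      d[1L] <- max(d[1L], 2L * mult - 1L)
      d[2L] <- max(d[2L], 2L * mult - 1L)
      full <- .box_coords(d)
      a <- lapply(.carve(d[1L], mult), function(xs)
        full[full[, 1L] %in% xs, , drop = FALSE])
      b <- lapply(.carve(d[2L], mult), function(ys)
        full[full[, 2L] %in% ys, , drop = FALSE])
      list(a = a, b = b, bbox = d,
           target_sdi = NA_real_, realized_sdi = NA_real_)
    },
    stop("unknown class: ", class, call. = FALSE))
}

# place a bbox at a random free origin, keeping >= 2 empty voxels to any
# previously claimed region; marks the claim and returns the origin
.place_bbox <- function(claimed, bbox, margin = 2L, tries = 200L) {
  gd <- dim(claimed)
  if (any(bbox > gd)) return(NULL)
  for (t in seq_len(tries)) {
    origin <- vapply(seq_len(3L), function(i)
      sample.int(gd[i] - bbox[i] + 1L, 1L), integer(1))
    lo <- pmax(1L, origin - margin)
    hi <- pmin(gd, origin + bbox - 1L + margin)
    if (!any(claimed[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]]))
      return(origin)
  }
  NULL
}

.claim <- function(claimed, origin, bbox) {
  claimed[origin[1L]:(origin[1L] + bbox[1L] - 1L),
          origin[2L]:(origin[2L] + bbox[2L] - 1L),
          origin[3L]:(origin[3L] + bbox[3L] - 1L)] <- TRUE
  claimed
}

.rlogunif <- function(n, range) 10^stats::runif(n, log10(range[1L]), log10(range[2L]))

#' Specification of a synthetic segmentation pair
#'
#' Describes a pair of masks with a designed detection-class composition,
#' emulating an inter-rater or algorithm-vs-reference comparison.
#'
#' @param grid_dim 3D grid shape (default 48^3).
#' @param spacing voxel spacing in mm (default 1 mm isotropic, the
#'   common-template resolution the package targets).
#' @param counts named integer vector of match groups to generate per
#'   class code.  The default composition is dominated by correct
#'   detections, with a few splits/merges and disagreement lesions on
#'   both sides and split-merge rare, mirroring what inter-rater lesion
#'   comparisons typically show.
#' @param volume_range lesion volumes are drawn log-uniformly from this
#'   range in mm^3 (default 2--200).
#' @param target_sdi target group SDI for 1-1 pairs (default 0.65, the
#'   level typical of expert agreement on lesion boundaries).
#' @param multiplicity range of split/merge multiplicities M (default
#'   2--3).
#' @param seed integer seed; the generated pair is a deterministic
#'   function of the spec.
#' @return object of class \code{pair_spec}.
#' @export
pair_spec <- function(grid_dim = c(48L, 48L, 48L), spacing = c(1, 1, 1),
                      counts = c("1-1" = 4L, "1-N" = 1L, "M-1" = 1L,
                                 "M-N" = 1L, "0-1" = 2L, "1-0" = 2L),
                      volume_range = c(2, 200), target_sdi = 0.65,
                      multiplicity = c(2L, 3L), seed = 1L) {
  full <- stats::setNames(integer(length(.class_codes)), .class_codes)
  bad <- setdiff(names(counts), .class_codes)
  if (length(bad))
    stop("unknown class code(s) in counts: ", paste(bad, collapse = ", "),
         call. = FALSE)
  full[names(counts)] <- as.integer(counts)
  structure(list(grid_dim = as.integer(grid_dim), spacing = spacing,
                 counts = full, volume_range = volume_range,
                 target_sdi = target_sdi,
                 multiplicity = as.integer(multiplicity),
                 seed = as.integer(seed)),
            class = "pair_spec")
}

#' Generate a synthetic segmentation pair with known taxonomy
#'
#' Places one box-shaped match group per requested class instance (see
#' [pair_spec()]), with at least 2 empty voxels between groups, and
#' records the realized composition as ground truth.
#'
#' @param spec a [pair_spec()].
#' @return object of class \code{synthetic_pair}: list with
#'   \code{side_a}, \code{side_b} ([binary_mask()]s), and \code{truth},
#'   a data frame with one row per generated group (\code{class},
#'   \code{M}, \code{N}, \code{target_sdi}, \code{realized_sdi},
#'   \code{a_volume_mm3}, \code{b_volume_mm3}).
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "pair_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  gd <- spec$grid_dim
  vv <- prod(spec$spacing)
  a_grid <- array(FALSE, dim = gd)
  b_grid <- array(FALSE, dim = gd)
  claimed <- array(FALSE, dim = gd)
  truth <- list()

  for (cl in .class_codes) {
    for (k in seq_len(spec$counts[[cl]])) {
      v <- .rlogunif(1L, spec$volume_range)
      V <- max(1L, as.integer(round(v / vv)))
      mrange <- seq.int(spec$multiplicity[1L],
                        spec$multiplicity[length(spec$multiplicity)])
      mult <- if (length(mrange) == 1L) mrange else sample(mrange, 1L)
      grp <- .make_group(cl, V, spec$target_sdi, mult)
      origin <- .place_bbox(claimed, grp$bbox)
      if (is.null(origin))
        stop("capacity error: could not place a ", cl,
             " group of ~", V, " voxels on the grid", call. = FALSE)
      claimed <- .claim(claimed, origin, grp$bbox)
      for (co in grp$a)
        a_grid[co + matrix(origin - 1L, nrow(co), 3L, byrow = TRUE)] <- TRUE
      for (co in grp$b)
        b_grid[co + matrix(origin - 1L, nrow(co), 3L, byrow = TRUE)] <- TRUE
      truth[[length(truth) + 1L]] <- data.frame(
        class = cl, M = length(grp$a), N = length(grp$b),
        target_sdi = grp$target_sdi, realized_sdi = grp$realized_sdi,
        a_volume_mm3 = sum(vapply(grp$a, nrow, integer(1))) * vv,
        b_volume_mm3 = sum(vapply(grp$b, nrow, integer(1))) * vv,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(class = character(0), M = integer(0), N = integer(0),
               target_sdi = numeric(0), realized_sdi = numeric(0),
               a_volume_mm3 = numeric(0), b_volume_mm3 = numeric(0))
  structure(list(
    side_a = binary_mask(a_grid, spacing = spec$spacing,
                         space_tag = "synthetic", source_id = "side_a"),
    side_b = binary_mask(b_grid, spacing = spec$spacing,
                         space_tag = "synthetic", source_id = "side_b"),
    truth = truth, spec = spec),
    class = "synthetic_pair")
}

#' Specification of a synthetic segmentation ensemble
#'
#' Describes a cohort of reference segmentations plus several candidate
#' algorithms whose per-lesion SDI tracks a designed volume profile, for
#' exercising trend fitting and hybrid fusion end to end.  The default
#' ensemble is the two-algorithm crossover design: volumes log-uniform
#' on 10--250 mm^3, algorithm A1 renders lesions at mean SDI 0.8 up to
#' 50 mm^3 and 0.4 above, A2 the reverse, with Gaussian SDI noise of
#' SD 0.05; 20 subjects with 4 time-points and 5 lesions per image give
#' 400 lesions in total.
#'
#' @param n_subjects,timepoints cohort layout (default 20 x 4).
#' @param grid_dim,spacing image grid (default 32^3 at 1 mm isotropic).
#' @param lesions_per_image reference lesions per image (default 5).
#' @param volume_range log-uniform lesion volume range in mm^3.
#' @param profiles named list of functions volume (mm^3) -> mean SDI in
#'   (0, 1), one per algorithm.
#' @param noise_sd SD of the Gaussian noise added to the profile SDI.
#' @param false_alarm_rate expected number of false-alarm lesions per
#'   image per algorithm (Poisson; default 0).
#' @param detection_failure_rate probability an algorithm misses a
#'   reference lesion entirely (default 0).
#' @param seed integer seed.
#' @return object of class \code{ensemble_spec}.
#' @export
ensemble_spec <- function(n_subjects = 20L, timepoints = 4L,
                          grid_dim = c(32L, 32L, 32L), spacing = c(1, 1, 1),
                          lesions_per_image = 5L, volume_range = c(10, 250),
                          profiles = list(
                            A1 = function(v) ifelse(v <= 50, 0.8, 0.4),
                            A2 = function(v) ifelse(v <= 50, 0.4, 0.8)),
                          noise_sd = 0.05, false_alarm_rate = 0,
                          detection_failure_rate = 0, seed = 1L) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            !is.null(names(profiles)))
  structure(list(n_subjects = as.integer(n_subjects),
                 timepoints = as.integer(timepoints),
                 grid_dim = as.integer(grid_dim), spacing = spacing,
                 lesions_per_image = as.integer(lesions_per_image),
                 volume_range = volume_range, profiles = profiles,
                 noise_sd = noise_sd, false_alarm_rate = false_alarm_rate,
                 detection_failure_rate = detection_failure_rate,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate a synthetic ensemble with designed SDI-volume profiles
#'
#' For every image, reference lesions are placed as separated boxes; each
#' algorithm's rendition of a lesion keeps a scan-order subset of the
#' reference voxels calibrated so the realized SDI matches the
#' algorithm's profile at that lesion volume (plus noise).  False alarms
#' and detection failures are injected at the specified rates.
#'
#' @param spec an [ensemble_spec()].
#' @return object of class \code{synthetic_ensemble}: list with
#'   \code{reference} (named list of masks by image id),
#'   \code{algorithms} (algorithm -> named list of masks),
#'   \code{image_subjects} (named vector image id -> subject id),
#'   \code{truth} (one row per lesion per algorithm: target and realized
#'   SDI, rendered flag), \code{false_alarms}.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  gd <- spec$grid_dim
  vv <- prod(spec$spacing)
  algs <- names(spec$profiles)
  reference <- list()
  algorithms <- stats::setNames(
    replicate(length(algs), list(), simplify = FALSE), algs)
  image_subjects <- character(0)
  truth <- list()
  fas <- list()

  for (s in seq_len(spec$n_subjects)) {
    subject <- sprintf("S%02d", s)
    for (tp in seq_len(spec$timepoints)) {
      image_id <- sprintf("%s_T%d", subject, tp)
      claimed <- array(FALSE, dim = gd)
      ref_grid <- array(FALSE, dim = gd)
      alg_grids <- lapply(algs, function(a) array(FALSE, dim = gd))
      names(alg_grids) <- algs

      for (li in seq_len(spec$lesions_per_image)) {
        v <- .rlogunif(1L, spec$volume_range)
        V <- max(1L, as.integer(round(v / vv)))
        d <- .box_dims(V)
        origin <- .place_bbox(claimed, d)
        if (is.null(origin))
          stop("capacity error: could not place lesion ", li, " of image ",
               image_id, call. = FALSE)
        claimed <- .claim(claimed, origin, d)
        cb <- .box_coords(d)
        gl <- cb + matrix(origin - 1L, nrow(cb), 3L, byrow = TRUE)
        ref_grid[gl] <- TRUE
        Vb <- nrow(cb)
        vol <- Vb * vv

        for (a in algs) {
          rendered <- stats::runif(1L) >= spec$detection_failure_rate
          if (rendered) {
            p <- spec$profiles[[a]](vol) + stats::rnorm(1L, 0, spec$noise_sd)
            p <- min(1, max(0.02, p))
            o <- .subset_prefix(p, Vb)
            alg_grids[[a]][gl[seq_len(o), , drop = FALSE]] <- TRUE
            realized <- 2 * o / (Vb + o)
          } else {
            p <- NA_real_
            realized <- 0
          }
          truth[[length(truth) + 1L]] <- data.frame(
            image_id = image_id, subject = subject, algorithm = a,
            lesion = li, ref_volume_mm3 = vol, target_sdi = p,
            realized_sdi = realized, rendered = rendered,
            stringsAsFactors = FALSE)
        }
      }

      if (spec$false_alarm_rate > 0) {
        for (a in algs) {
          nfa <- stats::rpois(1L, spec$false_alarm_rate)
          for (k in seq_len(nfa)) {
            v <- .rlogunif(1L, spec$volume_range)
            d <- .box_dims(max(1L, as.integer(round(v / vv))))
            origin <- .place_bbox(claimed, d)
            if (is.null(origin)) next   # image full; skip this false alarm
            claimed <- .claim(claimed, origin, d)
            cb <- .box_coords(d)
            alg_grids[[a]][cb + matrix(origin - 1L, nrow = nrow(cb),
                                       ncol = 3L, byrow = TRUE)] <- TRUE
            fas[[length(fas) + 1L]] <- data.frame(
              image_id = image_id, algorithm = a,
              volume_mm3 = nrow(cb) * vv, stringsAsFactors = FALSE)
          }
        }
      }

      reference[[image_id]] <- binary_mask(
        ref_grid, spacing = spec$spacing, space_tag = "synthetic",
        source_id = "reference")
      for (a in algs)
        algorithms[[a]][[image_id]] <- binary_mask(
          alg_grids[[a]], spacing = spec$spacing, space_tag = "synthetic",
          source_id = a)
      image_subjects[image_id] <- subject
    }
  }

  truth <- do.call(rbind, truth)
  fas <- if (length(fas)) do.call(rbind, fas) else
    data.frame(image_id = character(0), algorithm = character(0),
               volume_mm3 = numeric(0))
  structure(list(reference = reference, algorithms = algorithms,
                 image_subjects = image_subjects, truth = truth,
                 false_alarms = fas, spec = spec),
            class = "synthetic_ensemble")
}
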