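# LOESS trends of per-lesion SDI versus lesion volume.
#
# Local regression is implemented directly from its definition: at each
# evaluation point the span-fraction nearest neighbors (in the abscissa)
# get tricube weights w = (1 - (d/dmax)^3)^3 and a weighted polynomial
# least-squares fit is evaluated at the point.  Keeping the smoother's
# hat rows explicit gives the pointwise variance of the fit for the
# confidence band (linear-smoother formula).  The abscissa is
# log10(volume) by default: lesion volumes span orders of magnitude, and
# a linear axis would degenerate the span neighborhoods.

# hat row of the local fit at x0: fitted(x0) = sum(l * y).
# Falls back to a lower local degree if the weighted design is singular
# (e.g. all neighbors at the same abscissa).
.local_hat_row <- function(x, x0, span, degree) {
  n <- length(x)
  q <- floor(n * span + 1e-9)
  d <- abs(x - x0)
  dmax <- sort(d, partial = q)[q]
  w <- numeric(n)
  if (dmax <= 0) {
    w[d == 0] <- 1
  } else {
    u <- d / dmax
    inside <- u < 1
    w[inside] <- (1 - u[inside]^3)^3
  }
  for (deg in seq(degree, 0)) {
    X <- outer(x - x0, 0:deg, `^`)
    XtW <- t(X * w)
    A <- XtW %*% X
    l <- tryCatch(solve(A, XtW)[1L, ],
                  error = function(e) NULL)
    if (!is.null(l)) return(l)
  }
  w / sum(w)
}

.smoother_matrix <- function(x, x_eval, span, degree) {
  t(vapply(x_eval, function(x0) .local_hat_row(x, x0, span, degree),
           numeric(length(x))))
}

#' LOESS trend of per-lesion SDI against lesion volume
#'
#' Fits a tricube-weighted local polynomial regression of SDI on
#' log10(volume) and evaluates it, with a pointwise confidence band, on a
#' regular grid spanning the observed volume range (no extrapolation).
#'
#' The band uses the linear-smoother variance: the fit at a grid point is
#' \eqn{l' y}, its standard error \eqn{\hat\sigma \|l\|}, with
#' \eqn{\hat\sigma^2} the residual sum of squares over the approximate
#' residual degrees of freedom \eqn{n - 2\mathrm{tr}(L) + \mathrm{tr}(L L')}.
#'
#' @param volumes positive lesion volumes in mm^3.
#' @param sdi per-lesion SDI values in [0, 1], same length.
#' @param span smoothing fraction in (0, 1]: the fraction of points in
#'   each local neighborhood (default 0.75).
#' @param degree local polynomial degree, 1 or 2 (default 2).
#' @param level confidence level of the band (default 0.95).
#' @param log_volume fit on log10(volume)?  Default \code{TRUE}.
#' @param n_grid number of evaluation points (default 100).
#' @return object of class \code{sdi_trend}: list with
#'   \code{grid_volumes}, \code{grid_log10_volumes}, \code{fitted_sdi},
#'   \code{band_low}, \code{band_high}, \code{se}, the smoothing
#'   parameters, \code{n_points}, \code{df_resid} and the data used.
#' @export
sdi_trend <- function(volumes, sdi, span = 0.75, degree = 2, level = 0.95,
                      log_volume = TRUE, n_grid = 100L) {
  volumes <- as.numeric(volumes)
  sdi <- as.numeric(sdi)
  if (length(volumes) != length(sdi))
    stop("volumes and sdi must have equal length", call. = FALSE)
  ok <- !is.na(volumes) & !is.na(sdi)
  volumes <- volumes[ok]; sdi <- sdi[ok]
  if (any(volumes <= 0))
    stop("volumes must be positive", call. = FALSE)
  n <- length(volumes)
  if (n < max(degree + 2L, 5L))
    stop("too few points for a LOESS fit (need at least ",
         max(degree + 2L, 5L), ")", call. = FALSE)
  if (!degree %in% c(1L, 2L))
    stop("degree must be 1 or 2", call. = FALSE)
  if (span <= 0 || span > 1)
    stop("span must be in (0, 1]", call. = FALSE)
  if (floor(n * span) < degree + 1L)
    stop("span too small for the requested degree", call. = FALSE)

  x <- if (log_volume) log10(volumes) else volumes
  grid_x <- seq(min(x), max(x), length.out = n_grid)

  Lg <- .smoother_matrix(x, grid_x, span, degree)
  fitted <- drop(Lg %*% sdi)

  Ld <- .smoother_matrix(x, x, span, degree)
  resid <- sdi - drop(Ld %*% sdi)
  df_resid <- max(1, n - 2 * sum(diag(Ld)) + sum(Ld^2))
  sigma2 <- sum(resid^2) / df_resid
  se <- sqrt(sigma2 * rowSums(Lg^2))
  tq <- stats::qt((1 + level) / 2, df_resid)

  structure(list(class = NA_character_,
                 grid_volumes = if (log_volume) 10^grid_x else grid_x,
                 grid_log10_volumes = if (log_volume) grid_x else log10(grid_x),
                 fitted_sdi = fitted,
                 band_low = fitted - tq * se,
                 band_high = fitted + tq * se,
                 se = se, span = span, degree = degree, level = level,
                 n_points = n, df_resid = df_resid,
                 log_volume = log_volume, x = x, y = sdi),
            class = "sdi_trend")
}

#' Recompute the confidence band of a fitted trend at a new level
#'
#' @param curve an [sdi_trend()] object.
#' @param level confidence level in (0, 1).
#' @return the curve with \code{band_low}, \code{band_high} and
#'   \code{level} replaced.
#' @export
confidence_band <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "sdi_trend"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  tq <- stats::qt((1 + level) / 2, curve$df_resid)
  curve$band_low <- curve$fitted_sdi - tq * curve$se
  curve$band_high <- curve$fitted_sdi + tq * curve$se
  curve$level <- level
  curve
}

#' Evaluate a fitted trend at new volumes
#'
#' Refits the local regression at the requested abscissas using the
#' stored data.  Volumes outside the observed range return \code{NA}
#' (the curve is never extrapolated).
#'
#' @param object an [sdi_trend()] object.
#' @param volumes positive volumes in mm^3 at which to evaluate.
#' @param ... unused.
#' @return numeric vector of fitted SDI values.
#' @export
predict.sdi_trend <- function(object, volumes, ...) {
  xnew <- if (object$log_volume) log10(as.numeric(volumes))
          else as.numeric(volumes)
  out <- rep(NA_real_, length(xnew))
  inside <- xnew >= min(object$x) & xnew <= max(object$x)
  if (any(inside)) {
    L <- .smoother_matrix(object$x, xnew[inside], object$span, object$degree)
    out[inside] <- drop(L %*% object$y)
  }
  out
}

#' @export
print.sdi_trend <- function(x, ...) {
  cat("<sdi_trend>",
      if (!is.na(x$class)) paste0(" class ", x$class), " n = ", x$n_points,
      ", span = ", x$span, ", degree = ", x$degree, "\n", sep = "")
  cat("  volume range (mm^3): [", format(min(x$grid_volumes)), ", ",
      format(max(x$grid_volumes)), "]   fitted SDI range: [",
      format(round(min(x$fitted_sdi), 4)), ", ",
      format(round(max(x$fitted_sdi), 4)), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.sdi_trend <- function(x, add = FALSE, col = "steelblue",
                           band = TRUE, ...) {
  if (!add)
    graphics::plot(x$x, x$y, pch = 16, col = "grey60",
                   xlab = if (x$log_volume) "log10 lesion volume (mm^3)"
                          else "lesion volume (mm^3)",
                   ylab = "per-lesion SDI", ylim = c(0, 1), ...)
  gx <- x$grid_log10_volumes
  if (band)
    graphics::polygon(c(gx, rev(gx)), c(x$band_low, rev(x$band_high)),
                      col = grDevices::adjustcolor(col, 0.2), border = NA)
  graphics::lines(gx, x$fitted_sdi, col = col, lwd = 2)
  invisible(x)
}

#' Per-class trend curves from a lesion evaluation
#'
#' Fits one [sdi_trend()] per requested detection class on that class's
#' (reference volume, group SDI) rows.  Classes with too few lesions are
#' skipped with a warning and reported in the \code{"skipped"} attribute.
#'
#' @param report a \code{lesion_eval}, or a data frame of pooled
#'   per-lesion rows with columns \code{ref_volume_mm3},
#'   \code{group_sdi}, \code{class} (e.g. several evaluations row-bound
#'   for a cohort-level fit).
#' @param classes class codes to fit (default the four agreement classes
#'   1-1, 1-N, M-1, M-N).
#' @param span,degree,level see [sdi_trend()].
#' @return named list of \code{sdi_trend} objects (one per fitted class).
#' @export
class_trends <- function(report, classes = c("1-1", "1-N", "M-1", "M-N"),
                         span = 0.75, degree = 2, level = 0.95) {
  pl <- if (inherits(report, "lesion_eval")) report$per_lesion else report
  stopifnot(is.data.frame(pl),
            all(c("ref_volume_mm3", "group_sdi", "class") %in% names(pl)))
  bad <- setdiff(classes, .class_codes)
  if (length(bad))
    stop("unknown class code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- list()
  skipped <- character(0)
  need <- max(degree + 2L, 5L)
  for (cl in classes) {
    rows <- pl[pl$class == cl & pl$ref_volume_mm3 > 0, ]
    if (nrow(rows) < need) {
      skipped <- c(skipped, cl)
      warning("class ", cl, " skipped: only ", nrow(rows),
              " lesion(s), need ", need, call. = FALSE)
      next
    }
    cu <- sdi_trend(rows$ref_volume_mm3, rows$group_sdi, span = span,
                    degree = degree, level = level)
    cu$class <- cl
    out[[cl]] <- cu
  }
  attr(out, "skipped") <- skipped
  out
}
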