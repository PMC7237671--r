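# Paired nonparametric comparison of per-image SDI between methods.

#' Two-sided Wilcoxon signed-rank paired test
#'
#' Compares two paired samples of per-image SDI values.  Zero differences
#' are dropped (the classic Wilcoxon convention).  The exact null
#' distribution is used when at most \code{exact_max} nonzero differences
#' remain and their absolute values are untied; otherwise the normal
#' approximation with tie correction is used.  Computation is delegated
#' to \code{stats::wilcox.test}.
#'
#' @param x,y equal-length numeric vectors (e.g. per-image SDI of two
#'   methods).
#' @param exact_max largest effective n for which the exact distribution
#'   is used (default 25).
#' @return object of class \code{paired_test}: list with
#'   \code{statistic} (V, sum of positive ranks), \code{p_value},
#'   \code{n_effective}, \code{method}, \code{degenerate}.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  d <- as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(structure(list(statistic = NA_real_, p_value = 1,
                          n_effective = 0L,
                          method = "degenerate (all differences zero)",
                          degenerate = TRUE),
                     class = "paired_test"))
  use_exact <- n <= exact_max && !anyDuplicated(abs(d))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = use_exact, correct = !use_exact))
  structure(list(statistic = unname(wt$statistic),
                 p_value = min(1, wt$p.value),
                 n_effective = n,
                 method = if (use_exact) "exact signed-rank distribution"
                          else "normal approximation with tie correction",
                 degenerate = FALSE),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat("Two-sided Wilcoxon signed-rank paired test\n")
  cat("  n (nonzero differences): ", x$n_effective,
      "   method: ", x$method, "\n", sep = "")
  if (!x$degenerate)
    cat("  V = ", format(x$statistic), ", p = ",
        format.pval(x$p_value, digits = 4), "\n", sep = "")
  else cat("  all paired differences are zero; p = 1\n")
  invisible(x)
}

#' Multiple-comparison adjustment of p-values
#'
#' Holm step-down by default (uniformly more powerful than Bonferroni at
#' the same family-wise error rate); Bonferroni selectable.  Wraps
#' \code{stats::p.adjust}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method \code{"holm"} (default) or \code{"bonferroni"}.
#' @return adjusted p-values, order-preserving, clipped to 1.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  p <- as.numeric(p)
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = method)
}

#' Pairwise SDI comparison between methods
#'
#' Runs a two-sided Wilcoxon signed-rank paired test for every pair of
#' methods on their per-image SDI values and adjusts the p-values for
#' multiple comparisons.
#'
#' @param sdi_by_method named list of equal-length numeric vectors of
#'   per-image SDI (images aligned across methods).
#' @param method adjustment method, see [adjust_pvalues()].
#' @return data frame with one row per method pair: \code{method_a},
#'   \code{method_b}, \code{statistic}, \code{n_effective},
#'   \code{p_value}, \code{p_adjusted}.
#' @export
compare_sdi <- function(sdi_by_method, method = "holm") {
  stopifnot(is.list(sdi_by_method), length(sdi_by_method) >= 2L,
            !is.null(names(sdi_by_method)))
  nm <- names(sdi_by_method)
  pairs <- utils::combn(nm, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    keep <- !is.na(sdi_by_method[[a]]) & !is.na(sdi_by_method[[b]])
    wt <- wilcoxon_signed_rank(sdi_by_method[[a]][keep],
                               sdi_by_method[[b]][keep])
    data.frame(method_a = a, method_b = b, statistic = wt$statistic,
               n_effective = wt$n_effective, p_value = wt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_value, method = method)
  out
}
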