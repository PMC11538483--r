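#' Paired comparison of two plan cohorts
#'
#' For each metric column shared by the two tables, computes the median
#' of the paired differences (second minus first) and the two-sided
#' Wilcoxon signed-rank p-value (exact distribution for n <= 25 without
#' ties or zeros, normal approximation otherwise).  Differences are
#' called non-significant when p exceeds `alpha`; no multiple-testing
#' correction is applied.
#'
#' @param a,b data.frames with a shared `case` column and identical
#'   numeric metric columns (e.g. one row per phantom, IMPT in `a`, PAT
#'   in `b`).
#' @param alpha significance threshold, default 0.05.
#' @return data.frame: `metric`, `median_diff` (b - a), `p_value`,
#'   `significant`.
#' @export
compare_plans <- function(a, b, alpha = 0.05) {
  if (!("case" %in% names(a)) || !("case" %in% names(b)))
    stop("both tables need a 'case' column")
  if (nrow(a) != nrow(b)) stop("cohorts must be the same size")
  b <- b[match(a$case, b$case), ]
  if (any(is.na(b$case))) stop("cases do not pair up")
  metrics <- setdiff(intersect(names(a), names(b)), "case")
  metrics <- metrics[vapply(metrics, function(m) is.numeric(a[[m]]), TRUE)]
  out <- lapply(metrics, function(m) {
    diff <- b[[m]] - a[[m]]
    p <- wilcoxon_signed_rank(b[[m]], a[[m]])
    data.frame(metric = m, median_diff = stats::median(diff),
               p_value = p, significant = p <= alpha)
  })
  do.call(rbind, out)
}

#' Two-sided Wilcoxon signed-rank test p-value for paired samples
#'
#' Thin wrapper over [stats::wilcox.test()] with `paired = TRUE`.  The
#' degenerate case of all-zero differences (identical samples) returns
#' p = 1 with a warning, since no difference is detectable.
#'
#' @param x,y paired numeric vectors.
#' @return two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  if (all(d == 0)) {
    warning("all paired differences are zero; degenerate test, p = 1")
    return(1)
  }
  suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
}
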