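#' Spearman rank correlation with a binary outcome
#'
#' Rank correlation using average ranks for ties, with the p value from the
#' large-sample t approximation. A constant input yields `r_s = 0`, `p = 1`
#' with a warning.
#'
#' @param x numeric feature vector (length >= 3).
#' @param y outcome vector (binary labels in the pipeline, but any
#'   non-constant numeric vector is accepted).
#' @return list with `r_s` and `p`.
#' @export
spearman_rs <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) stopf("need equal lengths >= 3")
  if (length(unique(y)) < 2) stopf("y must not be constant")
  if (length(unique(x)) < 2) {
    warnf("constant feature: r_s set to 0, p to 1")
    return(list(r_s = 0, p = 1))
  }
  rs <- cor(rank(x), rank(y))
  if (abs(rs) >= 1) return(list(r_s = rs, p = 0))
  tstat <- rs * sqrt((n - 2) / (1 - rs^2))
  list(r_s = rs, p = 2 * pt(-abs(tstat), df = n - 2))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param K number of comparisons (>= 1).
#' @return `alpha / K`.
#' @export
bonferroni_threshold <- function(alpha, K) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (!is_count(K) || K < 1) stopf("K must be a positive count")
  alpha / K
}

#' Univariate Spearman screening of a feature table
#'
#' Computes `r_s` and its p value for every feature against the class
#' label and flags significance at the Bonferroni-corrected level
#' `alpha / K`. `K` defaults to the number of features, but can be given
#' explicitly when screening is calibrated at a coarser grouping (e.g. at
#' the statistic-family level).
#'
#' @param table a [feature_table()].
#' @param alpha family-wise significance level.
#' @param K number of comparisons for the correction.
#' @return data.frame with `feature`, `r_s`, `p`, `significant`.
#' @export
univariate_screen <- function(table, alpha = 0.05, K = ncol(table$X)) {
  stopifnot(inherits(table, "feature_table"))
  thr <- bonferroni_threshold(alpha, K)
  res <- lapply(seq_len(ncol(table$X)), function(j) {
    suppressWarnings(spearman_rs(table$X[, j], table$y))
  })
  data.frame(feature = colnames(table$X),
             r_s = vapply(res, `[[`, numeric(1), "r_s"),
             p = vapply(res, `[[`, numeric(1), "p"),
             significant = vapply(res, `[[`, numeric(1), "p") < thr)
}
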