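#' Sensitivity, specificity and accuracy at a probability threshold
#'
#' Necrosis (label 1) is the positive class; a score at or above the
#' threshold predicts positive.
#'
#' @param scores predicted probabilities.
#' @param labels binary labels (both classes present).
#' @param threshold classification threshold in (0, 1).
#' @return named vector `Se`, `Sp`, `Acc`.
#' @export
sens_spec_acc <- function(scores, labels, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  pos <- labels == 1
  if (!any(pos) || all(pos)) stopf("both classes must be present")
  pred <- scores >= threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  c(Se = tp / (tp + fn), Sp = tn / (tn + fp),
    Acc = (tp + tn) / length(labels))
}

#' Ensemble evaluation of a feature combination
#'
#' For each bootstrap replicate the model is refit on the in-bag sample
#' and scored on both the in-bag sample (training role) and the
#' out-of-bag sample (validation role); AUC, sensitivity, specificity and
#' accuracy are recorded per replicate, with means, standard deviations,
#' standard errors and the 95% confidence half-width of the mean.
#'
#' @param features feature names to model.
#' @param table a [feature_table()].
#' @param ensemble a [imbalance_adjusted_resample()] ensemble.
#' @param threshold classification threshold.
#' @param ridge ridge penalty.
#' @return object of class `metric_set`: per-role matrices `training` and
#'   `validation` (B x 4), plus `summary` (mean/sd/se/ci95 per metric and
#'   role) and `B`.
#' @export
evaluate_ensemble <- function(features, table, ensemble, threshold = 0.5,
                              ridge = 1e-4) {
  stopifnot(inherits(table, "feature_table"),
            inherits(ensemble, "bootstrap_ensemble"))
  const <- standardize_constants(table$X[, features, drop = FALSE])
  Xs <- apply_standardize(table$X[, features, drop = FALSE], const)
  y <- table$y
  B <- ensemble$B
  tr <- matrix(NA_real_, B, 4, dimnames = list(NULL, c("AUC", "Se", "Sp", "Acc")))
  va <- tr
  for (b in seq_len(B)) {
    idx <- ensemble$inbag[[b]]
    oob <- ensemble$oob[[b]]
    cf <- fit_logistic(Xs[idx, , drop = FALSE], y[idx], ridge, quiet = TRUE)
    score <- function(rows) {
      eta <- drop(cbind(1, Xs[rows, , drop = FALSE]) %*% cf)
      1 / (1 + exp(-eta))
    }
    s_in <- score(idx); s_out <- score(oob)
    tr[b, ] <- c(auc(s_in, y[idx]), sens_spec_acc(s_in, y[idx], threshold))
    va[b, ] <- c(auc(s_out, y[oob]), sens_spec_acc(s_out, y[oob], threshold))
  }
  summarize <- function(M, role) {
    data.frame(role = role, metric = colnames(M),
               mean = colMeans(M), sd = apply(M, 2, sd),
               se = apply(M, 2, sd) / sqrt(B),
               ci95 = qt(0.975, B - 1) * apply(M, 2, sd) / sqrt(B),
               row.names = NULL)
  }
  structure(list(training = tr, validation = va,
                 summary = rbind(summarize(tr, "training"),
                                 summarize(va, "validation")),
                 features = features, threshold = threshold, B = B),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> %s | B = %d replicates\n",
              paste(x$features, collapse = " + "), x$B))
  s <- x$summary
  s$mean <- round(s$mean, 4); s$sd <- round(s$sd, 4)
  s$se <- round(s$se, 4); s$ci95 <- round(s$ci95, 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Paired t test between two per-replicate metric vectors
#'
#' Replicates must be aligned by ensemble index. Zero-variance differences
#' are flagged degenerate: p = 1 for identical vectors, p = 0 for a
#' constant nonzero difference.
#'
#' @param metric_a,metric_b numeric vectors of equal length >= 2.
#' @return object of class `comparison_result`: `t`, `p`, `df`, `n`,
#'   `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(metric_a, metric_b) {
  n <- length(metric_a)
  if (n != length(metric_b) || n < 2) stopf("need equal lengths >= 2")
  d <- metric_a - metric_b
  md <- mean(d)
  sdd <- sd(d)
  # a constant difference vector (up to rounding) is degenerate
  if (sdd <= 1e-12 * max(abs(md), 1)) {
    res <- list(t = if (md == 0) 0 else sign(md) * Inf,
                p = if (md == 0) 1 else 0,
                df = n - 1, n = n, mean_diff = md, degenerate = TRUE)
    return(structure(res, class = "comparison_result"))
  }
  tstat <- md / (sdd / sqrt(n))
  structure(list(t = tstat, p = 2 * pt(-abs(tstat), df = n - 1),
                 df = n - 1, n = n, mean_diff = md, degenerate = FALSE),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> mean diff %.4g, t = %.3f (df %d), p = %.3g%s\n",
              x$mean_diff, x$t, x$df, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Long-format AUC trace of an evaluated ensemble
#'
#' One row per replicate and role, for plotting or export.
#'
#' @param metricset a [evaluate_ensemble()] result.
#' @return data.frame with `replicate`, `role`, `AUC`.
#' @export
auc_trace <- function(metricset) {
  stopifnot(inherits(metricset, "metric_set"))
  B <- metricset$B
  data.frame(replicate = rep(seq_len(B), 2),
             role = rep(c("training", "validation"), each = B),
             AUC = c(metricset$training[, "AUC"],
                     metricset$validation[, "AUC"]))
}
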