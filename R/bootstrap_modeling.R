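#' Imbalance-adjusted bootstrap resampling
#'
#' Draws `B` bootstrap replicates of size `N`. In `"imbalance"` mode each
#' draw first picks a class with probability 1/2 and then a uniform member
#' of that class, so positives and negatives are equally likely per draw
#' regardless of the class imbalance. In `"uniform"` mode draws are
#' uniform over all patients (the classical bootstrap, whose expected
#' distinct in-bag fraction is 0.632). Replicates whose out-of-bag set
#' or in-bag multiset lacks either class are redrawn, up to `max_retry`
#' times each; when a class has a single member this is unattainable and
#' only a non-empty out-of-bag set is required.
#'
#' @param labels binary vector (both classes present).
#' @param B replicate count (>= 1).
#' @param seed RNG seed.
#' @param mode `"imbalance"` (default) or `"uniform"`.
#' @param max_retry redraw bound per replicate.
#' @return object of class `bootstrap_ensemble`: lists `inbag` (index
#'   multisets of size N) and `oob` (complement index sets), plus `B`,
#'   `mode`, `seed`, `labels`.
#' @export
imbalance_adjusted_resample <- function(labels, B, seed = 1L,
                                        mode = c("imbalance", "uniform"),
                                        max_retry = 100L) {
  mode <- match.arg(mode)
  if (!is_count(B) || B < 1) stopf("B must be a positive count")
  N <- length(labels)
  pos <- which(labels == 1)
  neg <- which(labels != 1)
  if (length(pos) == 0 || length(neg) == 0)
    stopf("both classes must be present")
  # with a singleton class, an out-of-bag set holding both classes may be
  # unattainable (e.g. N = 2); the redraw rule then only requires a
  # non-empty out-of-bag set
  need_both <- length(pos) >= 2 && length(neg) >= 2
  all_idx <- seq_len(N)
  ens <- with_seed(derive_seed(seed, "resample"), {
    inbag <- vector("list", B)
    oob <- vector("list", B)
    for (b in seq_len(B)) {
      for (try in seq_len(max_retry + 1L)) {
        if (try > max_retry)
          stopf("replicate %d: no out-of-bag set with both classes after %d redraws",
                b, max_retry)
        draw <- if (mode == "imbalance") {
          take_pos <- runif(N) < 0.5
          ifelse(take_pos,
                 pos[sample.int(length(pos), N, replace = TRUE)],
                 neg[sample.int(length(neg), N, replace = TRUE)])
        } else {
          sample.int(N, N, replace = TRUE)
        }
        out <- setdiff(all_idx, draw)
        ok <- if (need_both)
          any(labels[out] == 1) && any(labels[out] != 1) &&
            any(labels[draw] == 1) && any(labels[draw] != 1)
        else length(out) > 0
        if (ok) {
          inbag[[b]] <- as.integer(draw)
          oob[[b]] <- as.integer(out)
          break
        }
      }
    }
    list(inbag = inbag, oob = oob)
  })
  structure(list(inbag = ens$inbag, oob = ens$oob, B = as.integer(B),
                 mode = mode, seed = as.integer(seed),
                 labels = as.integer(labels)),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("<bootstrap_ensemble> B = %d, N = %d, mode = %s\n",
              x$B, length(x$labels), x$mode))
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(score_pos > score_neg) + 0.5 P(tie)`, computed from average ranks.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Ridge-penalized logistic regression fit
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' with a small ridge penalty on the slopes (the intercept is never
#' penalized), which keeps coefficients finite under separation.
#' Zero-variance columns are dropped from the fit and reported with
#' coefficient 0.
#'
#' @param X numeric matrix (rows = patients); an intercept is added
#'   internally. May have zero columns for an intercept-only fit.
#' @param y binary outcome vector.
#' @param ridge ridge penalty on slopes.
#' @param quiet suppress the zero-variance-column warning.
#' @return named coefficient vector `(Intercept), <columns>`.
#' @export
fit_logistic <- function(X, y, ridge = 1e-4, quiet = FALSE) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stopf("both classes must be present in-bag")
  p <- ncol(X)
  keep <- if (p > 0) apply(X, 2, function(v) sd(v) > 0) else logical(0)
  if (p > 0 && any(!keep) && !quiet)
    warnf("zero-variance column(s) dropped from fit: %s",
          paste(colnames(X)[!keep], collapse = ", "))
  Xf <- cbind(1, X[, keep, drop = FALSE])
  beta <- cpp_logistic_irls(Xf, as.numeric(y), ridge)
  out <- numeric(p + 1)
  out[c(TRUE, keep)] <- as.numeric(beta)
  names(out) <- c("(Intercept)", colnames(X))
  out
}

# Standardization constants from the whole sample (features are z-scored on
# a common scale before fitting, so bootstrap-averaged coefficients are
# comparable across replicates).
standardize_constants <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_standardize <- function(X, const) {
  sweep(sweep(X, 2, const$center), 2, const$scale, "/")
}

# fast 0.632+ core: Xs standardized matrix of the candidate features only
boot_auc632_core <- function(Xs, y, ensemble, ridge = 1e-4) {
  app_coef <- fit_logistic(Xs, y, ridge, quiet = TRUE)
  app_scores <- drop(cbind(1, Xs) %*% app_coef)
  auc_app <- auc(app_scores, y)
  B <- ensemble$B
  auc_oob <- numeric(B)
  for (b in seq_len(B)) {
    idx <- ensemble$inbag[[b]]
    oob <- ensemble$oob[[b]]
    cf <- fit_logistic(Xs[idx, , drop = FALSE], y[idx], ridge, quiet = TRUE)
    sc <- drop(cbind(1, Xs[oob, , drop = FALSE]) %*% cf)
    auc_oob[b] <- auc(sc, y[oob])
  }
  auc_prime <- pmax(0.5, auc_oob)
  R <- ifelse(auc_oob < 0.5, 1,
              ifelse(auc_app > 0.5 & auc_oob < auc_app,
                     (auc_app - auc_oob) / (auc_app - 0.5), 0))
  R <- pmin(pmax(R, 0), 1)
  alpha <- 0.632 / (1 - 0.368 * R)
  est <- mean((1 - alpha) * auc_app + alpha * auc_prime)
  list(auc_apparent = auc_app, auc_oob = auc_oob, auc_prime = auc_prime,
       R = R, alpha = alpha, estimate = est)
}

#' 0.632+ bootstrap AUC of a feature combination
#'
#' Fits the logistic model on each in-bag replicate, scores its
#' out-of-bag set, clips each out-of-bag AUC at 0.5 (`AUC'`), computes the
#' relative overfitting rate `R^b` (1 when the out-of-bag AUC falls below
#' 0.5; interpolating between 0 and 1 while it lies between the apparent
#' AUC and 0.5; 0 otherwise) and the weight
#' `alpha^b = 0.632 / (1 - 0.368 R^b)`, and averages
#' `(1 - alpha^b) AUC(x, x) + alpha^b AUC'` over replicates.
#'
#' @param features feature names to model.
#' @param table a [feature_table()].
#' @param ensemble a [imbalance_adjusted_resample()] ensemble built on the
#'   table's labels.
#' @param ridge ridge penalty for the per-replicate fits.
#' @return object of class `auc632_result` with `auc_apparent`,
#'   `auc_oob`, `auc_prime`, `R`, `alpha`, `estimate`.
#' @export
auc_632plus <- function(features, table, ensemble, ridge = 1e-4) {
  stopifnot(inherits(table, "feature_table"),
            inherits(ensemble, "bootstrap_ensemble"))
  missing <- setdiff(features, colnames(table$X))
  if (length(missing) > 0)
    stopf("features not in table: %s", paste(missing, collapse = ", "))
  const <- standardize_constants(table$X[, features, drop = FALSE])
  Xs <- apply_standardize(table$X[, features, drop = FALSE], const)
  res <- boot_auc632_core(Xs, table$y, ensemble, ridge)
  structure(c(res, list(features = features)), class = "auc632_result")
}

#' @export
print.auc632_result <- function(x, ...) {
  cat(sprintf("<auc632_result> %s | apparent %.4f | 0.632+ estimate %.4f (B = %d)\n",
              paste(x$features, collapse = " + "), x$auc_apparent,
              x$estimate, length(x$auc_oob)))
  invisible(x)
}

#' Stepwise forward selection by 0.632+ bootstrap AUC
#'
#' For each starter feature, the combination grows greedily: at each step
#' the remaining feature maximizing the 0.632+ bootstrap AUC is added, up
#' to the largest requested order. Per order, the best combination over
#' all starters is retained (ties resolved toward the combination whose
#' features rank earlier in the reduced list). The same ensemble is shared
#' by every candidate evaluation.
#'
#' @param reduced ordered reduced feature names (or a
#'   [reduce_features()] result).
#' @param table a [feature_table()].
#' @param ensemble a [imbalance_adjusted_resample()] ensemble.
#' @param orders model orders to search (default 1..10).
#' @param starters starter features (default: all of `reduced`).
#' @param ridge ridge penalty.
#' @return object of class `model_search`: `per_order` (list with
#'   `features` and `auc` per order), `chosen_order`, `chosen_features`.
#' @export
forward_select <- function(reduced, table, ensemble, orders = 1:10,
                           starters = NULL, ridge = 1e-4) {
  if (inherits(reduced, "reduction_state")) reduced <- reduced$selected
  stopifnot(inherits(table, "feature_table"))
  max_order <- max(orders)
  if (max_order > length(reduced))
    stopf("max order %d exceeds the %d reduced features", max_order,
          length(reduced))
  starters <- starters %||% reduced
  if (!all(starters %in% reduced)) stopf("starters must be reduced features")
  const <- standardize_constants(table$X[, reduced, drop = FALSE])
  Xs <- apply_standardize(table$X[, reduced, drop = FALSE], const)
  y <- table$y
  rank_of <- setNames(seq_along(reduced), reduced)
  eval632 <- function(feats)
    boot_auc632_core(Xs[, feats, drop = FALSE], y, ensemble, ridge)$estimate
  best <- vector("list", max_order) # per order: list(features, auc)
  ranks_before <- function(f1, f2) {
    # lexicographic comparison of sorted reduced-set ranks
    r1 <- sort(rank_of[f1]); r2 <- sort(rank_of[f2])
    d <- r1 - r2
    nz <- which(d != 0)
    length(nz) > 0 && d[nz[1]] < 0
  }
  consider <- function(order, feats, aucval) {
    aucval <- unname(aucval)
    cur <- best[[order]]
    take <- is.null(cur) || aucval > cur$auc ||
      (aucval == cur$auc && ranks_before(feats, cur$features))
    if (take) best[[order]] <<- list(features = feats, auc = aucval)
  }
  for (s in starters) {
    combo <- s
    consider(1L, combo, eval632(combo))
    while (length(combo) < max_order) {
      rest <- setdiff(reduced, combo)
      vals <- vapply(rest, function(f) eval632(c(combo, f)), numeric(1))
      ord <- order(-vals, rank_of[rest])
      combo <- c(combo, rest[ord[1]])
      consider(length(combo), combo, vals[ord[1]])
    }
  }
  per_order <- best[orders]
  names(per_order) <- paste0("order", orders)
  aucs <- vapply(per_order, `[[`, numeric(1), "auc")
  chosen <- orders[which.max(aucs)] # ties -> smaller order
  structure(list(per_order = per_order, orders = orders,
                 chosen_order = chosen,
                 chosen_features = per_order[[which.max(aucs)]]$features),
            class = "model_search")
}

#' Optimal model order from a search result
#'
#' The order with the maximum 0.632+ bootstrap AUC; ties resolve to the
#' smaller order.
#'
#' @param result a [forward_select()] result.
#' @return the chosen order (integer).
#' @export
choose_order <- function(result) {
  stopifnot(inherits(result, "model_search"))
  aucs <- vapply(result$per_order, `[[`, numeric(1), "auc")
  result$orders[which.max(aucs)]
}

#' @export
print.model_search <- function(x, ...) {
  cat("<model_search>\n")
  for (i in seq_along(x$per_order)) {
    po <- x$per_order[[i]]
    cat(sprintf("  order %2d: 0.632+ AUC %.4f | %s\n", x$orders[i], po$auc,
                paste(po$features, collapse = " + ")))
  }
  cat(sprintf("  chosen order: %d\n", x$chosen_order))
  invisible(x)
}

#' Bootstrap-averaged logistic model
#'
#' Fits the logistic model on every in-bag replicate and averages the
#' coefficients (including the intercept) element-wise. Features are
#' z-scored with whole-sample constants before fitting; the constants are
#' stored so the model can score raw feature vectors.
#'
#' @param features fixed feature combination.
#' @param table a [feature_table()].
#' @param ensemble a [imbalance_adjusted_resample()] ensemble.
#' @param ridge ridge penalty.
#' @return object of class `fitted_logistic`: `features`, `coefficients`
#'   (averaged, intercept first), `center`, `scale`, `ridge`, `B`.
#' @export
average_coefficients <- function(features, table, ensemble, ridge = 1e-4) {
  stopifnot(inherits(table, "feature_table"),
            inherits(ensemble, "bootstrap_ensemble"))
  const <- standardize_constants(table$X[, features, drop = FALSE])
  Xs <- apply_standardize(table$X[, features, drop = FALSE], const)
  y <- table$y
  coefs <- vapply(seq_len(ensemble$B), function(b) {
    idx <- ensemble$inbag[[b]]
    fit_logistic(Xs[idx, , drop = FALSE], y[idx], ridge, quiet = TRUE)
  }, numeric(length(features) + 1))
  avg <- if (is.null(dim(coefs))) mean(coefs) else rowMeans(coefs)
  structure(list(features = features, coefficients = avg,
                 center = const$center, scale = const$scale,
                 ridge = ridge, B = ensemble$B),
            class = "fitted_logistic")
}

#' @export
print.fitted_logistic <- function(x, ...) {
  cat(sprintf("<fitted_logistic> order %d, B = %d\n", length(x$features), x$B))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted probability of necrosis
#'
#' Logistic transform of the linear predictor of the averaged model,
#' `p = exp(y) / (1 + exp(y))`.
#'
#' @param model a [average_coefficients()] model.
#' @param x named numeric vector, matrix, or [feature_table()] holding the
#'   model's features (raw scale).
#' @return probability vector in `(0, 1)`.
#' @export
predict_probability <- function(model, x) {
  stopifnot(inherits(model, "fitted_logistic"))
  X <- if (inherits(x, "feature_table")) x$X
       else if (is.matrix(x)) x
       else matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  missing <- setdiff(model$features, colnames(X))
  if (length(missing) > 0)
    stopf("missing feature(s): %s", paste(missing, collapse = ", "))
  Xs <- apply_standardize(X[, model$features, drop = FALSE],
                          list(center = model$center, scale = model$scale))
  eta <- drop(cbind(1, Xs) %*% model$coefficients)
  1 / (1 + exp(-eta))
}
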