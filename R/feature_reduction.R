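#' Maximal information coefficient
#'
#' MIC of two numeric vectors: the maximum, over grid sizes `k x l` with
#' `k * l <= max(4, n^alpha)`, of mutual information normalized by
#' `log2(min(k, l))`. One axis is split into equal-probability bins (ties
#' kept together) and the partition of the other axis is optimized exactly
#' by dynamic programming over tie-group boundaries; both orientations are
#' searched. Constant input yields 0 with a warning.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param alpha grid-bound exponent (default 0.6).
#' @return MIC value in `[0, 1]`.
#' @export
mic <- function(x, y, alpha = 0.6) {
  n <- length(x)
  if (n != length(y) || n < 4) stopf("need equal lengths >= 4")
  if (anyNA(x) || anyNA(y)) stopf("missing values not allowed")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warnf("constant input: MIC set to 0")
    return(0)
  }
  cpp_mic(as.numeric(x), as.numeric(y), alpha)
}

#' Triangular redundancy weights of the gain equation
#'
#' Weight `2 (d - c + 1) / (d (d + 1))` for each already-selected feature
#' `c = 1..d` (earlier selections weigh more); the weights sum to 1 for
#' any `d >= 1`.
#'
#' @param d number of already-selected features.
#' @return numeric vector of length `d` (length 0 when `d = 0`).
#' @export
gain_weights <- function(d) {
  if (d < 1) return(numeric(0))
  2 * (d - seq_len(d) + 1) / (d * (d + 1))
}

#' Gain-equation configuration
#'
#' @param gamma weight of the bootstrap-averaged Spearman term.
#' @param delta_a weight of the redundancy-versus-selected term.
#' @param delta_b weight of the redundancy-versus-remaining term (0 by
#'   default, which makes that term inert; it is still implemented).
#' @param B_reduce bootstrap replicate count for the averaged terms.
#' @param target_size reduced-set size.
#' @param absolute_rs use `|r_s|` in the first term (default) rather than
#'   signed `r_s`, so strongly negatively associated features are not
#'   anti-selected.
#' @param mic_alpha MIC grid-bound exponent.
#' @param seed RNG seed for the resampling.
#' @return object of class `gain_config`.
#' @export
gain_config <- function(gamma = 0.5, delta_a = 0.5, delta_b = 0,
                        B_reduce = 1000L, target_size = 25L,
                        absolute_rs = TRUE, mic_alpha = 0.6, seed = 1L) {
  if (gamma < 0 || delta_a < 0 || delta_b < 0)
    stopf("weights must be >= 0")
  if (!is_count(target_size) || target_size < 1)
    stopf("target_size must be >= 1")
  if (!is_count(B_reduce) || B_reduce < 1) stopf("B_reduce must be >= 1")
  structure(list(gamma = gamma, delta_a = delta_a, delta_b = delta_b,
                 B_reduce = as.integer(B_reduce),
                 target_size = as.integer(target_size),
                 absolute_rs = absolute_rs, mic_alpha = mic_alpha,
                 seed = as.integer(seed)),
            class = "gain_config")
}

#' Gain value from its bootstrap-averaged components
#'
#' The gain of a candidate feature is
#' `gamma * rs_bar + delta_a * sum_c w_c * (1 - MIC)_bar_c +
#'  delta_b * mean_k (1 - MIC)_bar_k`,
#' with `w_c` the [gain_weights()] over the `d` already-selected features
#' (term dropped when `d = 0`) and the last average taken over the `D`
#' not-yet-removed features.
#'
#' @param rs_bar bootstrap-mean (absolute) Spearman correlation of the
#'   candidate with the outcome.
#' @param one_minus_mic_selected vector of bootstrap-mean `1 - MIC` values
#'   against each selected feature, in selection order (length `d`).
#' @param one_minus_mic_remaining vector of bootstrap-mean `1 - MIC`
#'   values against the remaining features (length `D`), used only when
#'   `delta_b > 0`.
#' @param config a [gain_config()].
#' @return the gain value.
#' @export
gain_value <- function(rs_bar, one_minus_mic_selected = numeric(0),
                       one_minus_mic_remaining = numeric(0),
                       config = gain_config()) {
  g <- config$gamma * rs_bar
  d <- length(one_minus_mic_selected)
  if (d > 0)
    g <- g + config$delta_a * sum(gain_weights(d) * one_minus_mic_selected)
  if (config$delta_b > 0 && length(one_minus_mic_remaining) > 0)
    g <- g + config$delta_b * mean(one_minus_mic_remaining)
  g
}

# Bootstrap-mean |r_s(x_j, y)| for every column, over the ensemble's in-bag
# replicates.
boot_rs_means <- function(X, y, ensemble, absolute = TRUE) {
  B <- length(ensemble$inbag)
  acc <- numeric(ncol(X))
  for (b in seq_len(B)) {
    idx <- ensemble$inbag[[b]]
    ry <- rank(y[idx])
    if (sd(ry) == 0) next
    rX <- apply(X[idx, , drop = FALSE], 2, rank)
    rs <- suppressWarnings(cor(rX, ry))
    rs[is.na(rs)] <- 0
    acc <- acc + if (absolute) abs(rs) else rs
  }
  acc / B
}

# Bootstrap-mean (1 - MIC(x_a, x_j)) for one anchor column against many.
boot_one_minus_mic <- function(X, a, js, ensemble, alpha) {
  B <- length(ensemble$inbag)
  acc <- numeric(length(js))
  for (b in seq_len(B)) {
    idx <- ensemble$inbag[[b]]
    xa <- X[idx, a]
    if (length(unique(xa)) < 2) {
      acc <- acc + 1
      next
    }
    for (t in seq_along(js)) {
      xj <- X[idx, js[t]]
      m <- if (length(unique(xj)) < 2) 0 else cpp_mic(xa, xj, alpha)
      acc[t] <- acc[t] + (1 - m)
    }
  }
  acc / B
}

#' Stepwise gain-equation feature reduction
#'
#' Iteratively selects the remaining feature with the largest gain until
#' `target_size` features are chosen (ties broken lexicographically by
#' name). All bootstrap-averaged terms share one imbalance-adjusted
#' ensemble of `B_reduce` replicates, reused across candidates and
#' iterations. The returned list is ordered by descending gain at
#' selection time.
#'
#' @param table a [feature_table()].
#' @param config a [gain_config()].
#' @return object of class `reduction_state`: `selected` (ordered feature
#'   names), `gains` (gain at selection), `remaining`.
#' @export
reduce_features <- function(table, config = gain_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "gain_config"))
  X <- table$X
  y <- table$y
  D0 <- ncol(X)
  if (D0 < config$target_size)
    stopf("table has %d features, fewer than target_size %d", D0,
          config$target_size)
  ensemble <- imbalance_adjusted_resample(y, config$B_reduce,
                                          seed = config$seed)
  rs_bar <- boot_rs_means(X, y, ensemble, config$absolute_rs)
  names(rs_bar) <- colnames(X)
  selected <- integer(0)
  gains <- numeric(0)
  remaining <- seq_len(D0)
  # lazily filled bootstrap-mean (1 - MIC) between selected and remaining
  omm <- matrix(NA_real_, D0, D0)
  for (step in seq_len(config$target_size)) {
    d <- length(selected)
    g <- config$gamma * rs_bar[remaining]
    if (d > 0 && config$delta_a > 0) {
      w <- gain_weights(d)
      red <- colSums(w * omm[selected, remaining, drop = FALSE])
      g <- g + config$delta_a * red
    }
    if (config$delta_b > 0) {
      for (j in remaining) {
        need <- remaining[is.na(omm[remaining, j])]
        need <- setdiff(need, j)
        if (length(need) > 0) {
          v <- boot_one_minus_mic(X, j, need, ensemble, config$mic_alpha)
          omm[need, j] <- v
          omm[j, need] <- v
        }
        omm[j, j] <- 0
      }
      g <- g + config$delta_b *
        colMeans(omm[remaining, remaining, drop = FALSE])
    }
    ord <- order(-g, colnames(X)[remaining])
    pick <- remaining[ord[1]]
    selected <- c(selected, pick)
    gains <- c(gains, g[ord[1]])
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0 && step < config$target_size &&
        config$delta_a > 0) {
      v <- boot_one_minus_mic(X, pick, remaining, ensemble, config$mic_alpha)
      omm[remaining, pick] <- v
      omm[pick, remaining] <- v
    }
  }
  ord <- order(-gains)
  structure(list(selected = colnames(X)[selected][ord],
                 gains = unname(gains[ord]),
                 remaining = colnames(X)[remaining],
                 config = config),
            class = "reduction_state")
}

#' @export
print.reduction_state <- function(x, ...) {
  cat(sprintf("<reduction_state> %d selected features (gain %.4g .. %.4g), %d remaining\n",
              length(x$selected), max(x$gains), min(x$gains),
              length(x$remaining)))
  invisible(x)
}

#' Fuse a reduced handcrafted set with a reduced deep set
#'
#' Concatenates the two reduced name lists (handcrafted first), preserving
#' order within each block. Both lists must have the expected size
#' (default 25, giving 50 fusion features) and disjoint names.
#'
#' @param reduced_handcrafted,reduced_deep character vectors of feature
#'   names, or [reduce_features()] results.
#' @param expected_size required size of each input list.
#' @return character vector of fused feature names.
#' @export
fuse_features <- function(reduced_handcrafted, reduced_deep,
                          expected_size = 25L) {
  a <- if (inherits(reduced_handcrafted, "reduction_state"))
    reduced_handcrafted$selected else reduced_handcrafted
  b <- if (inherits(reduced_deep, "reduction_state"))
    reduced_deep$selected else reduced_deep
  if (length(a) != expected_size || length(b) != expected_size)
    stopf("both reduced sets must have %d features (got %d and %d)",
          expected_size, length(a), length(b))
  if (length(intersect(a, b)) > 0)
    stopf("name collision between reduced sets: %s",
          paste(head(intersect(a, b), 3), collapse = ", "))
  c(a, b)
}

#' Column-bind two feature tables over the same patients
#'
#' @param a,b [feature_table()] objects with identical ids and labels.
#' @return a combined [feature_table()].
#' @export
bind_feature_tables <- function(a, b) {
  stopifnot(inherits(a, "feature_table"), inherits(b, "feature_table"))
  if (!identical(a$ids, b$ids) || !identical(a$y, b$y))
    stopf("tables must share patients and labels")
  feature_table(cbind(a$X, b$X), a$y, a$ids)
}
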