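test_that("imbalance-adjusted draws pick each class with probability one half", {
  y <- rep(c(1, 0), c(16, 35))
  ens <- imbalance_adjusted_resample(y, 1000, seed = 3)
  posfrac <- mean(vapply(ens$inbag, function(i) mean(y[i] == 1), numeric(1)))
  expect_lt(abs(posfrac - 0.5), 0.02)
  sizes <- lengths(ens$inbag)
  expect_true(all(sizes == 51))
  # every OOB set is the in-bag complement and holds both classes
  for (b in c(1, 500, 1000)) {
    expect_equal(sort(ens$oob[[b]]), setdiff(1:51, unique(ens$inbag[[b]])))
    expect_true(any(y[ens$oob[[b]]] == 1) && any(y[ens$oob[[b]]] == 0))
  }
})

test_that("two-patient cohorts keep the in-bag size contract", {
  ens <- imbalance_adjusted_resample(c(0, 1), 50, seed = 1)
  expect_true(all(lengths(ens$inbag) == 2))
  expect_error(imbalance_adjusted_resample(c(1, 1, 1), 10), "both classes")
})

test_that("uniform-mode resampling reproduces the 0.632 size arithmetic", {
  y <- rep(c(1, 0), c(16, 35))
  ens <- imbalance_adjusted_resample(y, 400, seed = 9, mode = "uniform")
  distinct <- mean(vapply(ens$inbag, function(i) length(unique(i)),
                          numeric(1)))
  expect_lt(abs(distinct - 51 * 0.632), 1) # ~= 32 in-bag, ~= 19 out-of-bag
  oobs <- mean(lengths(ens$oob))
  expect_lt(abs(oobs - 51 * 0.368), 1)
})

test_that("AUC matches pair enumeration and its edge cases", {
  expect_equal(auc(c(0.9, 0.3, 0.4, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc(c(10, 9, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  # tie handling: P(pos > neg) + 0.5 P(tie) by enumeration
  s <- c(1, 2, 2, 3); y <- c(0, 0, 1, 1)
  expect_equal(auc(s, y), (1 + 0.5 + 1 + 1) / 4)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("ridge IRLS agrees with the glm second-solver oracle", {
  set.seed(14)
  X <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(500, 1, plogis(0.3 + X %*% c(1, -1.5, 0.4)))
  ours <- fit_logistic(X, y, ridge = 1e-8)
  glmfit <- coef(glm(y ~ X, family = binomial()))
  expect_lt(max(abs(ours - glmfit) / pmax(abs(glmfit), 0.1)), 0.10)
})

test_that("logistic edge cases are handled by the ridge and column guards", {
  # intercept-only closed form
  cf <- fit_logistic(matrix(numeric(0), 40, 0), rep(c(1, 0), c(10, 30)),
                     ridge = 1e-8)
  expect_equal(unname(cf[1]), log(10 / 30), tolerance = 1e-6)
  # perfectly separable two-point set stays finite
  X <- matrix(c(-1, 1), 2, 1, dimnames = list(NULL, "z"))
  cf <- fit_logistic(X, c(0, 1))
  expect_true(all(is.finite(cf)))
  # zero-variance column dropped with coefficient 0
  X <- cbind(good = rnorm(30), flat = rep(2, 30))
  y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  expect_warning(cf <- fit_logistic(X, y), "zero-variance")
  expect_equal(unname(cf["flat"]), 0)
})

test_that("0.632+ arithmetic identities hold per replicate", {
  # a noise feature scatters OOB AUCs on both sides of 0.5
  tab <- tiny_table(p = 5, informative = integer(0), effect = 0, seed = 41)
  ens <- imbalance_adjusted_resample(tab$y, 150, seed = 6)
  res <- auc_632plus("f001", tab, ens)
  expect_true(all(res$auc_prime >= 0.5))
  expect_true(all(res$alpha >= 0.632 & res$alpha <= 1))
  expect_true(all(res$R >= 0 & res$R <= 1))
  below <- res$auc_oob < 0.5
  expect_gt(sum(below), 0)
  expect_equal(res$R[below], rep(1, sum(below)))
  expect_equal(res$alpha[below], rep(0.632 / (1 - 0.368), sum(below)))
  expect_equal(res$alpha[below], rep(1, sum(below)), tolerance = 1e-12)
  expect_equal(res$auc_prime[below], rep(0.5, sum(below)))
  none <- res$auc_oob >= res$auc_apparent & res$auc_oob >= 0.5
  if (any(none)) {
    expect_equal(res$R[none], rep(0, sum(none)))
    expect_equal(res$alpha[none], rep(0.632, sum(none)))
  }
  mid <- res$auc_oob >= 0.5 & res$auc_oob < res$auc_apparent
  if (any(mid)) {
    expect_equal(res$R[mid],
                 (res$auc_apparent - res$auc_oob[mid]) /
                   (res$auc_apparent - 0.5))
    expect_equal(res$alpha[mid], 0.632 / (1 - 0.368 * res$R[mid]))
  }
  # the estimate is a convex combination of its components
  expect_gte(res$estimate, min(res$auc_prime, res$auc_apparent))
  expect_lte(res$estimate, max(res$auc_prime, res$auc_apparent))
})

test_that("a strongly separable feature leaves no overfitting signal", {
  tab <- tiny_table(p = 4, informative = 1, effect = 6, seed = 10)
  ens <- imbalance_adjusted_resample(tab$y, 100, seed = 2)
  res <- auc_632plus("f001", tab, ens)
  expect_gt(res$estimate, 0.95)
  # with no overfitting the estimate reduces to
  # 0.368 * apparent + 0.632 * mean(AUC')
  r0 <- res$R == 0
  if (all(r0))
    expect_equal(res$estimate,
                 0.368 * res$auc_apparent + 0.632 * mean(res$auc_prime))
})

test_that("order-1 forward selection is exhaustive over starters", {
  tab <- tiny_table(p = 8, informative = 1:2, effect = 2, seed = 33)
  ens <- imbalance_adjusted_resample(tab$y, 60, seed = 5)
  fs <- forward_select(colnames(tab$X), tab, ens, orders = 1)
  all1 <- vapply(colnames(tab$X), function(f)
    auc_632plus(f, tab, ens)$estimate, numeric(1))
  expect_equal(fs$per_order$order1$features, names(which.max(all1)))
  expect_equal(fs$per_order$order1$auc, max(all1))
})

test_that("choose_order takes the argmax with ties to the smaller order", {
  fake <- function(aucs) structure(list(
    per_order = lapply(aucs, function(a) list(features = "x", auc = a)),
    orders = seq_along(aucs)), class = "model_search")
  expect_equal(choose_order(fake(c(0.7, 0.9, 0.85))), 2)
  expect_equal(choose_order(fake(c(0.9, 0.9))), 1)
  expect_equal(choose_order(fake(seq(0.5, 0.95, length.out = 10))), 10)
})

test_that("selection on pure noise does not fabricate strong models", {
  aucs <- vapply(1:5, function(s) {
    tab <- generate_feature_table(table_spec(p_features = 6,
                                             informative_idx = integer(0),
                                             seed = 200 + s))
    ens <- imbalance_adjusted_resample(tab$y, 50, seed = s)
    fs <- forward_select(colnames(tab$X), tab, ens, orders = 1:3)
    fs$per_order[[paste0("order", fs$chosen_order)]]$auc
  }, numeric(1))
  expect_gte(mean(aucs <= 0.75), 0.8)
})

test_that("coefficient averaging matches its degenerate and recovery contracts", {
  tab <- tiny_table(p = 3, informative = 1, effect = 2, seed = 3)
  ens1 <- imbalance_adjusted_resample(tab$y, 1, seed = 8)
  m1 <- average_coefficients("f001", tab, ens1)
  idx <- ens1$inbag[[1]]
  const <- gliorad:::standardize_constants(tab$X[, "f001", drop = FALSE])
  Xs <- gliorad:::apply_standardize(tab$X[, "f001", drop = FALSE], const)
  direct <- fit_logistic(Xs[idx, , drop = FALSE], tab$y[idx], quiet = TRUE)
  expect_equal(unname(m1$coefficients), unname(direct))
  # parameter recovery on simulated data with known coefficients
  set.seed(55)
  n <- 1000
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  y <- rbinom(n, 1, plogis(0.5 + X %*% c(1.2, -0.8)))
  ft <- feature_table(X, y)
  ens <- imbalance_adjusted_resample(y, 60, seed = 4, mode = "uniform")
  m <- average_coefficients(c("u", "v"), ft, ens, ridge = 1e-6)
  # back-transform the standardized-scale model to the raw scale
  slopes <- m$coefficients[-1] / m$scale
  intercept <- m$coefficients[1] - sum(m$coefficients[-1] * m$center / m$scale)
  truth <- c(0.5, 1.2, -0.8)
  expect_lt(max(abs(c(intercept, slopes) - truth) / abs(truth)), 0.2)
  # and the bootstrap average tracks the full-sample maximum likelihood fit
  mle <- unname(coef(glm(y ~ X, family = binomial())))
  expect_lt(max(abs(c(intercept, slopes) - mle)), 0.1)
})

test_that("predicted probabilities follow the logistic transform", {
  model <- structure(list(features = "a", coefficients = c(1, -2),
                          center = c(a = 0), scale = c(a = 1),
                          ridge = 1e-4, B = 1), class = "fitted_logistic")
  expect_equal(unname(predict_probability(model, c(a = 0.5))), 0.5)
  expect_gt(predict_probability(model, c(a = -100)), 1 - 1e-12)
  expect_lt(predict_probability(model, c(a = 100)), 1e-12)
  expect_error(predict_probability(model, c(b = 1)), "missing feature")
  # linear predictor 0 -> 0.5 through a fitted model
  tab <- tiny_table(p = 3, seed = 2)
  ens <- imbalance_adjusted_resample(tab$y, 10, seed = 1)
  m <- average_coefficients("f001", tab, ens)
  x0 <- (-m$coefficients[1] / m$coefficients[2]) * m$scale["f001"] +
    m$center["f001"]
  expect_equal(unname(predict_probability(m, c(f001 = unname(x0)))), 0.5)
})
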