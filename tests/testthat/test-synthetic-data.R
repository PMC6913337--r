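test_that("phantom generation is deterministic under a fixed seed", {
  cfg <- phantom_config(grid_shape = c(20, 20, 20), lesion_radius = 5,
                        seed = 42)
  a <- generate_phantom(cfg, 1)
  b <- generate_phantom(cfg, 1)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$mask, b$mask)
  d <- generate_phantom(cfg, 0)
  expect_false(identical(a$volumes$T1, d$volumes$T1))
})

test_that("lesion mask voxel count approximates the analytic ellipsoid volume", {
  cfg <- phantom_config(grid_shape = c(24, 24, 24), spacing = c(1, 1, 1),
                        lesion_radius = 5, seed = 1)
  st <- generate_phantom(cfg, 0)
  expect_lt(abs(sum(st$mask) - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3), 0.10)
  # convergence: finer spacing gets closer to the analytic volume in mm^3
  cfg2 <- phantom_config(grid_shape = c(44, 44, 44), spacing = c(0.5, 0.5, 0.5),
                         lesion_radius = 5, seed = 1)
  st2 <- generate_phantom(cfg2, 0)
  vol_true <- 4 / 3 * pi * 5^3
  err1 <- abs(sum(st$mask) * 1 - vol_true)
  err2 <- abs(sum(st2$mask) * 0.125 - vol_true)
  expect_lt(err2, err1)
})

test_that("identical class texture parameters give no class separation", {
  pars <- default_texture_params()
  pars$necrosis <- pars$recurrence
  means <- sapply(0:1, function(lab) {
    sapply(1:10, function(i) {
      cfg <- phantom_config(grid_shape = c(16, 16, 16), lesion_radius = 4,
                            class_texture_params = pars, seed = 100 + i)
      st <- generate_phantom(cfg, lab)
      mean(st$volumes$T1[st$mask == 1])
    })
  })
  se <- sqrt(var(means[, 1]) / 10 + var(means[, 2]) / 10)
  expect_lt(abs(mean(means[, 1]) - mean(means[, 2])), 2 * se + 1e-9)
})

test_that("phantom config rejects invalid geometry", {
  expect_error(phantom_config(grid_shape = c(4, 20, 20)), "grid_shape")
  expect_error(phantom_config(lesion_radius = 30,
                              grid_shape = c(16, 16, 16)), "fit")
  expect_error(phantom_config(spacing = c(1, -1, 1)), "spacing")
})

test_that("feature tables honor the configured class sizes", {
  tab <- generate_feature_table(table_spec(n_pos = 16, n_neg = 35,
                                           p_features = 10, seed = 3))
  expect_equal(sum(tab$y == 1), 16)
  expect_equal(sum(tab$y == 0), 35)
  expect_equal(dim(tab$X), c(51, 10))
})

test_that("informative columns carry the configured standardized shift", {
  tab <- generate_feature_table(table_spec(n_pos = 100, n_neg = 100,
                                           p_features = 10,
                                           informative_idx = 1:3,
                                           effect_size = 2, seed = 5))
  for (j in 1:3) {
    x1 <- tab$X[tab$y == 1, j]; x0 <- tab$X[tab$y == 0, j]
    smd <- (mean(x1) - mean(x0)) /
      sqrt(((length(x1) - 1) * var(x1) + (length(x0) - 1) * var(x0)) /
             (length(x1) + length(x0) - 2))
    expect_lt(abs(smd - 2), 0.3)
  }
})

test_that("zero effect size yields no informative signal", {
  sig <- t(vapply(1:500, function(s) {
    tab <- generate_feature_table(table_spec(n_pos = 16, n_neg = 35,
                                             p_features = 3,
                                             informative_idx = 1:3,
                                             effect_size = 0, seed = s))
    vapply(1:3, function(j)
      t.test(tab$X[tab$y == 1, j], tab$X[tab$y == 0, j])$p.value < 0.05,
      logical(1))
  }, logical(3)))
  # each nominal informative column is non-significant in >= 90% of seeds
  for (j in 1:3) expect_gte(mean(!sig[, j]), 0.9)
})

test_that("table generation is deterministic and validates its spec", {
  s <- table_spec(p_features = 6, seed = 9)
  expect_identical(generate_feature_table(s)$X, generate_feature_table(s)$X)
  expect_error(table_spec(p_features = 2, informative_idx = 1:5),
               "informative")
  expect_error(table_spec(effect_size = -1), "effect_size")
  expect_error(table_spec(block_correlation = 1), "block_correlation")
})

test_that("NIfTI study round trip preserves volumes, mask, spacing, label", {
  cfg <- phantom_config(grid_shape = c(14, 14, 10), spacing = c(1, 1, 2),
                        lesion_radius = 3.5, seed = 8)
  st <- generate_phantom(cfg, 1)
  d <- withr::local_tempdir()
  write_study(st, d)
  st2 <- read_study(d)
  expect_equal(st2$volumes$FLAIR, st$volumes$FLAIR, tolerance = 1e-6)
  expect_identical(st2$mask, st$mask)
  expect_equal(st2$spacing, st$spacing)
  expect_equal(st2$label, 1L)
})

test_that("feature CSV round trip is faithful and has the contracted layout", {
  tab <- tiny_table(p = 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  hdr <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_equal(gsub("\"", "", hdr[1]), "patient_id")
  expect_equal(gsub("\"", "", hdr[length(hdr)]), "label")
  tab2 <- read_feature_table(f)
  expect_equal(tab2$X, tab$X, tolerance = 1e-12)
  expect_identical(tab2$y, tab$y)
})
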