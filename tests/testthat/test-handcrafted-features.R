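test_that("nontexture features match closed forms on canonical shapes", {
  m <- array(0L, c(5, 5, 5)); m[3, 3, 3] <- 1L
  f <- nontexture_features(m, c(1, 1, 1))
  expect_equal(unname(f), c(1, 0, 1, 0))
  cube <- array(0L, c(12, 12, 12)); cube[2:11, 2:11, 2:11] <- 1L
  f <- nontexture_features(cube, c(1, 1, 1))
  expect_equal(unname(f["Volume"]), 1000)
  expect_equal(unname(f["Solidity"]), 1)
  expect_equal(unname(f["Eccentricity"]), 0)
  expect_equal(unname(f["Size"]), sqrt(3 * 81))
  block <- array(0L, c(12, 6, 6)); block[2:11, 2:5, 2:5] <- 1L
  f <- nontexture_features(block, c(1, 1, 1))
  # exhaustive pairwise-distance oracle over all mask voxel centers
  w <- which(block == 1, arr.ind = TRUE)
  expect_equal(unname(f["Size"]), max(dist(w)))
  expect_equal(unname(f["Size"]), sqrt(81 + 9 + 9))
})

test_that("anisotropic spacing scales volume and size in mm", {
  m <- array(0L, c(8, 8, 8)); m[2:5, 2:3, 2:3] <- 1L
  f <- nontexture_features(m, c(2, 1, 0.5))
  expect_equal(unname(f["Volume"]), 16 * prod(c(2, 1, 0.5)))
  w <- which(m == 1, arr.ind = TRUE)
  expect_equal(unname(f["Size"]),
               max(dist(sweep(w, 2, c(2, 1, 0.5), "*"))))
})

test_that("global moments match their closed forms", {
  g <- global_stats(c(1, 1, 2, 2))
  expect_equal(unname(g["Variance"]), 0.25)
  expect_equal(unname(g["Skewness"]), 0)
  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(unname(global_stats(sym)["Skewness"]), 0)
  expect_warning(g0 <- global_stats(rep(4, 6)), "constant")
  expect_equal(unname(g0), c(0, 0, 0))
})

test_that("GLCM equals the pairwise-enumeration oracle and its contracts", {
  for (seed in 1:4) {
    lv <- random_levels(c(4, 4, 3), n_gray = 4, seed = seed)
    if (sum(lv > 0) < 2) next
    M <- gliorad:::cpp_glcm(as.integer(lv), dim(lv), 4L)
    expect_equal(unname(M), unname(oracle_glcm(lv, 4)))
    P <- M / sum(M)
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))
  }
  # hand case: 2 voxels, levels 1 and 2
  lv <- array(0L, c(2, 1, 1)); lv[] <- c(1L, 2L)
  s <- glcm_stats(lv, 2)
  expect_equal(unname(s["Contrast"]), 1)
  expect_equal(unname(s["Energy"]), 0.5)
  # constant ROI: single-cell matrix, degenerate correlation imputed
  lv <- array(2L, c(3, 3, 1))
  expect_warning(s <- glcm_stats(lv, 4), "Correlation imputed")
  expect_equal(unname(s[c("Energy", "Contrast", "Entropy")]), c(1, 0, 0))
  expect_equal(unname(s["Correlation"]), 0)
})

test_that("GLRLM equals the line-walking rle oracle and its examples", {
  for (seed in 1:4) {
    lv <- random_levels(c(4, 3, 4), n_gray = 3, seed = 10 + seed)
    if (sum(lv > 0) < 1) next
    M <- gliorad:::cpp_glrlm(as.integer(lv), dim(lv), 3L)
    O <- oracle_glrlm(lv, 3)
    expect_equal(unname(M), unname(O[, seq_len(ncol(M)), drop = FALSE]))
  }
  lv <- array(0L, c(3, 1, 1)); lv[] <- 2L
  s <- glrlm_stats(lv, 2)
  expect_equal(unname(s["HGRE"]), 4)
  # alternating line: every run in every direction has length 1
  lv <- array(0L, c(6, 1, 1)); lv[] <- rep(c(1L, 2L), 3)
  s <- glrlm_stats(lv, 2)
  expect_equal(unname(s["SRE"]), 1)
  expect_equal(unname(s["LRE"]), 1)
  expect_gt(unname(s["RP"]), 0)
  expect_lte(unname(s["RP"]), 1)
})

test_that("GLSZM zones equal the label-propagation oracle and partition the ROI", {
  for (seed in 1:4) {
    lv <- random_levels(c(4, 4, 3), n_gray = 3, seed = 20 + seed)
    if (sum(lv > 0) < 1) next
    Z <- gliorad:::cpp_glszm_zones(as.integer(lv), dim(lv))
    O <- oracle_glszm_zones(lv)
    expect_equal(sum(Z[, 2]), sum(lv > 0)) # zones partition the ROI
    zs <- function(df) df[order(df[, 1], df[, 2]), ]
    expect_equal(zs(as.data.frame(Z))[, 1], zs(O)$level,
                 ignore_attr = TRUE)
    expect_equal(zs(as.data.frame(Z))[, 2], zs(O)$size,
                 ignore_attr = TRUE)
  }
  lv <- array(3L, c(2, 2, 1))
  s <- glszm_stats(lv, 4)
  expect_equal(unname(s["HGZE"]), 9)
  expect_equal(unname(s["SZHGE"]), 9 / 16)
  # alternating line: every 26-connected zone is a single voxel
  lv <- array(0L, c(6, 1, 1)); lv[] <- rep(c(1L, 2L), 3)
  s <- glszm_stats(lv, 2)
  expect_equal(unname(s["SZE"]), 1)
})

test_that("NGTDM accumulators equal the direct neighbour-enumeration oracle", {
  for (seed in 1:4) {
    lv <- random_levels(c(4, 3, 3), n_gray = 4, seed = 30 + seed)
    if (sum(lv > 0) < 2) next
    res <- gliorad:::cpp_ngtdm(as.integer(lv), dim(lv), 4L)
    O <- oracle_ngtdm(lv, 4)
    expect_equal(res$s, O$s)
    expect_equal(res$n, O$n)
  }
  # hand case on a 3x1x1 two-level line
  lv <- array(0L, c(3, 1, 1)); lv[] <- c(1L, 2L, 1L)
  res <- gliorad:::cpp_ngtdm(as.integer(lv), dim(lv), 2L)
  expect_equal(res$s, c(abs(1 - 2) + abs(1 - 2), abs(2 - 1)))
  expect_equal(res$n, c(2L, 1L))
  expect_equal(unname(ngtdm_stats(array(2L, c(3, 3, 3)), 4)["Contrast"]), 0)
  lv <- random_levels(c(4, 4, 4), 4, seed = 3)
  co <- unname(ngtdm_stats(lv, 4)["Coarseness"])
  expect_true(is.finite(co) && co > 0)
})

test_that("texture statistics are shift-invariant under equal-probability quantization", {
  set.seed(4)
  dm <- c(6, 6, 6)
  vol <- array(rnorm(prod(dm)), dm)
  mask <- array(1L, dm)
  stats_of <- function(v) {
    lev <- array(0L, dm)
    lev[] <- quantize(as.numeric(v), "equal", 8)
    gliorad:::texture_statistics(lev, 8)
  }
  expect_equal(stats_of(vol), stats_of(vol + 100))
})

test_that("feature counts match the per-modality and whole-study contracts", {
  grid <- texture_grid()
  expect_length(grid$params, 240)
  expect_length(grid$stat_names, 43)
  cfg <- phantom_config(grid_shape = c(18, 18, 18), lesion_radius = 4,
                        seed = 13)
  st <- generate_phantom(cfg, 1)
  ft1 <- extract_handcrafted(st, grid, modalities = "T1")
  expect_equal(ncol(ft1$X), 4 + 10320)
  ft4 <- extract_handcrafted(st, grid)
  expect_equal(ncol(ft4$X), 41284)
  expect_false(anyDuplicated(colnames(ft4$X)) > 0)
  expect_true(all(is.finite(ft4$X)))
  expect_equal(ft4$y, 1L)
})

test_that("extraction is deterministic for identical studies", {
  cfg <- phantom_config(grid_shape = c(16, 16, 16), lesion_radius = 4,
                        seed = 2)
  st <- generate_phantom(cfg, 0)
  small <- texture_grid(ratios = c(1, 2), scales = c(1, 2),
                        quantizers = "equal", n_grays = 8)
  a <- extract_handcrafted(list(st, st), small, modalities = c("T1", "T2"))
  expect_equal(a$X[1, ], a$X[2, ])
  expect_equal(ncol(a$X), 4 + 2 * length(small$params) * 43)
})
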