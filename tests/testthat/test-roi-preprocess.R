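test_that("bounding box is tight, idempotent, and rejects empty masks", {
  m <- array(0L, c(6, 8, 5))
  m[2, 3, 4] <- 1L
  b <- bounding_box(m)
  expect_equal(unname(b$min), c(2, 3, 4))
  expect_equal(unname(b$max), c(2, 3, 4))
  m[c(1, 4), c(1, 6), c(1, 2)] <- 1L
  b <- bounding_box(m)
  expect_equal(unname(b$min), c(1, 1, 1))
  expect_equal(unname(b$max), c(4, 6, 4))
  expect_error(bounding_box(array(0L, c(3, 3, 3))), "empty")
  # property: random masks are contained and every face is touched
  set.seed(7)
  for (i in 1:5) {
    m <- array(as.integer(runif(7 * 6 * 5) < 0.2), c(7, 6, 5))
    if (sum(m) == 0) m[3, 3, 3] <- 1L
    b <- bounding_box(m)
    w <- which(m == 1, arr.ind = TRUE)
    for (d in 1:3) {
      expect_true(all(w[, d] >= b$min[d] & w[, d] <= b$max[d]))
      expect_true(any(w[, d] == b$min[d]) && any(w[, d] == b$max[d]))
    }
    cropped <- crop_to_box(m, b)
    expect_equal(unname(bounding_box(cropped)$min), c(1, 1, 1))
  }
})

make_slice_study <- function(areas) {
  dm <- c(12, 12, length(areas))
  mask <- array(0L, dm)
  for (z in seq_along(areas))
    if (areas[z] > 0) mask[seq_len(areas[z]), 1, z] <- 1L
  vols <- list(T1 = array(rnorm(prod(dm)), dm))
  multimodal_study(vols, mask, c(1, 1, 1), 0)
}

test_that("largest-area slice selection follows the argmax and tie rules", {
  st <- make_slice_study(c(3, 9, 5))
  expect_equal(largest_area_slice_triplet(st, "T1")$central_index, 2)
  st <- make_slice_study(c(7, 7, 2))
  expect_equal(largest_area_slice_triplet(st, "T1")$central_index, 1)
})

test_that("slice triplet clamps neighbours at the box boundary", {
  st <- make_slice_study(c(0, 4, 0))
  tr <- largest_area_slice_triplet(st, "T1")
  expect_identical(tr$previous, tr$central)
  expect_identical(tr[["next"]], tr$central)
  st <- make_slice_study(c(5, 4, 3))
  tr <- largest_area_slice_triplet(st, "T1")
  expect_identical(tr$previous, tr$central) # box starts at the central slice
  expect_identical(tr[["next"]], st$volumes$T1[, , 2])
})

test_that("isotropic resampling is exact on identity and constants and conserves volume", {
  v <- array(rnorm(10 * 10 * 10), c(10, 10, 10))
  m <- array(0L, c(10, 10, 10)); m[4:7, 4:7, 4:7] <- 1L
  out <- resample_isotropic(v, m, c(1, 1, 1), 1)
  expect_identical(out$volume, v)
  expect_identical(out$mask, m)
  cv <- array(3.5, c(9, 11, 7))
  cm <- array(1L, c(9, 11, 7))
  out <- resample_isotropic(cv, cm, c(1, 1, 1), 1.7)
  expect_true(all(abs(out$volume - 3.5) < 1e-12))
  # volume conservation on a 20-voxel-wide lesion, 1 mm -> 2 mm
  dm <- c(24, 24, 24)
  mask <- array(0L, dm)
  ctr <- 12.5
  w <- which(array(TRUE, dm), arr.ind = TRUE)
  r2 <- rowSums(sweep(w, 2, ctr)^2)
  mask[w[r2 <= 100, ]] <- 1L
  vol <- array(rnorm(prod(dm)), dm)
  out <- resample_isotropic(vol, mask, c(1, 1, 1), 2)
  v_in <- sum(mask) * 1
  v_out <- sum(out$mask) * 8
  expect_lt(abs(v_out - v_in) / v_in, 0.15)
  expect_error(resample_isotropic(vol, mask, c(1, 1, 1), -2), "positive")
})

test_that("wavelet band-pass reconstructs, kills constants at ratio 0, and is linear", {
  set.seed(11)
  for (dm in list(c(8, 8, 8), c(13, 10, 9))) {
    v <- array(rnorm(prod(dm)), dm)
    expect_lt(max(abs(wavelet_bandpass(v, 1) - v)), 1e-6)
  }
  cv <- array(7, c(8, 8, 8))
  expect_lt(max(abs(wavelet_bandpass(cv, 0))), 1e-8)
  v <- array(rnorm(12^3), c(12, 12, 12))
  expect_lt(max(abs(wavelet_bandpass(5 * v, 0.5) - 5 * wavelet_bandpass(v, 0.5))),
            1e-8)
  # haar basis honors the same contracts
  expect_lt(max(abs(wavelet_bandpass(v, 1, wavelet = "haar") - v)), 1e-6)
})

test_that("quantizers match their stated examples and range contract", {
  expect_equal(quantize(1:8, "equal", 2), c(1, 1, 1, 1, 2, 2, 2, 2))
  expect_equal(quantize(c(0, 10), "uniform", 2), c(1, 2))
  set.seed(5)
  for (q in c("equal", "uniform", "lloyd")) {
    v <- rnorm(200)
    lev <- quantize(v, q, 16)
    expect_gte(min(lev), 1)
    expect_lte(max(lev), 16)
    expect_equal(sort(unique(lev))[1], 1)
  }
  expect_warning(out <- quantize(rep(2, 5), "equal", 4), "constant")
  expect_equal(out, rep(1L, 5))
})

test_that("equal-probability bins are balanced for distinct values", {
  set.seed(9)
  v <- rnorm(64)
  for (ng in c(2, 4, 8)) {
    counts <- table(quantize(v, "equal", ng))
    expect_lte(diff(range(counts)), 1)
  }
})

test_that("lloyd quantizer converges to the two cluster centers on bimodal data", {
  v <- c(rnorm(60, 0, 0.1), rnorm(40, 10, 0.1))
  lev <- quantize(v, "lloyd", 2)
  expect_equal(unname(lev), rep(c(1L, 2L), c(60, 40)))
})

test_that("extraction params are validated", {
  expect_error(extraction_params(ratio_R = -1), "ratio_R")
  expect_error(extraction_params(scale_mm = 0), "scale_mm")
  expect_error(extraction_params(n_gray = 1), "n_gray")
  expect_equal(extraction_params(quantizer = "lloyd")$quantizer, "lloyd")
})
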