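#' Tight bounding box of a binary mask
#'
#' @param mask 3D binary array with at least one nonzero voxel.
#' @return object of class `box`: list with per-axis inclusive `min` and
#'   `max` voxel indices (1-based).
#' @export
bounding_box <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (nrow(w) == 0) stopf("empty mask: no bounding box")
  structure(list(min = apply(w, 2, min), max = apply(w, 2, max)),
            class = "box")
}

#' Crop an array to a bounding box
#'
#' @param arr 3D array.
#' @param box a [bounding_box()].
#' @return cropped array.
#' @export
crop_to_box <- function(arr, box) {
  arr[box$min[1]:box$max[1], box$min[2]:box$max[2], box$min[3]:box$max[3],
      drop = FALSE]
}

#' Axial slice triplet around the largest-tumor-area slice
#'
#' Finds the axial (third-axis) slice with the largest in-mask area (ties
#' broken toward the smallest index), and returns it with its two
#' neighbours, clamped (duplicated) at the mask bounding box boundaries.
#'
#' @param study a [multimodal_study()].
#' @param modality modality name to slice.
#' @return object of class `slice_triplet`: 2D matrices `previous`,
#'   `central`, `next`, the `central_index`, and the mask `box`.
#' @export
largest_area_slice_triplet <- function(study, modality) {
  stopifnot(inherits(study, "multimodal_study"))
  if (!modality %in% names(study$volumes))
    stopf("unknown modality '%s'", modality)
  areas <- apply(study$mask, 3, sum)
  if (all(areas == 0)) stopf("empty mask: no axial slice to extract")
  z <- which.max(areas) # ties -> smallest index
  box <- bounding_box(study$mask)
  zprev <- max(z - 1L, box$min[3])
  znext <- min(z + 1L, box$max[3])
  vol <- study$volumes[[modality]]
  structure(list(previous = vol[, , zprev], central = vol[, , z],
                 "next" = vol[, , znext], central_index = z, box = box),
            class = "slice_triplet")
}

# ---- wavelet machinery -----------------------------------------------------

# Orthonormal filter banks. sym8 coefficients are the standard published
# Symlet-8 values; haar is included for tests and cheap configurations.
wavelet_filters <- function(wavelet = c("sym8", "haar")) {
  wavelet <- match.arg(wavelet)
  if (wavelet == "haar") {
    lo <- c(1, 1) / sqrt(2)
  } else {
    lo <- c(-0.00338241595100613, -0.00054213233179115, 0.03169508781149298,
            0.00760748732491761, -0.14329423835080970, -0.06127335906765852,
            0.48135965125837220, 0.77718575170052350, 0.36444189483533140,
            -0.05194583810770904, -0.02721902991705600, 0.04913717967360751,
            0.00380875201389062, -0.01495225833704823, -0.00030292051472137,
            0.00188995033275946)
  }
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  list(lo = lo, hi = hi)
}

# Orthogonal one-level periodized DWT matrix for even length n: the first
# n/2 rows are even circular shifts of the low-pass filter, the rest of the
# high-pass filter. Orthonormality gives exact inversion by the transpose.
dwt_matrix <- function(n, wavelet = "sym8") {
  key <- paste0(wavelet, "_", n)
  cache <- getOption("gliorad.dwt_cache", NULL)
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    options(gliorad.dwt_cache = cache)
  }
  if (!is.null(cache[[key]])) return(cache[[key]])
  f <- wavelet_filters(wavelet)
  L <- length(f$lo)
  W <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    for (m in seq_len(L)) {
      col <- ((2 * (k - 1) + m - 1) %% n) + 1
      W[k, col] <- W[k, col] + f$lo[m]
      W[n / 2 + k, col] <- W[n / 2 + k, col] + f$hi[m]
    }
  }
  cache[[key]] <- W
  W
}

apply_along <- function(a, d, M) {
  perm <- c(d, setdiff(1:3, d))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  out <- M %*% matrix(ap, nrow = dp[1])
  aperm(array(out, dim = c(nrow(M), dp[2], dp[3])), order(perm))
}

#' Wavelet band-pass filtering of a 3D volume
#'
#' One-level 3D discrete wavelet decomposition (default sym8, periodized);
#' the lowest (LLL) and highest (HHH) sub-bands are weighted by `ratio_R`
#' and the six band-pass sub-bands by 1, then the volume is reconstructed.
#' `ratio_R = 1` reproduces the input to numerical precision; `ratio_R < 1`
#' emphasizes band-pass structure, `> 1` the extremes. Odd dimensions are
#' padded internally by edge replication and cropped after reconstruction.
#'
#' @param volume 3D numeric array.
#' @param ratio_R nonnegative weight of the LLL and HHH sub-bands.
#' @param wavelet `"sym8"` (default) or `"haar"`.
#' @return filtered volume, same shape as the input.
#' @export
wavelet_bandpass <- function(volume, ratio_R, wavelet = "sym8") {
  if (ratio_R < 0) stopf("ratio_R must be >= 0")
  dm0 <- dim(volume)
  if (length(dm0) != 3) stopf("volume must be a 3D array")
  a <- volume
  # pad odd axes by replicating the final slice
  for (d in 1:3) {
    if (dim(a)[d] %% 2 == 1) {
      idx <- c(seq_len(dim(a)[d]), dim(a)[d])
      a <- switch(d, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                  a[, , idx, drop = FALSE])
    }
  }
  dm <- dim(a)
  Ws <- lapply(1:3, function(d) dwt_matrix(dm[d], wavelet))
  for (d in 1:3) a <- apply_along(a, d, Ws[[d]])
  lo <- lapply(dm, function(n) seq_len(n / 2))
  hi <- lapply(dm, function(n) (n / 2 + 1):n)
  a[lo[[1]], lo[[2]], lo[[3]]] <- a[lo[[1]], lo[[2]], lo[[3]]] * ratio_R
  a[hi[[1]], hi[[2]], hi[[3]]] <- a[hi[[1]], hi[[2]], hi[[3]]] * ratio_R
  for (d in 1:3) a <- apply_along(a, d, t(Ws[[d]]))
  a[seq_len(dm0[1]), seq_len(dm0[2]), seq_len(dm0[3]), drop = FALSE]
}

# ---- resampling ------------------------------------------------------------

trilinear_sample <- function(vol, ix, iy, iz) {
  dm <- dim(vol)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  x0 <- cl(floor(ix), dm[1]); x1 <- cl(x0 + 1, dm[1]); fx <- cl(ix, dm[1]) - x0
  y0 <- cl(floor(iy), dm[2]); y1 <- cl(y0 + 1, dm[2]); fy <- cl(iy, dm[2]) - y0
  z0 <- cl(floor(iz), dm[3]); z1 <- cl(z0 + 1, dm[3]); fz <- cl(iz, dm[3]) - z0
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  lin <- function(i, j, k) {
    outer(outer(i, (j - 1) * dm[1], "+"), (k - 1) * dm[1] * dm[2], "+")
  }
  wt <- function(wx, wy, wz) outer(outer(wx, wy), wz)
  out <- array(0, dim = c(nx, ny, nz))
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    xi <- if (a == 0) x0 else x1
    yj <- if (b == 0) y0 else y1
    zk <- if (cc == 0) z0 else z1
    w <- wt(if (a == 0) 1 - fx else fx,
            if (b == 0) 1 - fy else fy,
            if (cc == 0) 1 - fz else fz)
    out <- out + w * vol[lin(xi, yj, zk)]
  }
  out
}

#' Resample a volume and mask to an isotropic grid
#'
#' Trilinear interpolation for intensities, nearest neighbour for the mask.
#' The new grid keeps the world extent of the input (voxel centers at
#' multiples of `scale_mm` from the first voxel center).
#'
#' @param volume 3D numeric array.
#' @param mask 3D binary array, same shape.
#' @param spacing input voxel spacing in mm (length 3).
#' @param scale_mm target isotropic voxel size in mm.
#' @return list with `volume`, `mask`, and `spacing` (the new spacing).
#' @export
resample_isotropic <- function(volume, mask, spacing, scale_mm) {
  if (any(spacing <= 0) || scale_mm <= 0)
    stopf("spacing and scale_mm must be positive")
  dm <- dim(volume)
  if (all(abs(spacing - scale_mm) < 1e-12)) {
    return(list(volume = volume,
                mask = array(as.integer(mask != 0), dm),
                spacing = rep(scale_mm, 3)))
  }
  new_n <- pmax(1L, as.integer(round((dm - 1) * spacing / scale_mm)) + 1L)
  idx <- lapply(1:3, function(d) {
    (seq_len(new_n[d]) - 1) * scale_mm / spacing[d] + 1
  })
  vol_out <- trilinear_sample(volume, idx[[1]], idx[[2]], idx[[3]])
  ri <- lapply(1:3, function(d) pmin(pmax(round(idx[[d]]), 1), dm[d]))
  mask_out <- array(as.integer(mask != 0), dm)[as.matrix(
    expand.grid(ri[[1]], ri[[2]], ri[[3]]))]
  mask_out <- array(mask_out, dim = new_n)
  if (sum(mask_out) == 0)
    stopf("mask is empty after resampling to %.3g mm", scale_mm)
  list(volume = vol_out, mask = mask_out, spacing = rep(scale_mm, 3))
}

# ---- quantization ----------------------------------------------------------

#' Gray-level quantization of in-mask intensities
#'
#' Maps intensities to integer levels `1..n_gray`.
#' * `equal`: equal-probability (quantile) bins; ties share a level.
#' * `uniform`: equal-width bins over `[min, max]`.
#' * `lloyd`: Lloyd-Max iterative quantizer (1D k-means with deterministic
#'   equally spaced initial centroids).
#'
#' @param values numeric vector of in-mask intensities (length >= 1).
#' @param quantizer `"equal"`, `"uniform"`, or `"lloyd"`.
#' @param n_gray number of gray levels (>= 2).
#' @return integer vector of levels in `1..n_gray`.
#' @export
quantize <- function(values, quantizer = c("equal", "uniform", "lloyd"),
                     n_gray = 32L) {
  quantizer <- match.arg(quantizer)
  if (length(values) < 1) stopf("need at least one value to quantize")
  if (n_gray < 2) stopf("n_gray must be >= 2")
  rng <- range(values)
  if (diff(rng) == 0) {
    warnf("constant input: all values mapped to gray level 1")
    return(rep(1L, length(values)))
  }
  n <- length(values)
  lev <- switch(quantizer,
    equal = {
      r <- rank(values, ties.method = "max")
      pmin(as.integer(floor(n_gray * (r - 1) / n)) + 1L, n_gray)
    },
    uniform = {
      pmin(as.integer(floor((values - rng[1]) / diff(rng) * n_gray)) + 1L,
           n_gray)
    },
    lloyd = {
      centers <- seq(rng[1], rng[2], length.out = n_gray)
      assign_lev <- function(ctr) {
        bounds <- (ctr[-1] + ctr[-length(ctr)]) / 2
        findInterval(values, bounds) + 1L
      }
      for (it in 1:100) {
        lv <- assign_lev(centers)
        newc <- centers
        for (g in unique(lv)) newc[g] <- mean(values[lv == g])
        newc <- sort(newc)
        if (max(abs(newc - centers)) < 1e-10 * diff(rng)) {
          centers <- newc
          break
        }
        centers <- newc
      }
      as.integer(assign_lev(centers))
    })
  lev
}

#' Texture extraction parameters
#'
#' One point of the texture parameter grid: band-pass weighting ratio,
#' isotropic resampling scale, quantizer family, and gray-level count.
#'
#' @param ratio_R band-pass weighting ratio (> 0 in the default grid; 0 is
#'   allowed and zeroes the LLL/HHH sub-bands).
#' @param scale_mm isotropic voxel size in mm (> 0).
#' @param quantizer `"equal"`, `"uniform"`, or `"lloyd"`.
#' @param n_gray gray-level count (>= 2).
#' @return object of class `extraction_params`.
#' @export
extraction_params <- function(ratio_R = 1, scale_mm = 1,
                              quantizer = c("equal", "uniform", "lloyd"),
                              n_gray = 32L) {
  quantizer <- match.arg(quantizer)
  if (ratio_R < 0) stopf("ratio_R must be >= 0")
  if (scale_mm <= 0) stopf("scale_mm must be > 0")
  if (n_gray < 2) stopf("n_gray must be >= 2")
  structure(list(ratio_R = ratio_R, scale_mm = scale_mm,
                 quantizer = quantizer, n_gray = as.integer(n_gray)),
            class = "extraction_params")
}
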