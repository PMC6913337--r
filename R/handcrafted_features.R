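#' Names of the 43 texture statistics
#'
#' Three global histogram moments, nine co-occurrence (GLCM), thirteen
#' run-length (GLRLM), thirteen size-zone (GLSZM), and five neighbourhood
#' gray-tone difference (NGTDM) statistics, prefixed by family.
#'
#' @return character vector of length 43.
#' @export
texture_stat_names <- function() {
  c(paste0("global_", c("Variance", "Skewness", "Kurtosis")),
    paste0("glcm_", c("Energy", "Contrast", "Entropy", "Homogeneity",
                      "Correlation", "SumAverage", "Variance",
                      "Dissimilarity", "AutoCorrelation")),
    paste0("glrlm_", c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                       "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV")),
    paste0("glszm_", c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE",
                       "SZLGE", "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV")),
    paste0("ngtdm_", c("Coarseness", "Contrast", "Busyness", "Complexity",
                       "Strength")))
}

#' Texture extraction parameter grid
#'
#' The full factorial grid of [extraction_params()]. The default grid
#' (5 ratios x 4 scales x 3 quantizers x 4 gray-level counts = 240
#' combinations) times the 43 statistics yields 10,320 texture features
#' per modality.
#'
#' @param ratios band-pass weighting ratios.
#' @param scales isotropic resampling scales in mm.
#' @param quantizers quantizer algorithms.
#' @param n_grays gray-level counts.
#' @return object of class `texture_grid` with `params` (list of
#'   [extraction_params()]) and `stat_names`.
#' @export
texture_grid <- function(ratios = c(1 / 2, 2 / 3, 1, 3 / 2, 2),
                         scales = c(1, 2, 3, 4),
                         quantizers = c("equal", "uniform", "lloyd"),
                         n_grays = c(8, 16, 32, 64)) {
  combos <- expand.grid(n_gray = n_grays, quantizer = quantizers,
                        scale_mm = scales, ratio_R = ratios,
                        stringsAsFactors = FALSE)
  params <- lapply(seq_len(nrow(combos)), function(i) {
    extraction_params(ratio_R = combos$ratio_R[i],
                      scale_mm = combos$scale_mm[i],
                      quantizer = combos$quantizer[i],
                      n_gray = combos$n_gray[i])
  })
  structure(list(params = params, stat_names = texture_stat_names()),
            class = "texture_grid")
}

#' @export
print.texture_grid <- function(x, ...) {
  cat(sprintf("<texture_grid> %d parameter combinations x %d statistics = %d features per modality\n",
              length(x$params), length(x$stat_names),
              length(x$params) * length(x$stat_names)))
  invisible(x)
}

# ---- nontexture (shape) features -------------------------------------------

#' Nontexture shape features of a tumor mask
#'
#' * `Volume`: voxel count times voxel volume (mm^3).
#' * `Size`: maximum distance between surface-voxel centers (mm).
#' * `Solidity`: mask volume over convex-hull volume (hull of the surface
#'   voxels' corner points, so a solid cube has solidity exactly 1).
#' * `Eccentricity`: sqrt(1 - shortest/longest principal second-moment
#'   axis ratio squared).
#'
#' @param mask 3D binary array.
#' @param spacing voxel spacing in mm (length 3).
#' @return named numeric vector of the four features.
#' @export
nontexture_features <- function(mask, spacing) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (nrow(w) == 0) stopf("empty mask")
  nvox <- nrow(w)
  voxvol <- prod(spacing)
  volume <- nvox * voxvol
  centers <- sweep(w, 2, spacing, "*")
  if (nvox == 1)
    return(c(Volume = volume, Size = 0, Solidity = 1, Eccentricity = 0))
  # surface voxels: any 6-neighbour missing from the mask (or grid edge)
  dm <- dim(mask)
  is_surface <- rep(FALSE, nvox)
  lin <- function(m) m[, 1] + dm[1] * (m[, 2] - 1) + dm[1] * dm[2] * (m[, 3] - 1)
  inmask <- array(FALSE, dm)
  inmask[w] <- TRUE
  for (d in 1:3) for (s in c(-1L, 1L)) {
    nb <- w
    nb[, d] <- nb[, d] + s
    off <- nb[, d] < 1 | nb[, d] > dm[d]
    nb[, d] <- pmin(pmax(nb[, d], 1L), dm[d])
    is_surface <- is_surface | off | !inmask[cbind(nb[, 1], nb[, 2], nb[, 3])]
  }
  surf <- centers[is_surface, , drop = FALSE]
  hull_pts <- hull3d(surf)
  verts <- if (is.null(hull_pts)) surf else
    hull_pts$points[sort(unique(as.vector(hull_pts$faces))), , drop = FALSE]
  dmax <- if (nrow(verts) > 1) {
    dd <- as.matrix(stats::dist(verts))
    max(dd)
  } else 0
  # solidity from the hull of surface-voxel corners (center +/- half spacing)
  half <- spacing / 2
  corners <- do.call(rbind, lapply(1:8, function(i) {
    sgn <- c(if (bitwAnd(i - 1, 1L)) 1 else -1,
             if (bitwAnd(i - 1, 2L)) 1 else -1,
             if (bitwAnd(i - 1, 4L)) 1 else -1)
    sweep(surf, 2, sgn * half, "+")
  }))
  hv <- hull3d_volume(hull3d(corners))
  solidity <- if (hv > 0) min(volume / hv, 1) else 1
  ev <- eigen(stats::cov(centers), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ecc <- if (ev[1] > 0) sqrt(max(0, 1 - ev[length(ev)] / ev[1])) else 0
  c(Volume = volume, Size = dmax, Solidity = solidity, Eccentricity = ecc)
}

# ---- texture statistic families --------------------------------------------

#' Global histogram moments of ROI values
#'
#' Population variance, skewness and kurtosis (m4/m2^2) of the in-mask
#' values. Constant input yields variance 0 with skewness/kurtosis imputed
#' to 0 (with a warning).
#'
#' @param values numeric vector (length >= 2).
#' @return named vector `Variance`, `Skewness`, `Kurtosis`.
#' @export
global_stats <- function(values) {
  if (length(values) < 2) stopf("need at least 2 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) {
    warnf("constant ROI: skewness/kurtosis imputed to 0")
    return(c(Variance = 0, Skewness = 0, Kurtosis = 0))
  }
  c(Variance = m2,
    Skewness = mean((values - m)^3) / m2^1.5,
    Kurtosis = mean((values - m)^4) / m2^2)
}

#' Gray-level co-occurrence statistics
#'
#' A single 3D co-occurrence matrix aggregated over all 13 3D directions at
#' distance 1, restricted to in-mask voxel pairs, symmetrized and
#' normalized to sum 1.
#'
#' @param levels 3D integer array of quantized levels; 0 marks voxels
#'   outside the mask.
#' @param n_gray gray-level count.
#' @return named vector of the 9 GLCM statistics.
#' @export
glcm_stats <- function(levels, n_gray) {
  M <- cpp_glcm(as.integer(levels), dim(levels), as.integer(n_gray))
  tot <- sum(M)
  if (tot == 0) stopf("no valid in-mask voxel pair for the GLCM")
  P <- M / tot
  i <- row(P); j <- col(P)
  pi_marg <- rowSums(P)
  g <- seq_len(n_gray)
  mu <- sum(g * pi_marg)
  sig2 <- sum((g - mu)^2 * pi_marg)
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else {
    warnf("degenerate GLCM (single level): Correlation imputed to 0")
    0
  }
  c(Energy = sum(P^2),
    Contrast = sum((i - j)^2 * P),
    Entropy = -sum(ifelse(P > 0, P * log2(P), 0)),
    Homogeneity = sum(P / (1 + abs(i - j))),
    Correlation = corr,
    SumAverage = sum((i + j) * P),
    Variance = sig2,
    Dissimilarity = sum(abs(i - j) * P),
    AutoCorrelation = sum(i * j * P))
}

#' Gray-level run-length statistics
#'
#' Runs are maximal collinear constant-level in-mask sequences, aggregated
#' over all 13 3D directions into one matrix normalized to sum 1. Run
#' percentage (`RP`) is the run count over the number of voxel-direction
#' slots (13 x voxel count), so it lies in (0, 1].
#'
#' @inheritParams glcm_stats
#' @return named vector of the 13 GLRLM statistics.
#' @export
glrlm_stats <- function(levels, n_gray) {
  nvox <- sum(levels > 0)
  if (nvox == 0) stopf("empty ROI")
  M <- cpp_glrlm(as.integer(levels), dim(levels), as.integer(n_gray))
  keep <- max(which(colSums(M) > 0))
  M <- M[, seq_len(keep), drop = FALSE]
  nruns <- sum(M)
  P <- M / nruns
  g <- seq_len(n_gray); r <- seq_len(keep)
  pg <- rowSums(P); pr <- colSums(P)
  G <- matrix(g, n_gray, keep); R <- matrix(r, n_gray, keep, byrow = TRUE)
  mug <- sum(g * pg); mur <- sum(r * pr)
  c(SRE = sum(pr / r^2), LRE = sum(pr * r^2),
    GLN = sum(pg^2), RLN = sum(pr^2),
    RP = nruns / (13 * nvox),
    LGRE = sum(pg / g^2), HGRE = sum(pg * g^2),
    SRLGE = sum(P / (G^2 * R^2)), SRHGE = sum(P * G^2 / R^2),
    LRLGE = sum(P * R^2 / G^2), LRHGE = sum(P * R^2 * G^2),
    GLV = sum(pg * (g - mug)^2), RLV = sum(pr * (r - mur)^2))
}

#' Gray-level size-zone statistics
#'
#' Zones are 26-connected constant-level in-mask components; the size-zone
#' matrix is normalized over the zone count. Zone percentage (`ZP`) is the
#' zone count over the voxel count.
#'
#' @inheritParams glcm_stats
#' @return named vector of the 13 GLSZM statistics.
#' @export
glszm_stats <- function(levels, n_gray) {
  nvox <- sum(levels > 0)
  if (nvox == 0) stopf("empty ROI")
  zones <- cpp_glszm_zones(as.integer(levels), dim(levels))
  nz <- nrow(zones)
  g <- zones[, 1]; s <- zones[, 2]
  p <- rep(1 / nz, nz)
  pg <- tapply(p, factor(g, levels = seq_len(n_gray)), sum, default = 0)
  ps <- tapply(p, s, sum)
  gl <- seq_len(n_gray)
  mug <- sum(g * p); mus <- sum(s * p)
  c(SZE = sum(p / s^2), LZE = sum(p * s^2),
    GLN = sum(pg^2), ZSN = sum(ps^2),
    ZP = nz / nvox,
    LGZE = sum(pg / gl^2), HGZE = sum(p * g^2),
    SZLGE = sum(p / (g^2 * s^2)), SZHGE = sum(p * g^2 / s^2),
    LZLGE = sum(p * s^2 / g^2), LZHGE = sum(p * s^2 * g^2),
    GLV = sum(p * (g - mug)^2), ZSV = sum(p * (s - mus)^2))
}

#' Neighbourhood gray-tone difference statistics
#'
#' The gray-tone difference vector sums, per level, the absolute deviation
#' of each in-mask voxel from the mean of its in-mask 26-neighbours.
#' Statistics follow the Amadasun-King definitions with a small epsilon
#' stabilizer in the Coarseness and Strength denominators.
#'
#' @inheritParams glcm_stats
#' @param eps stabilizer added to denominators.
#' @return named vector of the 5 NGTDM statistics.
#' @export
ngtdm_stats <- function(levels, n_gray, eps = 1e-6) {
  res <- cpp_ngtdm(as.integer(levels), dim(levels), as.integer(n_gray))
  s <- res$s; cnt <- res$n
  nvc <- sum(cnt)
  if (nvc == 0) stopf("no voxel has an in-mask neighbour")
  p <- cnt / nvc
  valid <- which(cnt > 0)
  ngv <- length(valid)
  g <- seq_len(n_gray)
  coars <- 1 / (eps + sum(p * s))
  if (ngv > 1) {
    pv <- p[valid]; gv <- g[valid]; sv <- s[valid]
    dif2 <- outer(gv, gv, "-")^2
    contr <- sum(outer(pv, pv) * dif2) / (ngv * (ngv - 1)) * sum(s) / nvc
    denom_busy <- sum(abs(outer(gv * pv, gv * pv, "-")))
    busy <- if (denom_busy > 0) sum(p * s) / denom_busy else 0
    psum <- outer(pv, pv, "+")
    pssum <- outer(pv * sv, pv * sv, "+")
    offdiag <- row(dif2) != col(dif2)
    compl <- sum((sqrt(dif2) * pssum / psum)[offdiag]) / nvc
    strength <- sum((psum * dif2)[offdiag]) / (eps + sum(s))
  } else {
    contr <- busy <- compl <- strength <- 0
  }
  c(Coarseness = coars, Contrast = contr, Busyness = busy,
    Complexity = compl, Strength = strength)
}

# ---- per-ROI orchestration -------------------------------------------------

# wavelet band-pass -> isotropic resampling applied to the (padded) bounding
# box of the mask; returns the resampled volume/mask pair.
preprocess_roi <- function(volume, mask, spacing, ratio_R, scale_mm,
                           wavelet = "sym8", pad = 2L) {
  box <- bounding_box(mask)
  dm <- dim(volume)
  lo <- pmax(box$min - pad, 1L)
  hi <- pmin(box$max + pad, dm)
  pbox <- structure(list(min = lo, max = hi), class = "box")
  v <- crop_to_box(volume, pbox)
  m <- crop_to_box(mask, pbox)
  v <- wavelet_bandpass(v, ratio_R, wavelet)
  resample_isotropic(v, m, spacing, scale_mm)
}

# all 43 texture statistics for one preprocessed, quantized ROI; families
# that degenerate (e.g. a single resampled voxel) are imputed as 0.
texture_statistics <- function(levels, n_gray) {
  vals <- levels[levels > 0]
  fam <- function(fn, k, label) {
    tryCatch(fn, error = function(e) {
      warnf("%s statistics degenerate (%s): imputed 0", label,
            conditionMessage(e))
      rep(0, k)
    })
  }
  glb <- if (length(vals) >= 2) global_stats(vals) else {
    warnf("single-voxel ROI: global statistics imputed 0")
    c(Variance = 0, Skewness = 0, Kurtosis = 0)
  }
  stats_glcm <- fam(glcm_stats(levels, n_gray), 9, "GLCM")
  stats_glrlm <- fam(glrlm_stats(levels, n_gray), 13, "GLRLM")
  stats_glszm <- fam(glszm_stats(levels, n_gray), 13, "GLSZM")
  stats_ngtdm <- fam(ngtdm_stats(levels, n_gray), 5, "NGTDM")
  res <- c(glb, stats_glcm, stats_glrlm, stats_glszm, stats_ngtdm)
  names(res) <- texture_stat_names()
  res
}

#' Extract handcrafted features from one or more studies
#'
#' For each modality and each grid point: wavelet band-pass, isotropic
#' resampling, gray-level quantization, then the 43 texture statistics.
#' The 4 nontexture shape features are computed once per study from the
#' mask. Feature names encode modality, parameters and statistic. With the
#' default grid this yields 10,320 texture features per modality and
#' 41,284 features for a 4-modality study.
#'
#' @param studies a [multimodal_study()] or list of them.
#' @param grid a [texture_grid()].
#' @param modalities modalities to use (default: all in the first study).
#' @param wavelet wavelet basis for the band-pass step.
#' @param quiet suppress per-ROI degeneracy warnings (a single summary
#'   message is emitted instead).
#' @return a [feature_table()] (labels taken from the studies).
#' @export
extract_handcrafted <- function(studies, grid = texture_grid(),
                                modalities = NULL, wavelet = "sym8",
                                quiet = TRUE) {
  if (inherits(studies, "multimodal_study")) studies <- list(studies)
  stopifnot(inherits(grid, "texture_grid"))
  modalities <- modalities %||% names(studies[[1]]$volumes)
  pg <- do.call(rbind, lapply(grid$params, function(p)
    data.frame(ratio_R = p$ratio_R, scale_mm = p$scale_mm,
               quantizer = p$quantizer, n_gray = p$n_gray)))
  prep_keys <- unique(pg[, c("ratio_R", "scale_mm")])
  n_degen <- 0L
  rows <- lapply(studies, function(study) {
    nt <- nontexture_features(study$mask, study$spacing)
    names(nt) <- paste0("shape_", names(nt))
    feats <- list(nt)
    for (mod in modalities) {
      vol <- study$volumes[[mod]]
      for (pk in seq_len(nrow(prep_keys))) {
        rr <- prep_keys$ratio_R[pk]
        sc <- prep_keys$scale_mm[pk]
        pre <- preprocess_roi(vol, study$mask, study$spacing, rr, sc, wavelet)
        sel <- which(pg$ratio_R == rr & pg$scale_mm == sc)
        inmask <- pre$mask == 1
        vals <- pre$volume[inmask]
        for (s in sel) {
          qz <- pg$quantizer[s]
          ng <- pg$n_gray[s]
          levs <- array(0L, dim = dim(pre$mask))
          run <- function() {
            levs[inmask] <<- quantize(vals, qz, ng)
            texture_statistics(levs, ng)
          }
          st <- if (quiet) {
            withCallingHandlers(run(), warning = function(w) {
              n_degen <<- n_degen + 1L
              invokeRestart("muffleWarning")
            })
          } else run()
          names(st) <- sprintf("%s_R%s_S%s_%s_G%d_%s", mod,
                               format(rr, digits = 4), format(sc, digits = 4),
                               qz, ng, names(st))
          feats[[length(feats) + 1L]] <- st
        }
      }
    }
    unlist(feats)
  })
  if (quiet && n_degen > 0)
    message(sprintf("extract_handcrafted: %d degenerate statistics imputed as 0",
                    n_degen))
  X <- do.call(rbind, rows)
  y <- vapply(studies, function(s) s$label, integer(1))
  feature_table(X, y)
}
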