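#' Bilinear image resize
#'
#' @param mat 2D numeric matrix.
#' @param out_rows,out_cols output size.
#' @return resized matrix.
#' @export
resize_bilinear <- function(mat, out_rows, out_cols) {
  nr <- nrow(mat); nc <- ncol(mat)
  map <- function(n_out, n_in) {
    if (n_in == 1 || n_out == 1) rep(1, n_out)
    else (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1) + 1
  }
  ri <- map(out_rows, nr); ci <- map(out_cols, nc)
  r0 <- pmin(floor(ri), nr); r1 <- pmin(r0 + 1, nr); fr <- ri - r0
  c0 <- pmin(floor(ci), nc); c1 <- pmin(c0 + 1, nc); fc <- ci - c0
  a <- mat[r0, c0, drop = FALSE]; b <- mat[r1, c0, drop = FALSE]
  cc <- mat[r0, c1, drop = FALSE]; d <- mat[r1, c1, drop = FALSE]
  wr <- matrix(fr, out_rows, out_cols)
  wc <- matrix(fc, out_rows, out_cols, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) + cc * (1 - wr) * wc +
    d * wr * wc
}

#' Assemble the 3-channel CNN input from a slice triplet
#'
#' Channels are the (previous, central, next) axial slices, cropped
#' in-plane to the mask bounding box footprint, bilinearly resized to
#' `side x side`, and min-max scaled to `[0, 1]` per channel. A zero-range
#' channel is set to all zeros (with a warning).
#'
#' @param triplet a [largest_area_slice_triplet()] result.
#' @param side output side length in pixels (227 for AlexNet-shaped input,
#'   299 for Inception-v3-shaped input; any positive value is allowed).
#' @return numeric array `side x side x 3`.
#' @export
assemble_rgb_input <- function(triplet, side = 227L) {
  stopifnot(inherits(triplet, "slice_triplet"))
  if (side < 1) stopf("side must be positive")
  box <- triplet$box
  out <- array(0, dim = c(side, side, 3))
  slices <- list(triplet$previous, triplet$central, triplet[["next"]])
  for (ch in 1:3) {
    sl <- slices[[ch]][box$min[1]:box$max[1], box$min[2]:box$max[2],
                       drop = FALSE]
    # constancy is decided before resizing: bilinear weights introduce
    # rounding noise of order 1e-16 that min-max scaling would amplify
    if (diff(range(sl)) == 0) {
      warnf("zero-range slice: channel %d set to zeros", ch)
      next
    }
    sl <- resize_bilinear(sl, side, side)
    rng <- range(sl)
    out[, , ch] <- (sl - rng[1]) / diff(rng)
  }
  out
}

# cache of stub projection matrices (keyed by name/dim)
.stub_cache <- new.env(parent = emptyenv())

stub_extractor <- function(name, dim, latent_side = 32L) {
  force(name); force(dim); force(latent_side)
  function(img) {
    d_in <- latent_side^2 * 3L
    key <- sprintf("%s_%d", name, dim)
    if (is.null(.stub_cache[[key]])) {
      .stub_cache[[key]] <- with_seed(
        derive_seed(20400101L, key),
        matrix(rnorm(dim * d_in), dim, d_in) / sqrt(d_in))
    }
    v <- numeric(d_in)
    for (ch in 1:3) {
      small <- resize_bilinear(img[, , ch], latent_side, latent_side)
      v[((ch - 1) * latent_side^2 + 1):(ch * latent_side^2)] <- as.numeric(small)
    }
    as.numeric(.stub_cache[[key]] %*% v)
  }
}

#' Deep-feature backend specification
#'
#' Defines the deep-feature extraction contract: input side length, output
#' dimension, and an extractor honoring them. Two deterministic stub
#' backends are built in, shaped like the penultimate fully connected layer
#' of AlexNet (227-pixel input, 4,096 units) and the average-pooling layer
#' of Inception v3 (299-pixel input, 2,048 units): each is a seeded random
#' projection of the downsampled input, so it is deterministic and
#' approximately distance-preserving. Pretrained network weights are not
#' bundled; to use a real network, pass its forward pass as `extractor`.
#'
#' @param name `"stub-alexnet"`, `"stub-inception"`, or a custom name (in
#'   which case `side`, `dim` and `extractor` are required).
#' @param side input side length in pixels.
#' @param dim output feature dimension.
#' @param extractor function mapping a `side x side x 3` array to a
#'   numeric vector of length `dim`.
#' @param prefix feature-name prefix (layer code).
#' @return object of class `deep_backend`.
#' @export
deep_backend <- function(name = c("stub-alexnet", "stub-inception"),
                         side = NULL, dim = NULL, extractor = NULL,
                         prefix = NULL) {
  if (is.character(name) && length(name) == 1 &&
      name %in% c("alexnet", "inception")) {
    stopf(paste("pretrained '%s' weights are not bundled; use the deterministic",
                "'stub-%s' backend or supply your own extractor via",
                "deep_backend(name, side, dim, extractor)"), name, name)
  }
  name <- if (is.null(extractor)) match.arg(name) else name
  if (is.null(extractor)) {
    if (name == "stub-alexnet") {
      side <- side %||% 227L; dim <- dim %||% 4096L
      prefix <- prefix %||% "F7"
    } else {
      side <- side %||% 299L; dim <- dim %||% 2048L
      prefix <- prefix %||% "avg_pool"
    }
    extractor <- stub_extractor(name, dim)
  }
  if (is.null(side) || is.null(dim) || side < 1 || dim < 1)
    stopf("side and dim must be positive")
  structure(list(name = name, side = as.integer(side), dim = as.integer(dim),
                 extractor = extractor, prefix = prefix %||% name),
            class = "deep_backend")
}

#' Extract deep features from one or more studies
#'
#' For each modality: take the largest-tumor-area axial slice triplet,
#' assemble the 3-channel input, and forward it through the backend.
#' Per-modality vectors are concatenated; names encode layer code,
#' modality and unit index. Four modalities with the stub AlexNet-shaped
#' backend give 16,384 features; with the stub Inception-shaped backend,
#' 8,192.
#'
#' @param studies a [multimodal_study()] or list of them.
#' @param backend a [deep_backend()].
#' @param modalities modalities to use (default all).
#' @return a [feature_table()].
#' @export
extract_deep <- function(studies, backend = deep_backend("stub-alexnet"),
                         modalities = NULL) {
  if (inherits(studies, "multimodal_study")) studies <- list(studies)
  stopifnot(inherits(backend, "deep_backend"))
  modalities <- modalities %||% names(studies[[1]]$volumes)
  rows <- lapply(studies, function(study) {
    vecs <- lapply(modalities, function(mod) {
      trip <- largest_area_slice_triplet(study, mod)
      img <- assemble_rgb_input(trip, backend$side)
      v <- backend$extractor(img)
      if (length(v) != backend$dim)
        stopf("backend '%s' returned %d values, contract says %d",
              backend$name, length(v), backend$dim)
      names(v) <- sprintf("%s_%s_%d", backend$prefix, mod,
                          seq_len(backend$dim))
      v
    })
    unlist(vecs)
  })
  X <- do.call(rbind, rows)
  y <- vapply(studies, function(s) s$label, integer(1))
  feature_table(X, y)
}
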