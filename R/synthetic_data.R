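#' Default per-class texture parameters for phantom generation
#'
#' Two classes of lesion texture over the four standard modalities.
#' Recurrent lesions are modelled as brighter on T1C with fine-grained
#' texture (short spatial correlation length); necrotic lesions as smoother
#' (longer correlation length), darker on T1C and brighter on T2/FLAIR.
#' Each entry is `c(mean, sd, corr_len)` in intensity units / mm.
#'
#' @param modalities character vector of modality names.
#' @return named list with `recurrence` and `necrosis` components.
#' @export
default_texture_params <- function(modalities = c("T1", "T1C", "T2", "FLAIR")) {
  rec <- list(T1 = c(mean = 90, sd = 15, corr_len = 1.5),
              T1C = c(mean = 140, sd = 18, corr_len = 1.5),
              T2 = c(mean = 120, sd = 15, corr_len = 1.5),
              FLAIR = c(mean = 130, sd = 15, corr_len = 1.5))
  nec <- list(T1 = c(mean = 80, sd = 8, corr_len = 3),
              T1C = c(mean = 110, sd = 10, corr_len = 3),
              T2 = c(mean = 140, sd = 8, corr_len = 3),
              FLAIR = c(mean = 150, sd = 8, corr_len = 3))
  fill <- function(tmpl) {
    out <- lapply(modalities, function(m) {
      if (!is.null(tmpl[[m]])) tmpl[[m]] else tmpl[[1]]
    })
    names(out) <- modalities
    out
  }
  list(recurrence = fill(rec), necrosis = fill(nec))
}

#' Phantom configuration
#'
#' Describes a synthetic multimodality study: grid geometry, lesion size,
#' and per-class texture-field parameters.
#'
#' @param grid_shape integer length-3, voxels per axis (all >= 8).
#' @param spacing numeric length-3, mm per voxel along each axis (> 0).
#' @param lesion_radius lesion semi-axes in mm; a scalar gives a sphere,
#'   length 3 an axis-aligned ellipsoid.
#' @param modalities modality names (default the four structural MRI
#'   sequences).
#' @param class_texture_params per-class, per-modality `c(mean, sd,
#'   corr_len)` as returned by [default_texture_params()].
#' @param background_mean mean background intensity.
#' @param noise_sd additive white-noise standard deviation.
#' @param seed integer RNG seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32L, 32L, 32L),
                           spacing = c(1, 1, 1),
                           lesion_radius = 8,
                           modalities = c("T1", "T1C", "T2", "FLAIR"),
                           class_texture_params = default_texture_params(modalities),
                           background_mean = 100,
                           noise_sd = 2,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stopf("grid_shape must be 3 values, all >= 8")
  if (length(spacing) != 3 || any(spacing <= 0))
    stopf("spacing must be 3 positive values (mm)")
  if (length(lesion_radius) == 1) lesion_radius <- rep(lesion_radius, 3)
  if (length(lesion_radius) != 3 || any(lesion_radius <= 0))
    stopf("lesion_radius must be 1 or 3 positive values (mm)")
  half_extent <- (grid_shape - 1) / 2 * spacing
  if (any(lesion_radius > half_extent))
    stopf(paste("lesion (semi-axes %s mm) does not fit inside the grid",
                "(half-extent %s mm); enlarge grid_shape or shrink the lesion"),
          paste(signif(lesion_radius, 3), collapse = "x"),
          paste(signif(half_extent, 3), collapse = "x"))
  if (length(class_texture_params) != 2)
    stopf("class_texture_params needs exactly two class entries")
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 lesion_radius = as.numeric(lesion_radius),
                 modalities = modalities,
                 class_texture_params = class_texture_params,
                 background_mean = background_mean,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Construct a multimodality study object
#'
#' @param volumes named list of 3D intensity arrays (one per modality).
#' @param mask 3D binary array (same shape), the tumor segmentation.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param label class label: 0 = recurrence, 1 = necrosis.
#' @return object of class `multimodal_study`.
#' @export
multimodal_study <- function(volumes, mask, spacing, label) {
  if (!is.list(volumes) || length(volumes) < 1 || is.null(names(volumes)))
    stopf("volumes must be a named list of arrays")
  dm <- dim(volumes[[1]])
  if (length(dm) != 3) stopf("volumes must be 3D arrays")
  for (m in names(volumes))
    if (!identical(dim(volumes[[m]]), dm))
      stopf("volume '%s' does not share the common shape", m)
  mask <- array(as.integer(mask != 0), dim = dim(mask))
  if (!identical(dim(mask), dm)) stopf("mask shape differs from volumes")
  if (sum(mask) < 1) stopf("mask must contain at least one voxel")
  if (!label %in% c(0, 1)) stopf("label must be 0 (recurrence) or 1 (necrosis)")
  structure(list(volumes = volumes, mask = mask,
                 spacing = as.numeric(spacing), label = as.integer(label)),
            class = "multimodal_study")
}

#' @export
print.multimodal_study <- function(x, ...) {
  cat(sprintf("<multimodal_study> %s | grid %s | %d mask voxels | label %d (%s)\n",
              paste(names(x$volumes), collapse = "/"),
              paste(dim(x$mask), collapse = "x"), sum(x$mask), x$label,
              if (x$label == 1) "necrosis" else "recurrence"))
  invisible(x)
}

# Separable Gaussian smoothing with edge replication; sigma in voxels per axis.
smooth_gaussian3 <- function(a, sigma) {
  dm <- dim(a)
  for (d in 1:3) {
    s <- sigma[d]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-half, half))^2 / (2 * s^2))
    k <- k / sum(k)
    perm <- c(d, setdiff(1:3, d))
    ap <- aperm(a, perm)
    n <- dim(ap)[1]
    mat <- matrix(ap, nrow = n)
    out <- matrix(0, nrow = n, ncol = ncol(mat))
    for (t in seq_along(k)) {
      off <- t - half - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[t] * mat[idx, , drop = FALSE]
    }
    ap <- array(out, dim = dim(ap))
    a <- aperm(ap, order(perm))
  }
  a
}

#' Generate a synthetic multimodality phantom study
#'
#' Builds an ellipsoidal lesion centered in the grid; inside-mask voxels are
#' drawn from a class-specific smoothed-noise texture field (Gaussian noise
#' smoothed with the class correlation length, affinely mapped to the class
#' mean/SD), superimposed on a noisy uniform background. Deterministic given
#' the config seed and label.
#'
#' @param config a [phantom_config()].
#' @param label class label (0 recurrence, 1 necrosis).
#' @return a [multimodal_study()].
#' @export
generate_phantom <- function(config, label) {
  stopifnot(inherits(config, "phantom_config"))
  if (!label %in% c(0, 1)) stopf("label must be 0 or 1")
  dm <- config$grid_shape
  ctr <- (dm + 1) / 2
  coords <- lapply(1:3, function(d) (seq_len(dm[d]) - ctr[d]) * config$spacing[d])
  dist2 <- outer(outer(coords[[1]]^2 / config$lesion_radius[1]^2,
                       coords[[2]]^2 / config$lesion_radius[2]^2, "+"),
                 coords[[3]]^2 / config$lesion_radius[3]^2, "+")
  mask <- array(as.integer(dist2 <= 1), dim = dm)
  cls <- if (label == 1) 2L else 1L
  params <- config$class_texture_params[[cls]]
  vols <- with_seed(derive_seed(config$seed, paste0("phantom", label)), {
    lapply(config$modalities, function(m) {
      p <- params[[m]]
      field <- array(rnorm(prod(dm)), dim = dm)
      field <- smooth_gaussian3(field, p[["corr_len"]] / config$spacing)
      field <- (field - mean(field)) / sd(field)
      vol <- config$background_mean +
        array(rnorm(prod(dm), sd = config$noise_sd), dim = dm)
      inside <- mask == 1
      vol[inside] <- p[["mean"]] + p[["sd"]] * field[inside] +
        rnorm(sum(inside), sd = config$noise_sd)
      vol
    })
  })
  names(vols) <- config$modalities
  multimodal_study(vols, mask, config$spacing, label)
}

#' Feature-table specification
#'
#' Describes a synthetic patient-by-feature table: a small informative
#' subset shifted between classes against block-correlated noise features.
#'
#' @param n_pos number of positive (necrosis) patients.
#' @param n_neg number of negative (recurrence) patients.
#' @param p_features total feature count.
#' @param informative_idx indices of informative features (within
#'   `1:p_features`).
#' @param effect_size standardized mean difference added to positives on
#'   each informative feature (>= 0).
#' @param block_correlation within-block correlation of noise features
#'   (|rho| < 1).
#' @param block_size features per correlated block.
#' @param prefix feature-name prefix.
#' @param seed integer RNG seed.
#' @return object of class `table_spec`.
#' @export
table_spec <- function(n_pos = 16L, n_neg = 35L, p_features = 100L,
                       informative_idx = 1:3, effect_size = 1,
                       block_correlation = 0.3, block_size = 10L,
                       prefix = "f", seed = 1L) {
  if (!is_count(n_pos) || !is_count(n_neg) || n_pos < 1 || n_neg < 1)
    stopf("n_pos and n_neg must be positive counts")
  if (!is_count(p_features) || p_features < 1)
    stopf("p_features must be a positive count")
  if (length(informative_idx) > 0 &&
      (any(informative_idx < 1) || any(informative_idx > p_features)))
    stopf("informative_idx must lie within 1..p_features")
  if (length(informative_idx) > p_features)
    stopf("more informative indices than features")
  if (effect_size < 0) stopf("effect_size must be >= 0")
  if (abs(block_correlation) >= 1) stopf("|block_correlation| must be < 1")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 p_features = as.integer(p_features),
                 informative_idx = as.integer(informative_idx),
                 effect_size = effect_size,
                 block_correlation = block_correlation,
                 block_size = as.integer(block_size),
                 prefix = prefix, seed = as.integer(seed)),
            class = "table_spec")
}

#' Construct a feature table
#'
#' The patients-by-features container used throughout the pipeline.
#'
#' @param X numeric matrix (patients x features) with column names.
#' @param y binary label vector (0 recurrence, 1 necrosis), length nrow(X).
#' @param ids patient identifiers (default `P001`, ...).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(X, y, ids = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stopf("feature matrix needs column names")
  if (anyDuplicated(colnames(X))) stopf("duplicate feature names")
  if (length(y) != nrow(X)) stopf("label length must equal row count")
  if (!all(y %in% c(0, 1))) stopf("labels must be 0/1")
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(X)))
  structure(list(ids = as.character(ids), X = X, y = as.integer(y)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients x %d features | %d necrosis / %d recurrence\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

#' Generate a synthetic feature table
#'
#' Noise features are standard normal with block-wise equicorrelation;
#' informative features additionally receive a mean shift of
#' `effect_size` (in SD units) in the positive class. Deterministic given
#' the spec seed.
#'
#' @param spec a [table_spec()].
#' @return a [feature_table()].
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "table_spec"))
  n <- spec$n_pos + spec$n_neg
  p <- spec$p_features
  y <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  rho <- spec$block_correlation
  X <- with_seed(derive_seed(spec$seed, "table"), {
    blocks <- split(seq_len(p),
                    ceiling(seq_len(p) / spec$block_size))
    X <- matrix(0, n, p)
    for (b in blocks) {
      common <- rnorm(n)
      eps <- matrix(rnorm(n * length(b)), n, length(b))
      X[, b] <- sqrt(abs(rho)) * sign(rho) * common + sqrt(1 - abs(rho)) * eps
    }
    X[y == 1, spec$informative_idx] <-
      X[y == 1, spec$informative_idx, drop = FALSE] + spec$effect_size
    X
  })
  colnames(X) <- sprintf("%s%03d", spec$prefix, seq_len(p))
  feature_table(X, y)
}

#' Write a study to NIfTI files
#'
#' One file per modality plus `mask.nii.gz`, with voxel spacing in the
#' header, and a `study.json` sidecar holding the label and spacing.
#'
#' @param study a [multimodal_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "multimodal_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  put <- function(arr, file) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- study$spacing
    RNifti::writeNifti(img, file.path(dir, file))
  }
  for (m in names(study$volumes)) put(study$volumes[[m]], paste0(m, ".nii.gz"))
  put(study$mask, "mask.nii.gz")
  jsonlite::write_json(list(label = study$label, spacing = study$spacing,
                            modalities = names(study$volumes)),
                       file.path(dir, "study.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a study from NIfTI files written by [write_study()]
#'
#' @param dir study directory.
#' @return a [multimodal_study()].
#' @export
read_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "study.json"),
                              simplifyVector = TRUE)
  vols <- lapply(meta$modalities, function(m) {
    img <- RNifti::readNifti(file.path(dir, paste0(m, ".nii.gz")))
    array(as.numeric(img), dim = dim(img))
  })
  names(vols) <- meta$modalities
  maskimg <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  mask <- array(as.integer(maskimg != 0), dim = dim(maskimg))
  spacing <- RNifti::pixdim(maskimg)[1:3]
  multimodal_study(vols, mask, spacing, meta$label)
}

#' Write a feature table as CSV
#'
#' Header row, a `patient_id` column, features, and a final `label` column.
#'
#' @param table a [feature_table()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_feature_table <- function(table, file) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(patient_id = table$ids, table$X,
                   label = table$y, check.names = FALSE)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param file CSV path.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(file) {
  df <- read.csv(file, check.names = FALSE)
  if (!all(c("patient_id", "label") %in% names(df)))
    stopf("feature CSV needs 'patient_id' and 'label' columns")
  feat <- setdiff(names(df), c("patient_id", "label"))
  feature_table(as.matrix(df[, feat, drop = FALSE]), df$label, df$patient_id)
}
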