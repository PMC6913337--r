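#' Pipeline configuration
#'
#' A single declarative configuration binding all stages. Exactly one
#' primary input must be given: a synthetic table spec, a feature CSV, or
#' a directory of NIfTI studies. An optional deep-feature input (a second
#' synthetic spec, or a stub backend name for study extraction) switches
#' the run to a fusion analysis. One master seed drives every stage
#' through derived per-stage seeds.
#'
#' @param seed master integer seed.
#' @param table_spec a [table_spec()] for a synthetic handcrafted-style
#'   table, or NULL.
#' @param table_csv path to a feature CSV, or NULL.
#' @param studies_dir directory containing study subdirectories (see
#'   [write_study()]), or NULL.
#' @param deep NULL, a [table_spec()] (synthetic deep-style table), or a
#'   [deep_backend()] name such as `"stub-alexnet"` (used with
#'   `studies_dir`).
#' @param grid a [texture_grid()] for study extraction (default grid when
#'   NULL).
#' @param alpha univariate significance level.
#' @param K number of comparisons for the Bonferroni correction (NULL =
#'   feature count).
#' @param gain a [gain_config()]; its seed is overridden by a derived
#'   seed.
#' @param B bootstrap replicate count for selection/evaluation.
#' @param mode resampling mode, `"imbalance"` or `"uniform"`.
#' @param orders model orders to search.
#' @param n_starters number of starter features (NULL = all reduced).
#' @param threshold classification threshold.
#' @param ridge ridge penalty.
#' @param out_dir output directory for artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, table_spec = NULL, table_csv = NULL,
                            studies_dir = NULL, deep = NULL, grid = NULL,
                            alpha = 0.05, K = NULL, gain = gain_config(),
                            B = 1000L, mode = "imbalance", orders = 1:10,
                            n_starters = NULL, threshold = 0.5,
                            ridge = 1e-4, out_dir = tempfile("gliorad_run")) {
  n_inputs <- sum(!is.null(table_spec), !is.null(table_csv),
                  !is.null(studies_dir))
  if (n_inputs != 1)
    stopf("exactly one of table_spec, table_csv, studies_dir is required")
  if (!is.null(table_csv) && !file.exists(table_csv))
    stopf("table_csv '%s' does not exist", table_csv)
  if (!is.null(studies_dir) && !dir.exists(studies_dir))
    stopf("studies_dir '%s' does not exist", studies_dir)
  structure(list(seed = as.integer(seed), table_spec = table_spec,
                 table_csv = table_csv, studies_dir = studies_dir,
                 deep = deep, grid = grid, alpha = alpha, K = K,
                 gain = gain, B = as.integer(B), mode = mode,
                 orders = as.integer(orders), n_starters = n_starters,
                 threshold = threshold, ridge = ridge, out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  plain <- unclass(config)
  plain$out_dir <- NULL
  saveRDS(plain, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

acquire_tables <- function(config) {
  if (!is.null(config$table_spec)) {
    hc <- generate_feature_table(config$table_spec)
  } else if (!is.null(config$table_csv)) {
    hc <- read_feature_table(config$table_csv)
  } else {
    dirs <- list.dirs(config$studies_dir, recursive = FALSE)
    if (length(dirs) == 0) stopf("no study subdirectories found")
    studies <- lapply(dirs, read_study)
    grid <- config$grid %||% texture_grid()
    hc <- extract_handcrafted(studies, grid)
  }
  dp <- NULL
  if (!is.null(config$deep)) {
    if (inherits(config$deep, "table_spec")) {
      dp <- generate_feature_table(config$deep)
    } else if (is.character(config$deep)) {
      if (is.null(config$studies_dir))
        stopf("a deep backend name requires studies_dir input")
      dirs <- list.dirs(config$studies_dir, recursive = FALSE)
      studies <- lapply(dirs, read_study)
      dp <- extract_deep(studies, deep_backend(config$deep))
    } else stopf("deep must be NULL, a table_spec, or a backend name")
    if (!identical(dp$y, hc$y))
      stopf("deep and handcrafted inputs disagree on labels")
  }
  list(handcrafted = hc, deep = dp)
}

#' Run the full analysis pipeline
#'
#' Executes acquire/extract, univariate screening, gain-equation
#' reduction (and fusion when a deep input is configured), 0.632+
#' bootstrap stepwise selection, bootstrap-averaged model construction,
#' and ensemble evaluation. All intermediate artifacts are written under
#' `config$out_dir`; every JSON artifact records the config hash and
#' master seed, and the whole run is reproducible from them.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress messages.
#' @return a run report list (invisibly): `tables`, `univariate`,
#'   `reduced`, `fused`, `search`, `model`, `metrics`, `paths`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  hash <- config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = hash, seed = config$seed)
  out <- function(...) file.path(config$out_dir, ...)
  wjson <- function(x, file) {
    jsonlite::write_json(c(stamp, x), out(file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out(file)
  }

  say("[acquire] building feature tables")
  tabs <- acquire_tables(config)
  hc <- tabs$handcrafted
  write_feature_table(hc, out("features_handcrafted.csv"))
  if (!is.null(tabs$deep))
    write_feature_table(tabs$deep, out("features_deep.csv"))

  say("[univariate] Spearman screening of %d features", ncol(hc$X))
  uni <- univariate_screen(hc, alpha = config$alpha,
                           K = config$K %||% ncol(hc$X))
  write.csv(uni, out("univariate.csv"), row.names = FALSE)

  gain_cfg <- config$gain
  gain_cfg$seed <- derive_seed(config$seed, "reduce_hc")
  say("[reduce] gain-equation reduction to %d features", gain_cfg$target_size)
  red_hc <- reduce_features(hc, gain_cfg)
  wjson(list(selected = red_hc$selected, gains = red_hc$gains),
        "reduced_handcrafted.json")

  table <- hc
  fused <- NULL
  if (!is.null(tabs$deep)) {
    gain_cfg$seed <- derive_seed(config$seed, "reduce_deep")
    red_dp <- reduce_features(tabs$deep, gain_cfg)
    wjson(list(selected = red_dp$selected, gains = red_dp$gains),
          "reduced_deep.json")
    fused <- fuse_features(red_hc, red_dp,
                           expected_size = gain_cfg$target_size)
    table <- bind_feature_tables(hc, tabs$deep)
    reduced <- fused
  } else {
    reduced <- red_hc$selected
  }

  say("[select] 0.632+ stepwise search, B = %d, orders %s", config$B,
      paste(range(config$orders), collapse = "-"))
  ens <- imbalance_adjusted_resample(table$y, config$B,
                                     seed = derive_seed(config$seed, "select"),
                                     mode = config$mode)
  starters <- if (is.null(config$n_starters)) NULL
              else reduced[seq_len(min(config$n_starters, length(reduced)))]
  search <- forward_select(reduced, table, ens, orders = config$orders,
                           starters = starters, ridge = config$ridge)
  wjson(list(per_order = lapply(search$per_order, function(po)
               list(features = po$features, auc = po$auc)),
             chosen_order = search$chosen_order,
             chosen_features = search$chosen_features),
        "model_search.json")

  say("[fit] bootstrap-averaged coefficients at order %d",
      search$chosen_order)
  model <- average_coefficients(search$chosen_features, table, ens,
                                ridge = config$ridge)
  wjson(list(features = model$features,
             coefficients = as.list(model$coefficients),
             center = as.list(model$center), scale = as.list(model$scale),
             ridge = model$ridge, B = model$B), "model.json")

  say("[evaluate] ensemble metrics")
  metrics <- evaluate_ensemble(search$chosen_features, table, ens,
                               threshold = config$threshold,
                               ridge = config$ridge)
  write.csv(metrics$summary, out("metrics.csv"), row.names = FALSE)
  write.csv(auc_trace(metrics), out("auc_trace.csv"), row.names = FALSE)
  wjson(list(chosen_order = search$chosen_order,
             chosen_features = search$chosen_features,
             auc632 = search$per_order[[
               which(search$orders == search$chosen_order)]]$auc,
             validation_auc_mean =
               mean(metrics$validation[, "AUC"])), "run_report.json")

  invisible(list(tables = tabs, univariate = uni, reduced = red_hc,
                 fused = fused, search = search, model = model,
                 metrics = metrics, config_hash = hash,
                 paths = out("")))
}
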