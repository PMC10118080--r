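#' Pipeline configuration
#'
#' Bundles every tunable threshold of the discovery pipeline with defaults
#' matching the reference processing settings: 600-count peak height, quality
#' score 80, 50,000-count per-sample compound-abundance gate, 0.1% + 0.15 min
#' RT window, 5 ppm + 2.0 mDa mass window, 7 cross-validation folds, 200
#' permutations, VIP threshold 1.5 and RT-tolerance multiplier 3.
#'
#' @param windows [tolerance_windows()].
#' @param min_height,min_quality Flag-filter thresholds.
#' @param min_compound_abundance Per-sample summed-height QC gate, counts.
#' @param vip_threshold Minimum VIP for a marker candidate.
#' @param rt_tol_multiplier RT matching multiplier for screening.
#' @param n_orthogonal Orthogonal components of the OPLS-DA model.
#' @param n_folds Cross-validation folds.
#' @param n_perm Label permutations for model validation.
#' @param seed Simulation / permutation seed.
#' @param design A [simulation_design()] (its seed is overridden by `seed`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(windows = tolerance_windows(),
                       min_height = 600,
                       min_quality = 80,
                       min_compound_abundance = 50000,
                       vip_threshold = 1.5,
                       rt_tol_multiplier = 3,
                       n_orthogonal = 2,
                       n_folds = 7,
                       n_perm = 200,
                       seed = 1L,
                       design = NULL) {
  if (is.null(design)) design <- simulation_design(seed = seed)
  design$seed <- as.integer(seed)
  structure(list(windows = windows, min_height = min_height,
                 min_quality = min_quality,
                 min_compound_abundance = min_compound_abundance,
                 vip_threshold = vip_threshold,
                 rt_tol_multiplier = rt_tol_multiplier,
                 n_orthogonal = n_orthogonal, n_folds = n_folds,
                 n_perm = n_perm, seed = as.integer(seed),
                 design = design),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- unclass(config)
  obj$windows <- unclass(obj$windows)
  obj$design <- unclass(obj$design)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no config file '", path, "'", call. = FALSE)
  obj <- yaml::read_yaml(path)
  run_config(
    windows = do.call(tolerance_windows, obj$windows),
    min_height = obj$min_height, min_quality = obj$min_quality,
    min_compound_abundance = obj$min_compound_abundance,
    vip_threshold = obj$vip_threshold,
    rt_tol_multiplier = obj$rt_tol_multiplier,
    n_orthogonal = obj$n_orthogonal, n_folds = obj$n_folds,
    n_perm = obj$n_perm, seed = obj$seed,
    design = do.call(simulation_design, obj$design)
  )
}

#' Run the discovery pipeline end to end
#'
#' Simulate (or accept) a dataset, align features, apply the QC gate and
#' flag filters, subtract blanks, restrict to compounds found in every sample
#' of at least one oil, fit the OPLS-DA model, validate it by permutation,
#' and discover marker candidates per species. Returns a structured report;
#' optionally serialises it to JSON.
#'
#' @param config A [run_config()].
#' @param dataset An `oil_dataset`; simulated from `config$design` when
#'   missing.
#' @param report_path Optional path for a JSON report.
#' @param permutations Whether to run the permutation validation (slowest
#'   step).
#' @return A list of class `run_report`: `config_hash`, `seed`, filtering
#'   log, `model` statistics, per-class `markers` tibbles, and the fitted
#'   objects under `fits`.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL,
                         report_path = NULL, permutations = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(dataset)) dataset <- simulate_dataset(config$design)
  log <- list()
  fm <- align_features(dataset$features, dataset$samples,
                       windows = config$windows,
                       min_compound_abundance = config$min_compound_abundance)
  log$aligned <- nrow(fm$consensus)
  fm <- filter_flags(fm, min_height = config$min_height,
                     min_quality = config$min_quality)
  log$after_flags <- nrow(fm$consensus)
  fm <- subtract_blanks(fm)
  log$after_blanks <- nrow(fm$consensus)

  oil_classes <- unique(fm$samples$species[fm$samples$role == "oil"])
  in_all_of_some_class <- rep(FALSE, nrow(fm$consensus))
  for (cl in oil_classes) {
    ids <- fm$samples$sample_id[fm$samples$species == cl]
    in_all_of_some_class <- in_all_of_some_class |
      rowMeans(fm$abundance[, ids, drop = FALSE] > 0) >= 1
  }
  fm <- subset_features(fm, which(in_all_of_some_class))
  log$after_frequency <- nrow(fm$consensus)

  X <- as_sample_matrix(fm, roles = "oil")
  model <- oplsda_clamped(X, attr(X, "classes"),
                          n_predictive = length(oil_classes) - 1,
                          n_orthogonal = config$n_orthogonal,
                          n_folds = config$n_folds)
  perm <- NULL
  if (permutations) {
    perm <- suppressWarnings(
      permutation_test(X, attr(X, "classes"),
                       n_predictive = length(oil_classes) - 1,
                       n_orthogonal = model$n_orthogonal,
                       n_perm = config$n_perm, seed = config$seed,
                       n_folds = config$n_folds))
  }

  markers <- purrr::map(setNames(oil_classes, oil_classes), function(cl) {
    discover_markers(fm, cl, vip_threshold = config$vip_threshold,
                     model = model)
  })

  report <- structure(list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    log = log,
    model = list(n_predictive = model$n_predictive,
                 n_orthogonal = model$n_orthogonal,
                 r2x = model$r2x, r2x_cum = model$r2x_cum,
                 r2y = model$r2y, q2 = model$q2,
                 s2y = model$s2y, see = model$see,
                 p_q2 = if (is.null(perm)) NA_real_ else perm$p_q2),
    markers = markers,
    fits = list(feature_matrix = fm, model = model, permutation = perm,
                dataset = dataset)
  ), class = "run_report")
  if (!is.null(report_path)) write_run_report(report, report_path)
  report
}

#' @rdname run_pipeline
#' @param report A `run_report`.
#' @param path JSON output path.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- list(
    schema_version = "1.0",
    config_hash = report$config_hash,
    seed = report$seed,
    log = report$log,
    model = report$model,
    markers = purrr::map(report$markers, function(m) {
      m %>% select(-target_class)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed ", x$seed, ", config ", substr(x$config_hash, 1, 8),
      "\n  features: ", x$log$aligned, " aligned -> ",
      x$log$after_frequency, " modelled\n", sep = "")
  cat("  OPLS-DA (", x$model$n_predictive, "+", x$model$n_orthogonal,
      "+0): R2X=", round(x$model$r2x_cum, 3), " R2Y=",
      round(x$model$r2y, 3), " Q2=", round(x$model$q2, 3), "\n", sep = "")
  for (cl in names(x$markers)) {
    cat("  ", cl, ": ", nrow(x$markers[[cl]]), " marker candidate(s)\n",
        sep = "")
  }
  invisible(x)
}
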