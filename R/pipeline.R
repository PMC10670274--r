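# End-to-end pipeline: simulate -> filter -> ROI -> features -> fit ->
# evaluate, with every artifact stamped by config hash and seed.

#' Pipeline configuration
#'
#' @param n_cases cohort size; @param image_size pixels per slice side.
#' @param seed master seed for simulation, folds and penalty selection.
#' @param hu_window ROI threshold window in HU.
#' @param directions `"hv"` or `"diag"` co-occurrence offsets.
#' @param model `"bilateral90"` (one row per case, 90 fused features) or
#'   `"single45"` (one row per scan side, 45 features; folds stay at case
#'   level).
#' @param k_folds outer CV folds; @param lambda_grid optional penalty grid
#'   (default: data-driven via [default_lambda_grid()]).
#' @param max_interval_days cohort filter window.
#' @param exclusion_rates passed to [cohort_spec()].
#' @param targets subset of `lumbar_bmc`, `lumbar_bmd`, `hip_bmc`, `hip_bmd`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_cases = 395L, image_size = 64L, seed = 1L,
                            hu_window = c(-29, 150),
                            directions = c("hv", "diag"),
                            model = c("bilateral90", "single45"),
                            k_folds = 5L, lambda_grid = NULL,
                            max_interval_days = 31,
                            exclusion_rates = rep(0, 5),
                            targets = dxa_target_names) {
  directions <- match.arg(directions)
  model <- match.arg(model)
  targets <- match.arg(targets, dxa_target_names, several.ok = TRUE)
  structure(
    list(n_cases = as.integer(n_cases), image_size = as.integer(image_size),
         seed = as.integer(seed), hu_window = as.numeric(hu_window),
         directions = directions, model = model, k_folds = as.integer(k_folds),
         lambda_grid = lambda_grid, max_interval_days = max_interval_days,
         exclusion_rates = exclusion_rates, targets = targets),
    class = "pipeline_config"
  )
}

#' Extract per-case bilateral features
#'
#' Applies the thresholded-polygon ROI and the 45-feature extraction to both
#' sides of every case and fuses them.
#'
#' @param cohort an [generate_cohort()] result with rendered slices.
#' @param hu_window HU threshold window; @param directions `"hv"`/`"diag"`.
#' @return list with `features`: data.frame (case_id, left_x1..left_x45,
#'   right_x1..right_x45, f1..f90) and `case_features`: list of
#'   [fuse_bilateral()] objects.
#' @export
extract_cohort_features <- function(cohort, hu_window = c(-29, 150),
                                    directions = "hv") {
  stopifnot(inherits(cohort, "mfx_cohort"))
  feats <- lapply(cohort, function(cs) {
    per_side <- lapply(c("left", "right"), function(side) {
      sl <- cs[[side]]
      if (is.null(sl)) stop(sprintf("case %s has no rendered %s slice",
                                    cs$case_id, side), call. = FALSE)
      mask <- threshold_roi(sl, attr(sl, "annotation"), hu_window)
      extract_features(sl, mask, directions)
    })
    fuse_bilateral(per_side[[1]], per_side[[2]])
  })
  rows <- lapply(seq_along(cohort), function(i) {
    cf <- feats[[i]]
    row <- c(stats::setNames(as.numeric(cf$left), paste0("left_x", 1:45)),
             stats::setNames(as.numeric(cf$right), paste0("right_x", 1:45)),
             cf$fused)
    cbind(data.frame(case_id = cohort[[i]]$case_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(row), check.names = FALSE))
  })
  list(features = do.call(rbind, rows), case_features = feats)
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run the full texture-to-DXA pipeline
#'
#' Simulates a cohort under `config`, applies the exclusion filter, extracts
#' the bilateral feature table, fits one LASSO regressor per requested DXA
#' target (penalty by k-fold cross-validation), and evaluates each both
#' in-sample and by nested cross-validation. With an `out` directory it
#' writes `features.csv`, one model JSON per target, per-target scatter CSVs
#' and a `results.json` stamped with the config hash and seed; identical
#' config and seed reproduce `results.json` byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param out optional output directory.
#' @return list with `cohort`, `filtered`, `features`, per-target `models`,
#'   `evaluations` (in-sample and cross-validated `eval_result`s) and the
#'   `results` summary list.
#' @export
run_pipeline <- function(config = pipeline_config(), out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- cohort_spec(n_cases = config$n_cases, image_size = config$image_size,
                      exclusion_rates = config$exclusion_rates,
                      seed = config$seed)
  cohort <- generate_cohort(spec)
  meta <- cohort_table(cohort)
  filtered <- filter_cohort(meta, config$max_interval_days)
  keep <- meta$case_id %in% filtered$included$case_id
  analyzable <- structure(cohort[keep], class = "mfx_cohort",
                          spec = spec, targets = dxa_target_names)
  if (length(analyzable) < max(3L, config$k_folds)) {
    stop(sprintf("pipeline aborted at filtering: only %d analyzable cases",
                 length(analyzable)), call. = FALSE)
  }
  ext <- extract_cohort_features(analyzable, config$hu_window, config$directions)
  ftab <- ext$features

  if (config$model == "bilateral90") {
    X <- as.matrix(ftab[, paste0("f", 1:90)])
    case_ids <- ftab$case_id
    y_of <- function(target) vapply(analyzable, function(cs) cs$dxa[[target]], numeric(1))
  } else {
    left <- as.matrix(ftab[, paste0("left_x", 1:45)])
    right <- as.matrix(ftab[, paste0("right_x", 1:45)])
    colnames(left) <- colnames(right) <- paste0("x", 1:45)
    X <- rbind(left, right)
    case_ids <- rep(ftab$case_id, 2L)
    y_of <- function(target) {
      rep(vapply(analyzable, function(cs) cs$dxa[[target]], numeric(1)), 2L)
    }
  }

  models <- list(); evaluations <- list()
  for (target in config$targets) {
    y <- y_of(target)
    grid <- config$lambda_grid %||% default_lambda_grid(X, y)
    sel <- select_lambda(X, y, grid, k_folds = config$k_folds,
                         seed = config$seed, case_ids = case_ids)
    fit <- fit_lasso(X, y, sel$lambda, target_name = target)
    in_sample <- evaluate_predictions(predict(fit, X), y, target, "in-sample")
    cv <- cross_validated_eval(
      X, y, model_spec = list(method = "lasso", lambda_grid = grid,
                              inner_folds = config$k_folds),
      k_folds = config$k_folds, seed = config$seed, case_ids = case_ids,
      target_name = target
    )
    models[[target]] <- fit
    evaluations[[target]] <- list(in_sample = in_sample, cross_validated = cv)
  }

  results <- list(
    config_hash = config_hash(config), seed = config$seed,
    model = config$model, n_input = nrow(meta),
    n_analyzable = length(analyzable),
    excluded_by_reason = as.list(filtered$report),
    n_features = ncol(X),
    targets = lapply(evaluations, function(ev) {
      list(
        lambda = models[[ev$in_sample$target_name]]$lambda,
        n_nonzero_weights = sum(models[[ev$in_sample$target_name]]$weights != 0),
        in_sample = list(pearson_r = ev$in_sample$pearson_r,
                         mse = ev$in_sample$mse, n = ev$in_sample$n),
        cross_validated = list(pearson_r = ev$cross_validated$pearson_r,
                               mse = ev$cross_validated$mse,
                               n = ev$cross_validated$n)
      )
    })
  )

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ftab, file.path(out, "features.csv"), row.names = FALSE)
    for (target in names(models)) {
      write_model(models[[target]], file.path(out, paste0("model_", target, ".json")))
      export_scatter(evaluations[[target]]$cross_validated,
                     file.path(out, paste0("scatter_", target, ".csv")))
    }
    write_json_file(results, file.path(out, "results.json"))
  }

  invisible(list(cohort = cohort, filtered = filtered, features = ftab,
                 models = models, evaluations = evaluations,
                 results = results, config = config))
}
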