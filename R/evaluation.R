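#' Pearson correlation and MSE of predictions against DXA reference
#'
#' The study's readout: product-moment correlation and mean squared error
#' between texture-derived predictions and DXA-measured values, in raw target
#' units (g for BMC, g/cm^2 for BMD; MSE in their squares). Constant
#' predictions (or references) have undefined correlation; r is reported as 0
#' with a degenerate flag.
#'
#' @param predictions,references equal-length (>= 3) finite numeric vectors.
#' @param target_name optional label; @param mode `"in-sample"` or
#'   `"cross-validated"`.
#' @return Object of class `eval_result`: `target_name`, `pearson_r`, `mse`,
#'   `n`, `mode`, `degenerate` and the `scatter` data.frame
#'   `(predicted, reference)`.
#' @export
evaluate_predictions <- function(predictions, references, target_name = NULL,
                                 mode = c("in-sample", "cross-validated")) {
  mode <- match.arg(mode)
  n <- length(predictions)
  if (length(references) != n) {
    stop(sprintf("length mismatch: %d predictions vs %d references",
                 n, length(references)), call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (!all(is.finite(predictions)) || !all(is.finite(references))) {
    stop("all values must be finite", call. = FALSE)
  }
  degenerate <- stats::sd(predictions) == 0 || stats::sd(references) == 0
  r <- if (degenerate) 0 else stats::cor(predictions, references)
  mse <- mean((predictions - references)^2)
  structure(
    list(target_name = target_name, pearson_r = r, mse = mse, n = n,
         mode = mode, degenerate = degenerate,
         scatter = data.frame(predicted = predictions, reference = references)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s (%s): r = %.3f, MSE = %.4g, n = %d%s\n",
              x$target_name %||% "target", x$mode, x$pearson_r, x$mse, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Cross-validated evaluation of a texture regressor
#'
#' Assembles out-of-fold predictions over all cases (seeded case-level folds,
#' so both sides of a case stay together in per-scan designs), then applies
#' [evaluate_predictions()] once to the full out-of-fold vector.
#'
#' For `method = "lasso"` the penalty is chosen inside each training fold by
#' [select_lambda()] over `lambda_grid` (nested cross-validation) unless a
#' fixed `lambda` is supplied.
#'
#' @param X feature matrix; @param y response.
#' @param model_spec list: `method` (`"ols"` or `"lasso"`), optional fixed
#'   `lambda`, optional `lambda_grid`, optional `inner_folds` (default 5).
#' @param k_folds outer folds (>= 2); @param seed fold seed.
#' @param case_ids optional case identifiers (rows of one case share folds).
#' @param target_name optional label.
#' @return An `eval_result` with `mode = "cross-validated"`.
#' @export
cross_validated_eval <- function(X, y, model_spec = list(method = "ols"),
                                 k_folds = 5L, seed = 1L, case_ids = NULL,
                                 target_name = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k_folds < 2L) stop_field("k_folds", "must be >= 2")
  if (is.null(case_ids)) case_ids <- seq_len(n)
  method <- match.arg(model_spec$method, c("ols", "lasso"))
  folds <- assign_case_folds(case_ids, k_folds, seed)
  oof <- rep(NA_real_, n)
  for (f in seq_len(k_folds)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    if (method == "ols") {
      fit <- suppressWarnings(fit_ols(Xtr, ytr))
    } else {
      lam <- model_spec[["lambda"]]
      if (is.null(lam)) {
        grid <- model_spec[["lambda_grid"]] %||% default_lambda_grid(Xtr, ytr)
        lam <- select_lambda(Xtr, ytr, grid,
                             k_folds = model_spec[["inner_folds"]] %||% 5L,
                             seed = seed + f,
                             case_ids = case_ids[!test])$lambda
      }
      fit <- fit_lasso(Xtr, ytr, lam)
    }
    oof[test] <- predict(fit, X[test, , drop = FALSE])
  }
  evaluate_predictions(oof, y, target_name = target_name,
                       mode = "cross-validated")
}

#' Export a scatter readout as CSV and an annotated plot
#'
#' Writes the `(predicted, reference)` pairs as a CSV (byte-stable across
#' re-exports of the same result) and, when `plot_path` is given, a scatter
#' plot with the identity line and the Pearson r and MSE annotated to three
#' decimals.
#'
#' @param result an [evaluate_predictions()] result.
#' @param csv_path output CSV path.
#' @param plot_path optional PNG path.
#' @return The ggplot object, invisibly.
#' @export
export_scatter <- function(result, csv_path, plot_path = NULL) {
  stopifnot(inherits(result, "eval_result"))
  utils::write.csv(result$scatter, csv_path, row.names = FALSE)
  label <- sprintf("r = %.3f\nMSE = %.3f", result$pearson_r, result$mse)
  p <- ggplot2::ggplot(result$scatter,
                       ggplot2::aes(x = .data$reference, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.3,
                      label = label) +
    ggplot2::labs(
      title = sprintf("%s (%s)", result$target_name %||% "target", result$mode),
      x = "DXA reference", y = "Texture-model estimate"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(plot_path)) {
    ggplot2::ggsave(plot_path, p, width = 5, height = 4, dpi = 150)
  }
  invisible(p)
}
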