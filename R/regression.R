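# Linear texture -> DXA regressors: OLS (minimum-norm) and LASSO by cyclic
# coordinate descent, both on internally standardized features.

# Center/scale columns; scale is the population sd (denominator n) so that
# mean(x_s^2) = 1 exactly, which makes the LASSO null bound max|X'y|/n exact.
# Constant columns get scale 1 and are flagged (their weights stay 0).
standardize_columns <- function(X) {
  X <- as.matrix(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale <- sqrt(colMeans(Xc^2))
  constant <- scale == 0
  scale[constant] <- 1
  list(Xs = sweep(Xc, 2, scale, "/"), center = center, scale = scale,
       constant = constant)
}

new_texture_regressor <- function(weights, bias, lambda, center, scale,
                                  target_name, method, extra = list()) {
  structure(
    c(list(weights = weights, bias = bias, lambda = lambda, center = center,
           scale = scale, target_name = target_name, method = method,
           J = length(weights)), extra),
    class = "texture_regressor"
  )
}

#' @export
print.texture_regressor <- function(x, ...) {
  cat(sprintf("<texture_regressor> %s, J = %d, lambda = %g, %d nonzero weights, target = %s\n",
              x$method, x$J, x$lambda, sum(x$weights != 0),
              x$target_name %||% "unnamed"))
  invisible(x)
}

#' Ordinary least squares texture regressor
#'
#' Fits `y = sum_j w_j x_j + b` by least squares on internally standardized
#' features (center and population-sd scale stored in the model). Rank
#' deficiency — including n <= J — is resolved by the SVD minimum-norm
#' solution; underdetermined fits raise a warning and are flagged.
#'
#' @param X n x J numeric feature matrix, no missing entries.
#' @param y length-n response (DXA target).
#' @param target_name optional label (e.g. `"lumbar_bmd"`).
#' @return A `texture_regressor` with `lambda = 0`. Weights are on the
#'   standardized-feature scale; use [coef()] for original-scale
#'   coefficients.
#' @export
fit_ols <- function(X, y, target_name = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing entries are not allowed", call. = FALSE)
  n <- nrow(X)
  if (n < 2L || length(y) != n) stop("need n >= 2 rows matching length(y)", call. = FALSE)
  std <- standardize_columns(X)
  underdetermined <- n < ncol(X) + 1L
  if (underdetermined) {
    warning(sprintf("n = %d < J = %d: returning the minimum-norm least-squares fit",
                    n, ncol(X)))
  }
  b <- mean(y)
  yc <- y - b
  sv <- svd(std$Xs)
  pos <- sv$d > max(dim(std$Xs)) * .Machine$double.eps * max(sv$d, 1)
  w <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos])
  w <- as.vector(w)
  w[std$constant] <- 0
  names(w) <- colnames(X)
  new_texture_regressor(w, b, 0, std$center, std$scale, target_name, "ols",
                        extra = list(min_norm = underdetermined))
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Smallest penalty with an all-zero LASSO solution
#'
#' On standardized features and centered response the KKT conditions zero
#' every weight exactly when `lambda >= max_j |x_j' y| / n`.
#'
#' @param X feature matrix; @param y response.
#' @return The bound as a single number.
#' @export
lasso_lambda_max <- function(X, y) {
  std <- standardize_columns(as.matrix(X))
  yc <- y - mean(y)
  max(abs(crossprod(std$Xs, yc))) / nrow(std$Xs)
}

#' LASSO texture regressor by cyclic coordinate descent
#'
#' Minimizes `(1/2n) sum_i (y_i - yhat_i)^2 + lambda * sum_j |w_j|` over
#' weights on standardized features; the bias is unpenalized (it equals
#' `mean(y)` on the standardized problem). Cyclic coordinate descent with an
#' exact soft-threshold update per coordinate; convergence when the largest
#' weight change in a full sweep falls below `tol`. A guard handles
#' near-duplicate feature columns, where the objective (which coordinate
#' descent decreases monotonically) is numerically converged while weight
#' mass still shuffles between the duplicates at a per-sweep contraction
#' rate approaching 1: when the max weight change has stayed below
#' `10000 * tol` for 500 consecutive sweeps without reaching `tol`, the fit
#' stops and is flagged `crawl_stopped` — sustaining that many sub-threshold
#' sweeps requires a per-sweep contraction rate above 0.986, so the
#' remaining motion lies in a numerically non-identifiable subspace and does
#' not alter predictions. Fits on non-degenerate designs contract much
#' faster and terminate through the weight-change criterion.
#'
#' @param X n x J feature matrix; @param y length-n response.
#' @param lambda penalty strength >= 0.
#' @param tol convergence threshold on the max per-sweep weight change.
#' @param max_iter maximum number of sweeps.
#' @param w_init optional warm-start weights (standardized scale). Without
#'   one, small penalties are reached by an internal warm-started path from
#'   the null bound down to `lambda` (pathwise coordinate descent), which the
#'   collinear texture designs need for fast convergence; the returned fit is
#'   still the coordinate-descent solution at `lambda` under `tol`.
#' @param target_name optional label.
#' @param trace if TRUE, store the penalized objective after every sweep in
#'   the model's `objective_trace`.
#' @return A `texture_regressor`.
#' @export
fit_lasso <- function(X, y, lambda, tol = 1e-7, max_iter = 10000L,
                      w_init = NULL, target_name = NULL, trace = FALSE) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing entries are not allowed", call. = FALSE)
  if (length(lambda) != 1L || lambda < 0) stop_field("lambda", "must be a single penalty >= 0")
  n <- nrow(X); J <- ncol(X)
  if (n < 2L || length(y) != n) stop("need n >= 2 rows matching length(y)", call. = FALSE)
  if (lambda > 0 && lambda >= lasso_lambda_max(X, y)) {
    # KKT: at or above the null bound the all-zero solution is optimal
    std <- standardize_columns(X)
    w <- stats::setNames(rep(0, J), colnames(X))
    return(new_texture_regressor(w, mean(y), lambda, std$center, std$scale,
                                 target_name, "lasso",
                                 extra = list(n_sweeps = 0L,
                                              crawl_stopped = FALSE,
                                              objective_trace = if (trace) numeric(0) else NULL)))
  }
  if (is.null(w_init) && lambda > 0) {
    lmax <- lasso_lambda_max(X, y)
    if (lambda < lmax / 2) {
      path <- exp(seq(log(lmax), log(lambda), length.out = 8L))[-c(1L, 8L)]
      w_init <- numeric(J)
      for (lp in path) {
        w_init <- fit_lasso(X, y, lp, tol = tol, max_iter = max_iter,
                            w_init = w_init)$weights
      }
    }
  }
  std <- standardize_columns(X)
  b <- mean(y)
  w <- if (is.null(w_init)) numeric(J) else as.numeric(w_init)
  stopifnot(length(w) == J)
  w[std$constant] <- 0
  fit <- cd_lasso(std$Xs, y - b, lambda, tol, as.integer(max_iter), w,
                  !std$constant, trace)
  if (!fit$converged) {
    stop(sprintf("coordinate descent did not converge in %d sweeps (last max weight change %.3g)",
                 max_iter, fit$delta), call. = FALSE)
  }
  w <- fit$w
  names(w) <- colnames(X)
  new_texture_regressor(w, b, lambda, std$center, std$scale, target_name,
                        "lasso",
                        extra = list(n_sweeps = fit$n_sweeps,
                                     crawl_stopped = fit$crawl_stopped,
                                     objective_trace = if (trace) fit$objective_trace else NULL))
}

#' Select the LASSO penalty by k-fold cross-validation
#'
#' Computes the k-fold cross-validated mean squared error for every penalty
#' in `lambda_grid` (fits warm-started along the internally descending path)
#' and returns the penalty minimizing the mean CV MSE; ties break to the
#' first index of the grid as given. Folds are assigned at case level: rows
#' sharing a `case_ids` entry always land in the same fold.
#'
#' @param X feature matrix; @param y response.
#' @param lambda_grid nonempty vector of penalties >= 0.
#' @param k_folds number of folds (>= 2).
#' @param seed fold-assignment seed.
#' @param case_ids optional case identifiers (default: one case per row).
#' @return list with `lambda` (chosen), `cv_mse` (named by grid value, in the
#'   given grid order), `lambda_grid`, `folds`.
#' @export
select_lambda <- function(X, y, lambda_grid, k_folds = 5L, seed = 1L,
                          case_ids = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(lambda_grid) < 1L) stop_field("lambda_grid", "must be nonempty")
  if (any(lambda_grid < 0)) stop_field("lambda_grid", "penalties must be >= 0")
  if (k_folds < 2L) stop_field("k_folds", "must be >= 2")
  if (is.null(case_ids)) case_ids <- seq_len(n)
  stopifnot(length(case_ids) == n)
  folds <- assign_case_folds(case_ids, k_folds, seed)
  fold_sizes <- tabulate(folds, nbins = k_folds)
  if (any(fold_sizes < 2L)) {
    stop(sprintf("fold with fewer than 2 cases (sizes: %s); reduce k_folds",
                 paste(fold_sizes, collapse = ", ")), call. = FALSE)
  }
  ord <- order(lambda_grid, decreasing = TRUE)  # warm-start path
  sq_err <- matrix(NA_real_, n, length(lambda_grid))
  for (f in seq_len(k_folds)) {
    test <- folds == f
    w_prev <- NULL
    for (oi in ord) {
      fit <- fit_lasso(X[!test, , drop = FALSE], y[!test], lambda_grid[oi],
                       w_init = w_prev)
      w_prev <- fit$weights
      pred <- predict(fit, X[test, , drop = FALSE])
      sq_err[test, oi] <- (pred - y[test])^2
    }
  }
  cv_mse <- colMeans(sq_err)
  names(cv_mse) <- signif(lambda_grid, 6)
  best <- which.min(cv_mse)  # first index on ties
  list(lambda = lambda_grid[best], cv_mse = cv_mse,
       lambda_grid = lambda_grid, folds = folds)
}

# Seeded case-level fold assignment: unique cases are shuffled and dealt
# round-robin into k folds; rows inherit their case's fold.
assign_case_folds <- function(case_ids, k_folds, seed) {
  uc <- unique(case_ids)
  if (length(uc) < k_folds) {
    stop(sprintf("only %d cases for %d folds", length(uc), k_folds), call. = FALSE)
  }
  with_seed(seed, {
    shuffled <- sample(uc)
    fold_of <- stats::setNames(rep_len(seq_len(k_folds), length(uc)),
                               as.character(shuffled))
    unname(fold_of[as.character(case_ids)])
  })
}

#' Default penalty grid
#'
#' Log-spaced down from the all-zero bound [lasso_lambda_max()]. The floor
#' follows the usual path convention: `0.01 * lambda_max` when n < J (where
#' the unpenalized limit is not unique), `0.001 * lambda_max` otherwise.
#'
#' @param X feature matrix; @param y response; @param length grid length.
#' @return Decreasing numeric vector.
#' @export
default_lambda_grid <- function(X, y, length = 20L) {
  X <- as.matrix(X)
  lmax <- lasso_lambda_max(X, y)
  floor_exp <- if (nrow(X) < ncol(X)) -2 else -3
  lmax * 10^seq(0, floor_exp, length.out = length)
}

#' Predict DXA values from a fitted texture regressor
#'
#' `yhat = sum_j w_j (x_j - center_j) / scale_j + b`, already in target
#' units.
#'
#' @param object a `texture_regressor`.
#' @param X feature matrix with the model's column count.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.texture_regressor <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$J) {
    stop(sprintf("feature count mismatch: model expects %d, got %d",
                 object$J, ncol(X)), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  as.vector(Xs %*% object$weights) + object$bias
}

#' Original-scale coefficients of a texture regressor
#'
#' @param object a `texture_regressor`.
#' @param ... unused.
#' @return list with `intercept` and per-feature `weights` on the raw
#'   (unstandardized) feature scale.
#' @export
coef.texture_regressor <- function(object, ...) {
  w_orig <- object$weights / object$scale
  list(intercept = object$bias - sum(w_orig * object$center),
       weights = w_orig)
}

#' Serialize / restore a texture regressor as JSON
#'
#' Full double precision is preserved, so a restored model predicts
#' bit-identically.
#'
#' @param model a `texture_regressor`; @param path JSON file path.
#' @return `path` invisibly (write); the model (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "texture_regressor"))
  # digits = I(17): significant-digit mode, enough for exact double round-trip
  jsonlite::write_json(
    list(target = model$target_name, J = model$J, method = model$method,
         weights = as.numeric(model$weights),
         feature_names = names(model$weights),
         bias = model$bias, lambda = model$lambda,
         center = as.numeric(model$center), scale = as.numeric(model$scale),
         software_version = as.character(utils::packageVersion("mfxbmd"))),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- as.numeric(m$weights)
  if (!is.null(m$feature_names)) names(w) <- m$feature_names
  new_texture_regressor(w, m$bias, m$lambda, as.numeric(m$center),
                        as.numeric(m$scale), m$target, m$method)
}
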