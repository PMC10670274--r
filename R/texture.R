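#' Feature index table for the 45-feature scheme
#'
#' Five intensity-histogram statistics occupy indices `j = 1..5`
#' (`k = 1..5`: mean, standard deviation, skewness, kurtosis, entropy). The 40
#' GLCM statistics occupy `j = 6..45` via
#' `j = 5 + n + 5 * (m - 1) + 20 * (l - 1)` for statistic `n = 1..5`
#' (contrast, correlation, energy, homogeneity, variance), gray-level count
#' index `m = 1..4` (16, 32, 64, 128 levels) and direction `l = 1..2`
#' (horizontal, vertical). The map is a bijection onto `1..45`.
#'
#' @param directions character vector of two direction names; defaults to the
#'   horizontal/vertical grid.
#' @return data.frame with columns `j`, `kind`, `k`, `l`, `m`, `n`,
#'   `direction`, `levels`, `statistic`, `name`.
#' @export
feature_index_table <- function(directions = c("horizontal", "vertical")) {
  stopifnot(length(directions) == 2L)
  hist_stats <- c("mean", "sd", "skewness", "kurtosis", "entropy")
  glcm_stats <- c("contrast", "correlation", "energy", "homogeneity", "variance")
  levels_grid <- c(16L, 32L, 64L, 128L)
  hist_part <- data.frame(
    j = 1:5, kind = "histogram", k = 1:5, l = NA_integer_, m = NA_integer_,
    n = NA_integer_, direction = NA_character_, levels = NA_integer_,
    statistic = hist_stats,
    name = paste0("hist_", hist_stats),
    stringsAsFactors = FALSE
  )
  grid <- expand.grid(n = 1:5, m = 1:4, l = 1:2)
  glcm_part <- data.frame(
    j = 5L + grid$n + 5L * (grid$m - 1L) + 20L * (grid$l - 1L),
    kind = "glcm", k = NA_integer_, l = grid$l, m = grid$m, n = grid$n,
    direction = directions[grid$l], levels = levels_grid[grid$m],
    statistic = glcm_stats[grid$n],
    name = paste0("glcm_", directions[grid$l], "_m", levels_grid[grid$m], "_",
                  glcm_stats[grid$n]),
    stringsAsFactors = FALSE
  )
  out <- rbind(hist_part, glcm_part)
  out[order(out$j), , drop = FALSE]
}

#' Intensity-histogram statistics of a masked ROI
#'
#' Computes the five first-order features over the masked HU values: mean,
#' standard deviation (denominator n - 1), skewness `m3 / m2^(3/2)`,
#' non-excess kurtosis `m4 / m2^2` (normal = 3) with central moments `m_r`,
#' and Shannon entropy in bits over a 64-bin equal-width histogram spanning
#' the observed masked HU range (the same min-max convention used for GLCM
#' quantization, which makes every feature except the mean invariant to a
#' constant HU shift). A constant ROI is degenerate: sd, skewness, kurtosis
#' and entropy are returned as 0 and the result is flagged.
#'
#' @param slice a [ct_slice()].
#' @param mask a [threshold_roi()] mask with `n_pixels >= 2`.
#' @param entropy_bins number of histogram bins for the entropy term.
#' @return Named numeric vector `mean`, `sd`, `skewness`, `kurtosis`,
#'   `entropy`, with attribute `degenerate` (logical).
#' @export
histogram_features <- function(slice, mask, entropy_bins = 64L) {
  stopifnot(inherits(slice, "ct_slice"), inherits(mask, "roi_mask"))
  if (mask$n_pixels < 2L) stop("mask must contain at least 2 pixels", call. = FALSE)
  x <- slice$pixels[mask$mask]
  n <- length(x)
  mu <- mean(x)
  s <- stats::sd(x)
  degenerate <- (s == 0)
  if (degenerate) {
    out <- c(mean = mu, sd = 0, skewness = 0, kurtosis = 0, entropy = 0)
  } else {
    m2 <- mean((x - mu)^2)
    m3 <- mean((x - mu)^3)
    m4 <- mean((x - mu)^4)
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
    lab <- minmax_labels(x, entropy_bins)
    p <- tabulate(lab + 1L, nbins = entropy_bins) / n
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
    out <- c(mean = mu, sd = s, skewness = skew, kurtosis = kurt, entropy = ent)
  }
  attr(out, "degenerate") <- degenerate
  out
}

# Equal-width min-max binning of `x` into `m` labels 0..m-1; the maximum maps
# to the top bin, a constant vector to bin 0.
minmax_labels <- function(x, m) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(0L, length(x)))
  lab <- floor((x - lo) / (hi - lo) * m)
  lab[lab >= m] <- m - 1L
  as.integer(lab)
}

#' Quantize a masked ROI to m gray levels
#'
#' Linear min-max binning of the masked HU values into `m_val` equal-width
#' bins labelled `0 .. m_val - 1`; the ROI maximum maps to the top bin and a
#' constant ROI maps every pixel to bin 0. Pixels outside the mask carry `NA`.
#'
#' @param slice a [ct_slice()].
#' @param mask a [threshold_roi()] mask.
#' @param m_val one of 16, 32, 64, 128.
#' @return Object of class `quantized_roi`: list with integer matrix `labels`
#'   (NA off-mask) and `m_val`.
#' @export
quantize <- function(slice, mask, m_val) {
  stopifnot(inherits(slice, "ct_slice"), inherits(mask, "roi_mask"))
  if (!m_val %in% c(16L, 32L, 64L, 128L)) {
    stop_field("m_val", "must be one of 16, 32, 64, 128")
  }
  if (mask$n_pixels < 1L) stop("mask is empty", call. = FALSE)
  labels <- matrix(NA_integer_, nrow(slice$pixels), ncol(slice$pixels))
  labels[mask$mask] <- minmax_labels(slice$pixels[mask$mask], as.integer(m_val))
  structure(list(labels = labels, m_val = as.integer(m_val)),
            class = "quantized_roi")
}

glcm_offsets <- list(
  horizontal = c(0L, 1L),   # (r, c) -> (r, c + 1)
  vertical   = c(1L, 0L),   # (r, c) -> (r + 1, c)
  diag45     = c(-1L, 1L),  # up-right, 45 degrees
  diag135    = c(-1L, -1L)  # up-left, 135 degrees
)

#' Nonsymmetric gray-level co-occurrence matrix
#'
#' Counts ordered pixel pairs at offset distance 1: for `horizontal` each pair
#' `(r, c) -> (r, c + 1)`, for `vertical` `(r, c) -> (r + 1, c)` (diagonal
#' offsets are available as `diag45`/`diag135`). Both pixels of a pair must be
#' inside the mask. Counts are NOT symmetrized: `counts[i, j]` need not equal
#' `counts[j, i]`. The normalized matrix divides by the total pair count.
#'
#' @param q a [quantize()]d ROI.
#' @param direction one of `"horizontal"`, `"vertical"`, `"diag45"`,
#'   `"diag135"`.
#' @return Object of class `glcm`: list with `counts`, `normalized` (both
#'   `m_val` x `m_val`), `direction`, `m_val`, `n_pairs`.
#' @export
compute_glcm <- function(q, direction = c("horizontal", "vertical", "diag45", "diag135")) {
  stopifnot(inherits(q, "quantized_roi"))
  direction <- match.arg(direction)
  off <- glcm_offsets[[direction]]
  lab <- q$labels
  nr <- nrow(lab); nc <- ncol(lab)
  r_from <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c_from <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- lab[r_from, c_from, drop = FALSE]
  b <- lab[r_from + off[1], c_from + off[2], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  total <- sum(ok)
  if (total == 0L) {
    stop(sprintf("no co-occurring pairs in direction '%s'", direction), call. = FALSE)
  }
  m <- q$m_val
  counts <- matrix(
    tabulate(a[ok] * m + b[ok] + 1L, nbins = m * m),
    nrow = m, ncol = m, byrow = TRUE
  )
  structure(
    list(counts = counts, normalized = counts / total,
         direction = direction, m_val = m, n_pairs = total),
    class = "glcm"
  )
}

#' Haralick statistics of a GLCM
#'
#' With `p(i, j)` the normalized co-occurrence probability over 0-based
#' levels and marginal means/sds `mu_i, mu_j, sigma_i, sigma_j`:
#' contrast `sum p(i,j) (i - j)^2`; correlation
#' `sum p(i,j) (i - mu_i)(j - mu_j) / (sigma_i sigma_j)` (0 with a degenerate
#' flag when either marginal sd is 0); energy `sum p(i,j)^2`; homogeneity
#' `sum p(i,j) / (1 + |i - j|)`; variance `sum p(i,j) (i - mu_i)^2` (the row
#' marginal variance).
#'
#' @param g a [compute_glcm()] result (its `normalized` matrix sums to 1).
#' @return Named numeric vector `contrast`, `correlation`, `energy`,
#'   `homogeneity`, `variance`, with attribute `degenerate`.
#' @export
glcm_statistics <- function(g) {
  stopifnot(inherits(g, "glcm"))
  p <- g$normalized
  m <- nrow(p)
  idx <- 0:(m - 1)
  I <- matrix(idx, m, m)          # row level i
  J <- matrix(idx, m, m, byrow = TRUE)  # col level j
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  mu_i <- sum(idx * pi_)
  mu_j <- sum(idx * pj_)
  var_i <- sum((idx - mu_i)^2 * pi_)
  var_j <- sum((idx - mu_j)^2 * pj_)
  contrast <- sum(p * (I - J)^2)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(I - J)))
  degenerate <- (var_i == 0 || var_j == 0)
  correlation <- if (degenerate) 0 else {
    sum(p * (I - mu_i) * (J - mu_j)) / sqrt(var_i * var_j)
  }
  out <- c(contrast = contrast, correlation = correlation, energy = energy,
           homogeneity = homogeneity, variance = var_i)
  attr(out, "degenerate") <- degenerate
  out
}

#' Extract the 45-feature texture vector of one ROI
#'
#' Histogram statistics fill `j = 1..5`; for each direction `l`, gray-level
#' count index `m` and GLCM statistic `n`, the value sits at
#' `j = 5 + n + 5 (m - 1) + 20 (l - 1)` (see [feature_index_table()]).
#'
#' @param slice a [ct_slice()].
#' @param mask a [threshold_roi()] mask with `n_pixels >= 2`.
#' @param directions `"hv"` (horizontal + vertical, the default grid) or
#'   `"diag"` (45 + 135 degree offsets).
#' @return Named numeric vector of length 45 (`x1 .. x45`), with attribute
#'   `index_table`.
#' @export
extract_features <- function(slice, mask, directions = c("hv", "diag")) {
  directions <- match.arg(directions)
  dir_names <- if (directions == "hv") c("horizontal", "vertical") else c("diag45", "diag135")
  out <- numeric(45)
  hf <- tryCatch(
    histogram_features(slice, mask),
    error = function(e) stop(sprintf("histogram features failed (side %s): %s",
                                     slice$side, conditionMessage(e)), call. = FALSE)
  )
  out[1:5] <- hf
  levels_grid <- c(16L, 32L, 64L, 128L)
  for (l in 1:2) {
    for (m in 1:4) {
      q <- quantize(slice, mask, levels_grid[m])
      for_dir <- tryCatch(
        compute_glcm(q, dir_names[l]),
        error = function(e) stop(sprintf("GLCM failed (side %s, %s, m=%d): %s",
                                         slice$side, dir_names[l], levels_grid[m],
                                         conditionMessage(e)), call. = FALSE)
      )
      st <- glcm_statistics(for_dir)
      out[5L + 1:5 + 5L * (m - 1L) + 20L * (l - 1L)] <- st
    }
  }
  names(out) <- paste0("x", 1:45)
  attr(out, "index_table") <- feature_index_table(dir_names)
  out
}

#' Fuse left and right 45-feature vectors into one 90-feature case vector
#'
#' The fused layout is fixed: entries 1-45 are the left side, 46-90 the
#' right. A missing or malformed side is an error; there is no silent
#' single-side fallback.
#'
#' @param left,right numeric vectors of length 45.
#' @return Object of class `case_features`: list with `left`, `right` and the
#'   90-entry `fused` vector named `f1 .. f90`.
#' @export
fuse_bilateral <- function(left, right) {
  for (nm in c("left", "right")) {
    v <- get(nm)
    if (is.null(v) || length(v) != 45L || !all(is.finite(v))) {
      stop(sprintf("`%s` must be a complete finite 45-feature vector", nm),
           call. = FALSE)
    }
  }
  fused <- c(unname(left), unname(right))
  names(fused) <- paste0("f", 1:90)
  structure(list(left = left, right = right, fused = fused),
            class = "case_features")
}
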