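# Fixture builders and independent brute-force oracles used across tests.

# Slice from a plain matrix with default spacing.
make_slice <- function(pixels, side = "left") {
  ct_slice(as.matrix(pixels), side = side)
}

# Rectangular polygon whose interior pixel centers are rows r0..r1, cols
# c0..c1 (0-based, inclusive).
rect_polygon <- function(r0, r1, c0, c1) {
  cbind(row = c(r0 - 0.5, r0 - 0.5, r1 + 0.5, r1 + 0.5),
        col = c(c0 - 0.5, c1 + 0.5, c1 + 0.5, c0 - 0.5))
}

# Full-image mask without thresholding (for direct texture-layer tests).
full_mask <- function(pixels) {
  pixels <- as.matrix(pixels)
  structure(list(mask = matrix(TRUE, nrow(pixels), ncol(pixels)),
                 n_pixels = length(pixels)),
            class = "roi_mask")
}

mask_from_logical <- function(m) {
  structure(list(mask = m, n_pixels = sum(m)), class = "roi_mask")
}

# Brute-force nonsymmetric GLCM: explicit double loop over pixels,
# independent of the vectorized implementation.
oracle_glcm_counts <- function(labels, mask, offset) {
  m <- max(labels, na.rm = TRUE) + 1L
  counts <- matrix(0L, m, m)
  nr <- nrow(labels); nc <- ncol(labels)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          mask[r, c] && mask[r2, c2]) {
        i <- labels[r, c] + 1L; j <- labels[r2, c2] + 1L
        counts[i, j] <- counts[i, j] + 1L
      }
    }
  }
  counts
}

# Direct-summation Haralick statistics from a normalized GLCM (scalar loops).
oracle_glcm_stats <- function(p) {
  m <- nrow(p)
  idx <- 0:(m - 1)
  contrast <- 0; energy <- 0; homogeneity <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    contrast <- contrast + p[i, j] * (idx[i] - idx[j])^2
    energy <- energy + p[i, j]^2
    homogeneity <- homogeneity + p[i, j] / (1 + abs(idx[i] - idx[j]))
  }
  mu_i <- sum(rowSums(p) * idx); mu_j <- sum(colSums(p) * idx)
  var_i <- sum(rowSums(p) * (idx - mu_i)^2)
  var_j <- sum(colSums(p) * (idx - mu_j)^2)
  corr <- 0
  if (var_i > 0 && var_j > 0) {
    for (i in seq_len(m)) for (j in seq_len(m)) {
      corr <- corr + p[i, j] * (idx[i] - mu_i) * (idx[j] - mu_j)
    }
    corr <- corr / sqrt(var_i * var_j)
  }
  c(contrast = contrast, correlation = corr, energy = energy,
    homogeneity = homogeneity, variance = var_i)
}

# Random quantized image + mask with at least one co-occurring pair in both
# axis directions.
random_labelled_case <- function(max_dim = 12L, m_levels = 4L) {
  repeat {
    nr <- sample(2:max_dim, 1); nc <- sample(2:max_dim, 1)
    labels <- matrix(sample(0:(m_levels - 1L), nr * nc, replace = TRUE), nr, nc)
    mask <- matrix(stats::runif(nr * nc) < 0.7, nr, nc)
    h <- oracle_glcm_counts(labels, mask, c(0L, 1L))
    v <- oracle_glcm_counts(labels, mask, c(1L, 0L))
    if (sum(h) > 0 && sum(v) > 0) {
      return(list(labels = labels, mask = mask))
    }
  }
}

# Wrap raw labels as a quantized_roi (labels NA outside the mask).
as_quantized <- function(labels, mask, m_val) {
  lab <- labels
  lab[!mask] <- NA_integer_
  structure(list(labels = lab, m_val = as.integer(m_val)),
            class = "quantized_roi")
}

# Toy case table: rows 1-5 carry one exclusion flag each, rows 6-8 are
# clean; all intervals within the window.
toy_case_table <- function() {
  flags <- c("no_axial_cut", "fracture", "vertebro_kypho", "metal_artifact",
             "osteolytic")
  df <- data.frame(case_id = sprintf("c%02d", 1:8),
                   interval_days = rep(5, 8),
                   stringsAsFactors = FALSE)
  for (f in flags) df[[paste0("flag_", f)]] <- FALSE
  for (k in seq_along(flags)) df[k, paste0("flag_", flags[k])] <- TRUE
  df
}
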