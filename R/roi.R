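#' CT slice container
#'
#' A single 2D axial CT slice in Hounsfield units (HU). Coordinates are
#' 0-based `(row, col)`, with rows increasing downward; this convention fixes
#' the meaning of the horizontal/vertical co-occurrence directions.
#'
#' @param pixels numeric matrix of HU values, at least 2 x 2, all finite.
#' @param pixel_spacing length-2 numeric, mm per pixel as `(row, col)`.
#' @param side `"left"` or `"right"` multifidus side.
#' @param vertebral_level optional label in `T12 ... S1`.
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, pixel_spacing = c(0.7, 0.7),
                     side = c("left", "right"), vertebral_level = NA_character_) {
  side <- match.arg(side)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_field("pixels", "must be a numeric matrix")
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop_field("pixels", "must be at least 2 x 2")
  }
  if (!all(is.finite(pixels))) stop_field("pixels", "HU values must be finite")
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0)) {
    stop_field("pixel_spacing", "must be two positive numbers (row, col) in mm")
  }
  structure(
    list(pixels = pixels, pixel_spacing = as.numeric(pixel_spacing),
         side = side, vertebral_level = vertebral_level),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px, %.2f x %.2f mm/px, side = %s, HU range [%.0f, %.0f]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing[1], x$pixel_spacing[2],
              x$side, min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Even-odd rule point-in-polygon test for pixel centers, vectorized over
# points. `pr`/`pc` are point rows/cols; `vr`/`vc` the polygon vertices in the
# same 0-based (row, col) frame. Rows play the role of "y", cols of "x".
point_in_polygon <- function(pr, pc, vr, vc) {
  nv <- length(vr)
  stopifnot(nv >= 3L, length(vc) == nv)
  inside <- rep(FALSE, length(pr))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- (vr[i] > pr) != (vr[j] > pr)
    if (any(crosses)) {
      xint <- (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i]
      inside <- xor(inside, crosses & (pc < xint))
    }
    j <- i
  }
  inside
}

#' Threshold-based ROI on a CT slice
#'
#' Builds the multifidus region-of-interest mask by intersecting a hand-drawn
#' polygon with an HU threshold window: a pixel belongs to the ROI exactly
#' when its center lies inside the polygon (even-odd rule) and its HU value is
#' within `[hu_window[1], hu_window[2]]` inclusive. The default window
#' `[-29, 150]` HU is the prevailing skeletal-muscle convention; it removes
#' both fat (around -100 HU) and bone from the drawn region.
#'
#' @param slice a [ct_slice()].
#' @param polygon numeric matrix with columns `row`, `col` (>= 3 vertices) in
#'   0-based pixel coordinates.
#' @param hu_window numeric length-2, `low < high`, inclusive HU bounds.
#' @return An object of class `roi_mask`: list with logical matrix `mask`
#'   (congruent with the slice) and `n_pixels`.
#' @export
threshold_roi <- function(slice, polygon, hu_window = c(-29, 150)) {
  stopifnot(inherits(slice, "ct_slice"))
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || ncol(polygon) != 2L) {
    stop_field("polygon", "needs >= 3 vertices as a 2-column (row, col) matrix")
  }
  if (length(hu_window) != 2L || !(hu_window[1] < hu_window[2])) {
    stop_field("hu_window", "must be (low, high) with low < high")
  }
  nr <- nrow(slice$pixels); nc <- ncol(slice$pixels)
  if (any(polygon[, 1] < -1 | polygon[, 1] > nr | polygon[, 2] < -1 | polygon[, 2] > nc)) {
    stop_field("polygon", "vertices fall outside the image bounds")
  }
  centers_r <- rep(0:(nr - 1L), times = nc)
  centers_c <- rep(0:(nc - 1L), each = nr)
  inside <- point_in_polygon(centers_r, centers_c, polygon[, 1], polygon[, 2])
  inside <- matrix(inside, nrow = nr, ncol = nc)
  pass <- slice$pixels >= hu_window[1] & slice$pixels <= hu_window[2]
  mask <- inside & pass
  n <- sum(mask)
  if (n == 0L) {
    stop("empty ROI: no pixel is both inside the polygon and within the HU window",
         call. = FALSE)
  }
  structure(list(mask = mask, n_pixels = n), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d x %d, %d pixels in ROI\n",
              nrow(x$mask), ncol(x$mask), x$n_pixels))
  invisible(x)
}

#' Read polygon annotations from JSON
#'
#' The annotation format is a JSON array of objects
#' `{case, side, level, vertices}` where `vertices` is an array of
#' `[row, col]` pairs in 0-based pixel coordinates.
#'
#' @param path JSON file path.
#' @return A list of annotations; each has `case`, `side`, `level` and a
#'   two-column `vertices` matrix.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(a) {
    v <- do.call(rbind, lapply(a$vertices, function(p) as.numeric(unlist(p))))
    colnames(v) <- c("row", "col")
    list(case = a$case, side = a$side, level = a$level %||% NA_character_,
         vertices = v)
  })
}
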