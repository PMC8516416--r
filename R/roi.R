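#' Binary region of interest
#'
#' A `RoiMask` is a 2-D logical mask with an offset into its parent image
#' (0-based, `(y, x)`) and the lateral pixel size so areas can be reported in
#' square micrometres.
#'
#' @param mask logical matrix (rows = y, cols = x).
#' @param offset integer `(y, x)` offset of the mask's top-left corner in the
#'   parent image, 0-based. Default `c(0, 0)`.
#' @param pixel_size_xy um/px (> 0).
#' @param allow_empty allow a mask with no `TRUE` pixel.
#' @return An object of class `RoiMask`.
#' @export
roi_mask <- function(mask, offset = c(0L, 0L), pixel_size_xy,
                     allow_empty = FALSE) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!allow_empty && !any(mask)) {
    sq_stop("FORMAT_ERROR", "RoiMask has no foreground pixel")
  }
  if (any(offset < 0)) sq_stop("FORMAT_ERROR", "offset must be non-negative")
  if (pixel_size_xy <= 0) {
    sq_stop("MISSING_CALIBRATION", "pixel_size_xy must be > 0")
  }
  structure(list(mask = mask, offset = as.integer(offset),
                 pixel_size_xy = pixel_size_xy), class = "RoiMask")
}

#' @export
print.RoiMask <- function(x, ...) {
  cat(sprintf("RoiMask: %d px (%.4g um^2), %d x %d frame, offset (%d, %d)\n",
              sum(x$mask), roi_area_um2(x), nrow(x$mask), ncol(x$mask),
              x$offset[1], x$offset[2]))
  invisible(x)
}

#' Physical area of an ROI
#'
#' @param roi a [roi_mask()].
#' @return Area in square micrometres: foreground pixel count times the
#'   squared pixel size.
#' @export
roi_area_um2 <- function(roi) {
  stopifnot(inherits(roi, "RoiMask"))
  sum(roi$mask) * roi$pixel_size_xy^2
}

#' Subtract one ROI from another
#'
#' Returns `a AND NOT b` after reconciling the two offsets, on `a`'s frame.
#'
#' @param a,b [roi_mask()] objects sharing a pixel size.
#' @return A `RoiMask` (possibly empty).
#' @export
roi_subtract <- function(a, b) {
  stopifnot(inherits(a, "RoiMask"), inherits(b, "RoiMask"))
  if (abs(a$pixel_size_xy - b$pixel_size_xy) > 1e-12) {
    sq_stop("CALIBRATION_MISMATCH",
            "ROIs have different pixel sizes (%g vs %g)",
            a$pixel_size_xy, b$pixel_size_xy)
  }
  out <- a$mask
  # map b's pixels into a's frame
  dy <- b$offset[1] - a$offset[1]
  dx <- b$offset[2] - a$offset[2]
  bi <- which(b$mask, arr.ind = TRUE)
  if (nrow(bi)) {
    ra <- bi[, 1] + dy
    ca <- bi[, 2] + dx
    keep <- ra >= 1 & ra <= nrow(out) & ca >= 1 & ca <= ncol(out)
    out[cbind(ra[keep], ca[keep])] <- FALSE
  }
  roi_mask(out, a$offset, a$pixel_size_xy, allow_empty = TRUE)
}

#' Wide-line selection
#'
#' A polyline in 0-based pixel coordinates with a sampling width across it,
#' the selection used to extract kymographs (30-px-wide line by default in
#' the interface measurements).
#'
#' @param vertices numeric matrix with columns `(x, y)`, at least two rows.
#' @param width line width in pixels (>= 1).
#' @return An object of class `LineRoi`.
#' @export
line_roi <- function(vertices, width = 30) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L || ncol(vertices) != 2L) {
    sq_stop("FORMAT_ERROR", "`vertices` must be an n x 2 (x, y) matrix, n >= 2")
  }
  if (width < 1) sq_stop("FORMAT_ERROR", "line width must be >= 1 px")
  structure(list(vertices = vertices, width = width), class = "LineRoi")
}
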