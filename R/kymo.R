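#' Kymograph container
#'
#' A kymograph is a time-by-position intensity matrix obtained by sampling a
#' wide line over a frame series: rows are frames, columns are arc-length
#' positions along the line (1-px spacing), values are the mean intensity
#' across the line's width.
#'
#' @param values numeric `time x position` matrix.
#' @param frame_interval s between rows.
#' @param pixel_size_xy um per position column.
#' @param source_line optional [line_roi()] the kymograph was sampled from.
#' @return An object of class `Kymograph`.
#' @export
kymograph <- function(values, frame_interval = 120, pixel_size_xy = 0.05,
                      source_line = NULL) {
  values <- as.matrix(values)
  structure(list(values = values, frame_interval = frame_interval,
                 pixel_size_xy = pixel_size_xy, source_line = source_line),
            class = "Kymograph")
}

#' @export
print.Kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d frames x %d positions (%.4g s/frame, %.4g um/px)\n",
              nrow(x$values), ncol(x$values), x$frame_interval,
              x$pixel_size_xy))
  invisible(x)
}

#' @export
dim.Kymograph <- function(x) dim(x$values)

#' Build a kymograph from a frame series and a wide line
#'
#' Samples the line at 1-px arc-length spacing; at each position the
#' intensity is averaged across `width` samples taken along the local normal
#' (bilinear interpolation), matching the wide-line plot-profile convention
#' (30-px width by default). With `width = 1` this reduces to the
#' single-pixel profile.
#'
#' @param frames a `T x Y x X` array, a list of `Y x X` matrices, or an
#'   [image_stack()] (in which case `channel`, `z` select the plane).
#' @param line a [line_roi()].
#' @param width sampling width in px; defaults to the line's width.
#' @param frame_interval,pixel_size_xy calibration attached to the result
#'   (taken from the stack when `frames` is an `ImageStack`).
#' @param channel,z plane selectors when `frames` is an `ImageStack`.
#' @return A [kymograph()] with one row per frame.
#' @export
build_kymograph <- function(frames, line, width = NULL,
                            frame_interval = 120, pixel_size_xy = 0.05,
                            channel = 1L, z = 1L) {
  stopifnot(inherits(line, "LineRoi"))
  if (inherits(frames, "ImageStack")) {
    frame_interval <- frames$frame_interval
    pixel_size_xy <- frames$pixel_size_xy
    d <- dim(frames$data)
    frames <- lapply(seq_len(d[1]), function(t) {
      matrix(frames$data[t, z, channel, , ], d[4], d[5])
    })
  } else if (is.array(frames) && length(dim(frames)) == 3L) {
    d <- dim(frames)
    frames <- lapply(seq_len(d[1]), function(t) matrix(frames[t, , ], d[2], d[3]))
  }
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (is.null(width)) width <- line$width
  ny <- nrow(frames[[1L]]); nx <- ncol(frames[[1L]])

  v <- line$vertices
  seg <- diff(v)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, floor(total), by = 1)
  # point and unit tangent at each arc-length position
  si <- findInterval(s, cum, rightmost.closed = TRUE)
  si <- pmin(si, nrow(seg))
  frac <- (s - cum[si]) / seg_len[si]
  px <- v[si, 1] + frac * seg[si, 1]
  py <- v[si, 2] + frac * seg[si, 2]
  tx <- seg[si, 1] / seg_len[si]
  ty <- seg[si, 2] / seg_len[si]
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = width)
  # sample coordinates: positions x width
  sx <- outer(px, offs, function(p, o) p) - outer(ty, offs)
  sy <- outer(py, offs, function(p, o) p) + outer(tx, offs)
  if (min(sx) < 0 || max(sx) > nx - 1 || min(sy) < 0 || max(sy) > ny - 1) {
    sq_stop("ROI_OUT_OF_BOUNDS", "line (with width %g) exits the image", width)
  }
  vals <- matrix(0, length(frames), length(s))
  for (t in seq_along(frames)) {
    samp <- bilinear(frames[[t]], as.vector(sx), as.vector(sy))
    vals[t, ] <- rowMeans(matrix(samp, length(s), width))
  }
  kymograph(vals, frame_interval, pixel_size_xy, source_line = line)
}

#' Per-frame interface intensity from a kymograph
#'
#' Averages a band of `band_width` columns (20 px by default) around the
#' interface position in each frame, the plot-profile step that yields the
#' raw interface intensity series. When `center` is not given, the interface
#' column defaults to the per-frame argmax column smoothed over time with a
#' running median; the band is shifted inwards where it would exceed the
#' kymograph's columns.
#'
#' @param kymo a [kymograph()].
#' @param band_width band width in columns.
#' @param center optional interface column per frame (1-based), recycled.
#' @return A numeric vector `raw(t)` with attribute `"columns"` (the band
#'   used per frame, as a matrix of start/end columns).
#' @export
interface_profile <- function(kymo, band_width = 20L, center = NULL) {
  stopifnot(inherits(kymo, "Kymograph"))
  vals <- kymo$values
  nt <- nrow(vals); np <- ncol(vals)
  if (band_width > np) {
    sq_stop("BAND_TOO_WIDE", "band width %d exceeds %d kymograph columns",
            band_width, np)
  }
  if (is.null(center)) {
    center <- apply(vals, 1L, which.max)
    if (nt >= 3L) {
      k <- min(5L, if (nt %% 2L == 1L) nt else nt - 1L)
      center <- as.integer(round(stats::runmed(center, k)))
    }
  }
  center <- rep_len(as.integer(center), nt)
  half_lo <- (band_width - 1L) %/% 2L
  lo <- pmin(pmax(center - half_lo, 1L), np - band_width + 1L)
  hi <- lo + band_width - 1L
  raw <- vapply(seq_len(nt), function(t) mean(vals[t, lo[t]:hi[t]]),
                numeric(1))
  attr(raw, "columns") <- cbind(start = lo, end = hi)
  raw
}

#' Background reference set
#'
#' Per-frame mean intensities of three reference regions around the cell,
#' whose average (the apical mean fluorescence) drives the photobleaching
#' correction.
#'
#' @param region_means `T x 3` matrix or data frame of per-frame region
#'   means, one column per reference region.
#' @return An object of class `BackgroundSet` with elements `regions` and
#'   `bg_mean` (per-frame mean of the three region means).
#' @export
background_set <- function(region_means) {
  m <- as.matrix(region_means)
  if (ncol(m) != 3L) {
    sq_stop("FORMAT_ERROR", "exactly 3 background regions are required")
  }
  structure(list(regions = m, bg_mean = rowMeans(m)), class = "BackgroundSet")
}

#' Measure background regions over a frame series
#'
#' @param frames a `T x Y x X` array or list of matrices.
#' @param rois list of exactly three [roi_mask()] objects.
#' @return A [background_set()].
#' @export
measure_background <- function(frames, rois) {
  if (length(rois) != 3L) {
    sq_stop("FORMAT_ERROR", "exactly 3 background ROIs are required")
  }
  if (is.array(frames) && length(dim(frames)) == 3L) {
    d <- dim(frames)
    frames <- lapply(seq_len(d[1]), function(t) matrix(frames[t, , ], d[2], d[3]))
  }
  m <- vapply(rois, function(roi) {
    sel <- which(roi$mask, arr.ind = TRUE)
    sel[, 1] <- sel[, 1] + roi$offset[1]
    sel[, 2] <- sel[, 2] + roi$offset[2]
    vapply(frames, function(fr) mean(fr[sel]), numeric(1))
  }, numeric(length(frames)))
  background_set(matrix(m, ncol = 3L))
}

#' Propose three background regions outside a cell mask
#'
#' Deterministically scans a coarse grid and returns the first three
#' `size x size` windows that lie entirely outside the supplied mask, spaced
#' at least one window apart.
#'
#' @param exclude_mask logical matrix marking pixels to avoid.
#' @param size window side, px.
#' @param pixel_size_xy calibration for the returned ROIs.
#' @return List of three [roi_mask()] objects.
#' @export
propose_background_rois <- function(exclude_mask, size = 10L,
                                    pixel_size_xy = 0.05) {
  ny <- nrow(exclude_mask); nx <- ncol(exclude_mask)
  found <- list()
  step <- 2L * size
  for (r0 in seq(1L, ny - size + 1L, by = step)) {
    for (c0 in seq(1L, nx - size + 1L, by = step)) {
      win <- exclude_mask[r0:(r0 + size - 1L), c0:(c0 + size - 1L)]
      if (!any(win)) {
        m <- matrix(TRUE, size, size)
        found[[length(found) + 1L]] <-
          roi_mask(m, offset = c(r0 - 1L, c0 - 1L), pixel_size_xy)
        if (length(found) == 3L) return(found)
      }
    }
  }
  sq_stop("DEGENERATE_BACKGROUND",
          "could not place 3 background windows outside the mask")
}

#' Photobleaching correction factor
#'
#' The per-frame correction factor is the ratio of the apical mean
#' fluorescence at the first frame to that at frame `t`:
#' `bg_mean(t0) / bg_mean(t)`. At `t0` the factor is exactly 1.
#'
#' @param bg a [background_set()].
#' @param t frame indices (1-based); defaults to all frames.
#' @return Numeric vector of correction factors.
#' @export
bleach_correction_factor <- function(bg, t = seq_along(bg$bg_mean)) {
  stopifnot(inherits(bg, "BackgroundSet"))
  if (any(bg$bg_mean[t] <= 0)) {
    sq_stop("DEGENERATE_BACKGROUND",
            "background mean is <= 0 at a requested frame")
  }
  bg$bg_mean[1L] / bg$bg_mean[t]
}

#' Bleach-correct and normalise an interface intensity series
#'
#' Applies the per-frame bleaching correction
#' `corrected(t) = raw(t) * bg_mean(t0) / bg_mean(t)` and then normalises to
#' the first frame's apical mean fluorescence:
#' `normalized(t) = corrected(t) / bg_mean(t0)`. Multiplying every frame
#' (signal and background alike) by any positive scalar series leaves the
#' normalised series unchanged.
#'
#' @param raw per-frame raw interface intensities (a.u.), e.g. from
#'   [interface_profile()].
#' @param bg a [background_set()] covering the same frames.
#' @param frame_interval s per frame, for the `t_s` column.
#' @return A `data.frame` of class `IntensitySeries` with columns `frame`,
#'   `t_s`, `raw`, `factor`, `corrected`, `normalized`.
#' @export
correct_and_normalize <- function(raw, bg, frame_interval = 120) {
  stopifnot(inherits(bg, "BackgroundSet"))
  raw <- as.numeric(raw)
  if (length(raw) != length(bg$bg_mean)) {
    sq_stop("FORMAT_ERROR", "series (%d) and background (%d) cover different frames",
            length(raw), length(bg$bg_mean))
  }
  fac <- bleach_correction_factor(bg)
  corrected <- raw * fac
  normalized <- corrected / bg$bg_mean[1L]
  out <- data.frame(frame = seq_along(raw) - 1L,
                    t_s = (seq_along(raw) - 1L) * frame_interval,
                    raw = raw, factor = fac, corrected = corrected,
                    normalized = normalized)
  class(out) <- c("IntensitySeries", "data.frame")
  out
}
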