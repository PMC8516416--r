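#' Calibrated multi-dimensional image stack
#'
#' An `ImageStack` holds a five-dimensional intensity array in canonical
#' `T x Z x C x Y x X` order together with its physical calibration: the
#' lateral pixel size (micrometres per pixel), the axial step between
#' z-slices (micrometres) and the interval between frames (seconds).
#' Intensities are arbitrary detector units (a.u.).
#'
#' @param data numeric array with exactly five dimensions, `T x Z x C x Y x X`.
#' @param pixel_size_xy lateral calibration, um/px (> 0).
#' @param z_step axial slice spacing, um (> 0). Default 0.5.
#' @param frame_interval time between frames, s (> 0). Default 120.
#' @param channel_names optional character vector, one name per channel.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(data, pixel_size_xy, z_step = 0.5,
                        frame_interval = 120, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 5L) {
    sq_stop("FORMAT_ERROR", "`data` must be a 5-D array (T x Z x C x Y x X)")
  }
  if (any(dim(data) < 1L)) {
    sq_stop("FORMAT_ERROR", "all five stack dimensions must be >= 1")
  }
  if (!is.numeric(pixel_size_xy) || pixel_size_xy <= 0) {
    sq_stop("MISSING_CALIBRATION", "pixel_size_xy must be a positive number")
  }
  if (z_step <= 0) sq_stop("MISSING_CALIBRATION", "z_step must be > 0")
  if (frame_interval <= 0) {
    sq_stop("MISSING_CALIBRATION", "frame_interval must be > 0")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(dim(data)[3L]))
  }
  stopifnot(length(channel_names) == dim(data)[3L])
  structure(
    list(data = data, pixel_size_xy = pixel_size_xy, z_step = z_step,
         frame_interval = frame_interval,
         channel_names = as.character(channel_names)),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "ImageStack: %d frame(s) x %d z x %d channel(s) x %d x %d px\n",
    d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  pixel size %.4g um/px, z step %.4g um, frame interval %.4g s\n",
              x$pixel_size_xy, x$z_step, x$frame_interval))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

#' Write a calibrated stack to disk
#'
#' The stack is written as a multi-page TIFF (pages ordered channel-fastest,
#' then z, then time) plus a JSON sidecar (`<path>.json`) carrying the axis
#' layout, calibration and the intensity scale used to map arbitrary units
#' into the TIFF's `[0, 1]` sample range. Integer-valued stacks up to 16 bits
#' round-trip exactly; other data round-trip to better than 1e-6 relative.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  mx <- max(stack$data)
  if (min(stack$data) < 0) {
    sq_stop("FORMAT_ERROR", "negative intensities cannot be serialised")
  }
  int_data <- all(stack$data == round(stack$data)) && mx <= 65535
  if (int_data) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- 2^ceiling(log2(max(mx, 1)))
    bits <- 32L
  }
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    k <- k + 1L
    pages[[k]] <- matrix(stack$data[t, z, ch, , ], d[4], d[5]) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta <- list(axes = "TZCYX", dim = d, pixel_size_xy = stack$pixel_size_xy,
               z_step = stack$z_step, frame_interval = stack$frame_interval,
               channel_names = stack$channel_names, scale = scale,
               integer_data = int_data)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated stack from disk
#'
#' Reads a TIFF written by [write_stack()] (using its JSON sidecar), or any
#' plain multi-page TIFF, in which case pages are interpreted as frames
#' (`Z = C = 1`) and the calibration must come from the TIFF resolution tags
#' or from the `pixel_size_xy` override.
#'
#' @param path TIFF path.
#' @param pixel_size_xy optional calibration override, um/px.
#' @param z_step,frame_interval optional calibration overrides used when no
#'   sidecar is present.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_xy = NULL, z_step = 0.5,
                       frame_interval = 120) {
  if (!file.exists(path)) sq_stop("FORMAT_ERROR", "no such file: %s", path)
  sidecar <- paste0(path, ".json")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(meta$axes, "TZCYX")) {
      sq_stop("FORMAT_ERROR", "unknown axis layout in sidecar: %s", meta$axes)
    }
    d <- as.integer(meta$dim)
    if (length(pages) != d[1] * d[2] * d[3]) {
      sq_stop("FORMAT_ERROR", "page count does not match sidecar dimensions")
    }
    arr <- array(0, d)
    k <- 0L
    for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
      k <- k + 1L
      v <- pages[[k]] * meta$scale
      if (isTRUE(meta$integer_data)) v <- round(v)
      arr[t, z, ch, , ] <- v
    }
    return(image_stack(arr, as.numeric(meta$pixel_size_xy),
                       as.numeric(meta$z_step),
                       as.numeric(meta$frame_interval), meta$channel_names))
  }
  ps <- pixel_size_xy
  if (is.null(ps)) {
    xres <- attr(pages[[1]], "x.resolution")
    unit <- attr(pages[[1]], "resolution.unit")
    if (!is.null(xres) && xres > 0) {
      # resolution is px per unit; assume centimetres unless inches stated
      per_um <- if (identical(unit, "inch")) xres / 25400 else xres / 10000
      ps <- 1 / per_um
    }
  }
  if (is.null(ps)) {
    sq_stop("MISSING_CALIBRATION",
            "TIFF has no resolution metadata; supply pixel_size_xy")
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(length(pages), 1L, 1L, ny, nx))
  for (t in seq_along(pages)) {
    pg <- pages[[t]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
    arr[t, 1, 1, , ] <- pg
  }
  image_stack(arr, ps, z_step, frame_interval)
}

#' Sum z-projection around a central slice
#'
#' Sums `n_slices` consecutive z-planes centred on `z_center` for one channel
#' and frame, the standard projection used before any interface measurement
#' (three slices 0.5 um apart by default). Output is double precision so the
#' sum never clips, whatever the input range.
#'
#' @param stack an [image_stack()].
#' @param channel channel index (1-based).
#' @param t frame index (1-based).
#' @param z_center central slice index (1-based).
#' @param n_slices number of slices summed (odd; default 3).
#' @return A `Y x X` numeric matrix.
#' @export
sum_project <- function(stack, channel = 1L, t = 1L, z_center, n_slices = 3L) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  half <- (n_slices - 1L) %/% 2L
  zs <- (z_center - half):(z_center - half + n_slices - 1L)
  if (min(zs) < 1L || max(zs) > d[2]) {
    sq_stop("Z_RANGE_ERROR",
            "projection window [%d, %d] outside stack z-range [1, %d]",
            min(zs), max(zs), d[2])
  }
  out <- matrix(0, d[4], d[5])
  for (z in zs) out <- out + matrix(stack$data[t, z, channel, , ], d[4], d[5])
  out
}
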