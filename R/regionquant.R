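#' Region specification for interface quantification
#'
#' Describes the fixed-size measurement regions used at cell-cell
#' interfaces: an apical ROI of 1 x 3 um summed over three z-planes at the
#' adherens-junction level, or a lateral ROI of 1 x 4 um summed over all
#' planes between 3 and 6 um below the apical plane (endpoints inclusive).
#'
#' @param kind `"apical"` or `"lateral"`.
#' @param roi_size_um `(width, length)` of the ROI in um; defaults to
#'   `c(1, 3)` (apical) or `c(1, 4)` (lateral).
#' @param apical_planes number of planes summed for an apical region.
#' @param lateral_depth_um `(shallow, deep)` window below the apical plane,
#'   um, for a lateral region.
#' @param lateral_planes optional override: take only this many planes
#'   (starting at the shallow end) instead of the full depth window.
#' @return An object of class `RegionSpec`.
#' @export
region_spec <- function(kind = c("apical", "lateral"), roi_size_um = NULL,
                        apical_planes = 3L, lateral_depth_um = c(3, 6),
                        lateral_planes = NULL) {
  kind <- match.arg(kind)
  if (is.null(roi_size_um)) {
    roi_size_um <- if (kind == "apical") c(1, 3) else c(1, 4)
  }
  if (any(roi_size_um <= 0)) {
    sq_stop("INVALID_PARAM", "roi_size_um must be positive")
  }
  structure(list(kind = kind, roi_size_um = as.numeric(roi_size_um),
                 apical_planes = as.integer(apical_planes),
                 lateral_depth_um = as.numeric(lateral_depth_um),
                 lateral_planes = lateral_planes),
            class = "RegionSpec")
}

#' Sum-projection over a region's z-window
#'
#' Apical regions sum `apical_planes` consecutive planes starting at
#' `apical_z` (z increasing with depth); lateral regions sum every plane
#' whose depth below `apical_z` lies in `lateral_depth_um` (inclusive).
#'
#' @param stack an [image_stack()].
#' @param spec a [region_spec()].
#' @param apical_z 1-based index of the apical (adherens junction) plane.
#' @param channel,t plane selectors.
#' @return A `Y x X` numeric matrix.
#' @export
region_projection <- function(stack, spec, apical_z, channel = 1L, t = 1L) {
  stopifnot(inherits(stack, "ImageStack"), inherits(spec, "RegionSpec"))
  d <- dim(stack$data)
  zs <- if (spec$kind == "apical") {
    apical_z:(apical_z + spec$apical_planes - 1L)
  } else {
    depths <- ((1:d[2]) - apical_z) * stack$z_step
    sel <- which(depths >= spec$lateral_depth_um[1] - 1e-9 &
                   depths <= spec$lateral_depth_um[2] + 1e-9)
    if (!is.null(spec$lateral_planes)) {
      sel <- utils::head(sel, spec$lateral_planes)
    }
    sel
  }
  if (!length(zs) || min(zs) < 1L || max(zs) > d[2]) {
    sq_stop("Z_RANGE_ERROR", "z-window outside the stack")
  }
  out <- matrix(0, d[4], d[5])
  for (z in zs) out <- out + matrix(stack$data[t, z, channel, , ], d[4], d[5])
  out
}

#' Mean intensity in a fixed-size interface ROI
#'
#' Places the region's rectangle with its long axis along the interface
#' direction, centred on the anchor point, and returns the arithmetic mean
#' of the pixels inside.
#'
#' @param image 2-D numeric matrix.
#' @param anchor_px `(x, y)` interface midpoint, 0-based px.
#' @param spec a [region_spec()].
#' @param pixel_size_xy um/px.
#' @param direction_deg interface direction in degrees (0 = +x, 90 = +y),
#'   the long axis of the rectangle.
#' @return Mean intensity, a.u.
#' @export
interface_mean <- function(image, anchor_px, spec, pixel_size_xy,
                           direction_deg = 90) {
  stopifnot(inherits(spec, "RegionSpec"))
  w_px <- spec$roi_size_um[1] / pixel_size_xy
  l_px <- spec$roi_size_um[2] / pixel_size_xy
  th <- direction_deg * pi / 180
  e <- c(cos(th), sin(th))
  ny <- nrow(image); nx <- ncol(image)
  corners_u <- c(-1, 1, -1, 1) * l_px / 2
  corners_v <- c(-1, -1, 1, 1) * w_px / 2
  cx <- anchor_px[1] + corners_u * e[1] - corners_v * e[2]
  cy <- anchor_px[2] + corners_u * e[2] + corners_v * e[1]
  if (min(cx) < 0 || max(cx) > nx - 1 || min(cy) < 0 || max(cy) > ny - 1) {
    sq_stop("ROI_OUT_OF_BOUNDS", "interface ROI does not fit in the image")
  }
  X <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
  Y <- matrix(seq_len(ny) - 1, ny, nx)
  U <- (X - anchor_px[1]) * e[1] + (Y - anchor_px[2]) * e[2]
  V <- -(X - anchor_px[1]) * e[2] + (Y - anchor_px[2]) * e[1]
  sel <- abs(U) <= l_px / 2 & abs(V) <= w_px / 2
  if (!any(sel)) sq_stop("ROI_OUT_OF_BOUNDS", "interface ROI covers no pixel")
  mean(image[sel])
}

#' Normalise an interface value to epidermal references
#'
#' @param value measured interface mean, a.u.
#' @param epidermal_values means of neighbouring epidermal interfaces, a.u.
#' @return `value / mean(epidermal_values)`.
#' @export
normalize_to_epidermal <- function(value, epidermal_values) {
  if (!length(epidermal_values) || mean(epidermal_values) <= 0) {
    sq_stop("DEGENERATE_REFERENCE",
            "epidermal reference list is empty or non-positive")
  }
  value / mean(epidermal_values)
}
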