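#' Cluster filter parameters
#'
#' Size and intensity filters applied to detected particles: clusters are
#' retained when their area lies in `[min_area, max_area]` (inclusive) and
#' their mean intensity reaches the apical-mean-dependent threshold
#' `slope * apical_mean + intercept`. The defaults are the calibrated
#' values used for the inter-nuclear Notch clusters: 0.03-0.2 um^2 and
#' `0.2654 * apical mean + 227.6` a.u.
#'
#' @param min_area minimal cluster area, um^2.
#' @param max_area maximal cluster area, um^2.
#' @param slope dimensionless slope of the intensity threshold.
#' @param intercept intensity-threshold intercept, a.u.
#' @return An object of class `FilterParams`.
#' @export
filter_params <- function(min_area = 0.03, max_area = 0.2,
                          slope = 0.2654, intercept = 227.6) {
  if (!(min_area > 0 && min_area < max_area)) {
    sq_stop("INVALID_PARAM", "need 0 < min_area < max_area")
  }
  if (slope < 0 || intercept < 0) {
    sq_stop("INVALID_PARAM", "slope and intercept must be >= 0")
  }
  structure(list(min_area = min_area, max_area = max_area,
                 slope = slope, intercept = intercept),
            class = "FilterParams")
}

#' Pair of segmented nuclei
#'
#' @param roi_a,roi_b disjoint non-empty [roi_mask()] objects, ordered by
#'   centroid x.
#' @param centroid_a,centroid_b `(x, y)` centroids in 0-based px.
#' @param z_offset_um signed axial separation of the nuclear centroids, um.
#' @return An object of class `NucleiPair`.
#' @export
nuclei_pair <- function(roi_a, roi_b, centroid_a, centroid_b,
                        z_offset_um = 0) {
  stopifnot(inherits(roi_a, "RoiMask"), inherits(roi_b, "RoiMask"))
  if (!any(roi_a$mask) || !any(roi_b$mask)) {
    sq_stop("SEGMENTATION_FAILED", "both nuclei ROIs must be non-empty")
  }
  if (any(roi_a$mask & roi_b$mask)) {
    sq_stop("SEGMENTATION_FAILED", "nuclei ROIs overlap")
  }
  structure(list(roi_a = roi_a, roi_b = roi_b,
                 centroid_a = as.numeric(centroid_a),
                 centroid_b = as.numeric(centroid_b),
                 z_offset_um = z_offset_um), class = "NucleiPair")
}

mask_centroid <- function(mask) {
  ij <- which(mask, arr.ind = TRUE)
  c(x = mean(ij[, 2]) - 1, y = mean(ij[, 1]) - 1)
}

#' Segment the two nuclei in a nuclear-channel image
#'
#' Applies Otsu's global threshold, labels connected components
#' (8-connectivity), keeps the two largest components of at least `min_px`
#' pixels, fills their holes and orders them by centroid x.
#'
#' @param nuclear_image 2-D numeric matrix (nuclear channel).
#' @param pixel_size_xy um/px for the returned ROIs.
#' @param min_px minimum component size considered a nucleus.
#' @param z_offset_um signed axial centroid separation, if known.
#' @return A [nuclei_pair()].
#' @export
segment_nuclei <- function(nuclear_image, pixel_size_xy = 0.05,
                           min_px = 50L, z_offset_um = 0) {
  rng <- range(nuclear_image)
  if (diff(rng) <= 0) {
    sq_stop("SEGMENTATION_FAILED", "nuclear image is constant")
  }
  img01 <- (nuclear_image - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(img01), range = c(0, 1), levels = 256L)
  lbl <- label8(img01 > th)
  sizes <- tabulate(lbl[lbl > 0L])
  big <- which(sizes >= min_px)
  if (length(big) < 2L) {
    sq_stop("SEGMENTATION_FAILED",
            "found %d component(s) >= %d px; need 2", length(big), min_px)
  }
  top2 <- big[order(sizes[big], decreasing = TRUE)][1:2]
  masks <- lapply(top2, function(k) {
    m <- lbl == k
    as.matrix(EBImage::fillHull(EBImage::Image(m * 1))) > 0
  })
  cents <- lapply(masks, mask_centroid)
  ord <- order(vapply(cents, `[[`, numeric(1), "x"))
  nuclei_pair(
    roi_mask(masks[[ord[1]]], pixel_size_xy = pixel_size_xy),
    roi_mask(masks[[ord[2]]], pixel_size_xy = pixel_size_xy),
    cents[[ord[1]]], cents[[ord[2]]], z_offset_um = z_offset_um)
}

# pixels of the mask with at least one 4-neighbour outside it
mask_boundary <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- mask
  core <- pad[2:(ny + 1L), 2:(nx + 1L)] &
    pad[1:ny, 2:(nx + 1L)] & pad[3:(ny + 2L), 2:(nx + 1L)] &
    pad[2:(ny + 1L), 1:nx] & pad[2:(ny + 1L), 3:(nx + 2L)]
  mask & !core
}

#' Quality-control check on a nuclei pair
#'
#' Flags the two degenerate configurations excluded from cluster counting:
#' `TOO_CLOSE` when the minimum boundary-to-boundary gap between the two
#' nuclei is below `min_gap_px`, and `Z_STACKED` when the nuclei overlap in
#' xy (bounding-box overlap fraction above `max_xy_overlap_frac`) while
#' sitting more than `z_limit_um` apart axially (one nucleus above the
#' other instead of face to face). Otherwise `OK`.
#'
#' @param pair a [nuclei_pair()].
#' @param min_gap_px minimum allowed gap, px.
#' @param max_xy_overlap_frac bounding-box overlap fraction triggering the
#'   z-stacking test.
#' @param z_limit_um axial separation limit, um.
#' @return One of `"OK"`, `"TOO_CLOSE"`, `"Z_STACKED"`.
#' @export
qc_check <- function(pair, min_gap_px = 3, max_xy_overlap_frac = 0.3,
                     z_limit_um = 1.5) {
  stopifnot(inherits(pair, "NucleiPair"))
  bb <- function(m) {
    ij <- which(m, arr.ind = TRUE)
    c(r1 = min(ij[, 1]), r2 = max(ij[, 1]), c1 = min(ij[, 2]), c2 = max(ij[, 2]))
  }
  ba <- bb(pair$roi_a$mask); bbx <- bb(pair$roi_b$mask)
  ov_r <- max(0, min(ba["r2"], bbx["r2"]) - max(ba["r1"], bbx["r1"]) + 1)
  ov_c <- max(0, min(ba["c2"], bbx["c2"]) - max(ba["c1"], bbx["c1"]) + 1)
  area_a <- (ba["r2"] - ba["r1"] + 1) * (ba["c2"] - ba["c1"] + 1)
  area_b <- (bbx["r2"] - bbx["r1"] + 1) * (bbx["c2"] - bbx["c1"] + 1)
  overlap_frac <- (ov_r * ov_c) / min(area_a, area_b)
  if (overlap_frac > max_xy_overlap_frac &&
      abs(pair$z_offset_um) > z_limit_um) {
    return("Z_STACKED")
  }
  pa <- which(mask_boundary(pair$roi_a$mask), arr.ind = TRUE)
  pb <- which(mask_boundary(pair$roi_b$mask), arr.ind = TRUE)
  gap <- sqrt(min(outer(pa[, 1], pb[, 1], `-`)^2 +
                    outer(pa[, 2], pb[, 2], `-`)^2))
  if (gap < min_gap_px) return("TOO_CLOSE")
  "OK"
}

#' Ovoid mask enclosing both nuclei
#'
#' Constructs the filled ellipse centred at the midpoint of the two nuclear
#' centroids with its major axis along the centroid-centroid direction: the
#' semi-major axis is the largest axial extent of the nuclei pixels plus
#' `margin_px`, and the semi-minor axis the smallest value such that every
#' nucleus pixel lies inside (at least the transverse extent plus
#' `margin_px`). Both nuclei ROIs are therefore contained in the result.
#'
#' @param pair a [nuclei_pair()].
#' @param margin_px growth margin, px.
#' @return A full-frame [roi_mask()].
#' @export
ovoid_mask <- function(pair, margin_px = 3) {
  stopifnot(inherits(pair, "NucleiPair"))
  m <- pair$roi_a$mask | pair$roi_b$mask
  ij <- which(m, arr.ind = TRUE)
  px <- ij[, 2] - 1; py <- ij[, 1] - 1
  mid <- (pair$centroid_a + pair$centroid_b) / 2
  ax <- pair$centroid_b - pair$centroid_a
  len <- sqrt(sum(ax^2))
  e <- if (len > 0) ax / len else c(1, 0)
  u <- (px - mid[1]) * e[1] + (py - mid[2]) * e[2]
  v <- -(px - mid[1]) * e[2] + (py - mid[2]) * e[1]
  a <- max(abs(u)) + margin_px
  b <- max(abs(v)) + margin_px
  inside_b <- abs(v) < a # all, since |v| <= b-ish << a usually; guard anyway
  req_b <- abs(v[inside_b]) / sqrt(1 - (u[inside_b] / a)^2)
  b <- max(b, max(req_b))
  ny <- nrow(m); nx <- ncol(m)
  X <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
  Y <- matrix(seq_len(ny) - 1, ny, nx)
  U <- (X - mid[1]) * e[1] + (Y - mid[2]) * e[2]
  V <- -(X - mid[1]) * e[2] + (Y - mid[2]) * e[1]
  roi_mask((U / a)^2 + (V / b)^2 <= 1, pixel_size_xy = pair$roi_a$pixel_size_xy)
}

#' Inter-nuclear search region
#'
#' Subtracts both nuclei ROIs from the ovoid mask, leaving the region
#' between the two nuclei in which clusters are counted.
#'
#' @param ovoid the [ovoid_mask()].
#' @param pair the [nuclei_pair()].
#' @return A [roi_mask()].
#' @export
internuclear_roi <- function(ovoid, pair) {
  out <- roi_subtract(roi_subtract(ovoid, pair$roi_a), pair$roi_b)
  if (!any(out$mask)) {
    sq_stop("EMPTY_SEARCH_REGION", "nuclei cover the whole ovoid mask")
  }
  out
}

#' Particle analysis inside an ROI
#'
#' Detects connected components (8-connectivity) of pixels strictly above
#' `threshold` and inside `roi`, and reports for each particle its pixel
#' count, physical area and the mean of the ORIGINAL image intensities over
#' its pixels, plus the centroid in 0-based px.
#'
#' @param image 2-D numeric matrix.
#' @param roi a [roi_mask()] within the image.
#' @param threshold intensity threshold, a.u.
#' @return A `data.frame` with columns `pixel_count`, `area_um2`,
#'   `mean_intensity`, `x_px`, `y_px` (possibly zero rows).
#' @export
analyse_particles <- function(image, roi, threshold) {
  stopifnot(inherits(roi, "RoiMask"))
  sel <- matrix(FALSE, nrow(image), ncol(image))
  ij <- which(roi$mask, arr.ind = TRUE)
  ij[, 1] <- ij[, 1] + roi$offset[1]
  ij[, 2] <- ij[, 2] + roi$offset[2]
  keep <- ij[, 1] >= 1 & ij[, 1] <= nrow(image) &
    ij[, 2] >= 1 & ij[, 2] <= ncol(image)
  sel[ij[keep, , drop = FALSE]] <- TRUE
  mask <- sel & (image > threshold)
  lbl <- label8(mask)
  nlab <- max(lbl)
  if (nlab == 0L) {
    return(data.frame(pixel_count = integer(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0), x_px = numeric(0),
                      y_px = numeric(0)))
  }
  ij <- which(lbl > 0L, arr.ind = TRUE)
  lab <- lbl[ij]
  vals <- image[ij]
  cnt <- tabulate(lab, nlab)
  data.frame(
    pixel_count = cnt,
    area_um2 = cnt * roi$pixel_size_xy^2,
    mean_intensity = as.numeric(tapply(vals, lab, mean)),
    x_px = as.numeric(tapply(ij[, 2] - 1, lab, mean)),
    y_px = as.numeric(tapply(ij[, 1] - 1, lab, mean)))
}

#' Apical-mean-dependent intensity threshold
#'
#' The minimal mean intensity a cluster must reach, linear in the apical
#' mean fluorescence: `slope * apical_mean + intercept`
#' (default `0.2654 * apical_mean + 227.6`).
#'
#' @param apical_mean apical mean fluorescence, a.u. (>= 0).
#' @param params a [filter_params()].
#' @return Threshold intensity, a.u.
#' @export
intensity_threshold <- function(apical_mean, params = filter_params()) {
  if (any(apical_mean < 0)) {
    sq_stop("INVALID_PARAM", "apical_mean must be >= 0")
  }
  params$slope * apical_mean + params$intercept
}

#' Apply the size and intensity filters to detected particles
#'
#' Keeps particles whose area lies within `[min_area, max_area]` (inclusive,
#' with a 1e-9 um^2 tolerance against floating-point representation of the
#' bounds) and whose mean intensity is at least
#' [intensity_threshold()] of the apical mean. Order is preserved; the
#' filter is idempotent.
#'
#' @param particles data frame from [analyse_particles()].
#' @param params a [filter_params()].
#' @param apical_mean apical mean fluorescence, a.u.
#' @return The retained subset of `particles`.
#' @export
filter_clusters <- function(particles, params = filter_params(),
                            apical_mean = 0) {
  eps <- 1e-9
  thr <- intensity_threshold(apical_mean, params)
  keep <- particles$area_um2 >= params$min_area - eps &
    particles$area_um2 <= params$max_area + eps &
    particles$mean_intensity >= thr
  particles[keep, , drop = FALSE]
}

#' Count inter-nuclear clusters over a time-lapse
#'
#' Runs the full counting macro on every frame of a two-channel stack:
#' sum-project both channels around `z_center`, segment the nuclei on the
#' nuclear channel, run the QC check, build the ovoid and inter-nuclear
#' ROI, autothreshold the ROI's intensities with the Renyi-entropy method
#' (256-bin min-max histogram), detect particles and apply the size and
#' intensity filters. Frames failing QC (or any stage) report zero clusters
#' with the reason and are thereby excluded from the analysis.
#'
#' @param stack an [image_stack()] with signal and nuclear channels.
#' @param signal_channel,nuclear_channel channel indices.
#' @param params a [filter_params()].
#' @param apical_mean apical mean fluorescence per frame (scalar recycled),
#'   on the same projection scale as the signal channel.
#' @param z_center central slice of the 3-slice projection; defaults to the
#'   middle slice.
#' @param n_slices slices summed in the projection.
#' @param margin_px ovoid growth margin.
#' @param min_gap_px,max_xy_overlap_frac,z_limit_um QC parameters, see
#'   [qc_check()].
#' @param nuclei_z_offset_um axial nuclear separation passed to QC.
#' @return An object of class `ClusterCountResult`: list with `frames`
#'   (per-frame data frame: frame, qc_status, n_clusters, apical_mean,
#'   threshold_used) and `clusters` (per-cluster data frame: frame,
#'   area_um2, mean_intensity, x_px, y_px).
#' @export
count_timecourse <- function(stack, signal_channel = 1L, nuclear_channel = 2L,
                             params = filter_params(), apical_mean,
                             z_center = NULL, n_slices = 3L, margin_px = 3,
                             min_gap_px = 3, max_xy_overlap_frac = 0.3,
                             z_limit_um = 1.5, nuclei_z_offset_um = 0) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  if (max(signal_channel, nuclear_channel) > d[3]) {
    sq_stop("FORMAT_ERROR", "requested channel not present in the stack")
  }
  if (is.null(z_center)) z_center <- (d[2] + 1L) %/% 2L
  apical_mean <- rep_len(apical_mean, d[1])
  frames <- data.frame(frame = seq_len(d[1]), qc_status = NA_character_,
                       n_clusters = 0L, apical_mean = apical_mean,
                       threshold_used = NA_real_)
  clusters <- list()
  for (t in seq_len(d[1])) {
    status <- tryCatch({
      sig <- sum_project(stack, signal_channel, t, z_center, n_slices)
      nuc <- sum_project(stack, nuclear_channel, t, z_center, n_slices)
      pair <- segment_nuclei(nuc, pixel_size_xy = stack$pixel_size_xy,
                             z_offset_um = nuclei_z_offset_um)
      qc <- qc_check(pair, min_gap_px, max_xy_overlap_frac, z_limit_um)
      if (qc != "OK") {
        qc
      } else {
        roi <- internuclear_roi(ovoid_mask(pair, margin_px), pair)
        h <- intensity_histogram(sig[roi$mask], 256L)
        tb <- renyi_threshold(h$counts)
        thr <- h$threshold_value(tb)
        parts <- analyse_particles(sig, roi, thr)
        kept <- filter_clusters(parts, params, apical_mean[t])
        frames$n_clusters[t] <- nrow(kept)
        frames$threshold_used[t] <- thr
        if (nrow(kept)) {
          clusters[[length(clusters) + 1L]] <- cbind(frame = t, kept)
        }
        "OK"
      }
    }, sopquant_error = function(e) "FAILED")
    frames$qc_status[t] <- status
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(frame = integer(0), pixel_count = integer(0),
               area_um2 = numeric(0), mean_intensity = numeric(0),
               x_px = numeric(0), y_px = numeric(0))
  structure(list(frames = frames, clusters = clusters, params = params),
            class = "ClusterCountResult")
}

#' @export
print.ClusterCountResult <- function(x, ...) {
  ok <- x$frames$qc_status == "OK"
  cat(sprintf("ClusterCountResult: %d frame(s), %d passed QC\n",
              nrow(x$frames), sum(ok)))
  if (any(ok)) {
    cat(sprintf("  clusters per OK frame: %s\n",
                paste(x$frames$n_clusters[ok], collapse = " ")))
  }
  invisible(x)
}
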