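#' Acquisition model for synthetic imaging
#'
#' Collects the camera/scan parameters the generator needs: calibration,
#' stack geometry, the photobleaching rate and the shot/read noise model.
#' Noise is `Poisson(signal * poisson_scale) / poisson_scale` (shot noise;
#' `poisson_scale` is the photon yield per arbitrary unit, `Inf` disables it)
#' plus additive zero-mean Gaussian read noise of standard deviation
#' `gaussian_sigma`.
#'
#' Defaults mirror the imaging this pipeline targets: 0.05 um/px over a
#' 256 x 256 px field, 9 z-slices 0.5 um apart, 120-s frames for division
#' time-lapse and 2-s frames when a high-time-resolution model is requested.
#'
#' @param pixel_size_xy um/px (> 0).
#' @param z_step um between z-slices (> 0).
#' @param frame_interval s between frames.
#' @param bleach_rate photobleaching rate per frame (>= 0); intensities decay
#'   as `exp(-bleach_rate * t)` with `t` the 0-based frame index.
#' @param gaussian_sigma read-noise standard deviation, a.u.
#' @param poisson_scale photons per a.u. (shot noise); `Inf` for none.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param field_px `(ny, nx)` field size in pixels.
#' @param n_z number of z-slices.
#' @param n_frames number of frames.
#' @return An object of class `AcquisitionModel`.
#' @export
acquisition_model <- function(pixel_size_xy = 0.05, z_step = 0.5,
                              frame_interval = 120, bleach_rate = 0,
                              gaussian_sigma = 0, poisson_scale = Inf,
                              seed = 1L, field_px = c(256L, 256L),
                              n_z = 9L, n_frames = 1L) {
  if (pixel_size_xy <= 0) sq_stop("INVALID_PARAM", "pixel_size_xy must be > 0")
  if (z_step <= 0) sq_stop("INVALID_PARAM", "z_step must be > 0")
  if (bleach_rate < 0) sq_stop("INVALID_PARAM", "bleach_rate must be >= 0")
  if (gaussian_sigma < 0) sq_stop("INVALID_PARAM", "gaussian_sigma must be >= 0")
  if (poisson_scale <= 0) sq_stop("INVALID_PARAM", "poisson_scale must be > 0")
  structure(
    list(pixel_size_xy = pixel_size_xy, z_step = z_step,
         frame_interval = frame_interval, bleach_rate = bleach_rate,
         gaussian_sigma = gaussian_sigma, poisson_scale = poisson_scale,
         seed = as.integer(seed), field_px = as.integer(field_px),
         n_z = as.integer(n_z), n_frames = as.integer(n_frames)),
    class = "AcquisitionModel")
}

#' Elliptical nucleus description
#'
#' @param center_um `(x, y)` centroid in micrometres.
#' @param semi_axes_um `(a, b)` semi-axes in micrometres.
#' @param z_extent_um axial extent of the nucleus, um.
#' @param mean_intensity fluorescence added inside the nucleus, a.u.
#' @return A list of class `EllipseSpec`.
#' @export
ellipse_spec <- function(center_um, semi_axes_um, z_extent_um = 4,
                         mean_intensity = 1200) {
  stopifnot(length(center_um) == 2L, length(semi_axes_um) == 2L)
  if (any(semi_axes_um <= 0) || z_extent_um <= 0 || mean_intensity < 0) {
    sq_stop("INVALID_PARAM", "ellipse geometry/intensity out of range")
  }
  structure(list(center_um = as.numeric(center_um),
                 semi_axes_um = as.numeric(semi_axes_um),
                 z_extent_um = z_extent_um,
                 mean_intensity = mean_intensity), class = "EllipseSpec")
}

#' Planted puncta table
#'
#' Builds/validates the ground-truth table of planted clusters. Each row is
#' one punctum: physical centroid, frame, area, peak intensity, the channel
#' set it appears in (`"1"`, `"2"` or `"both"`) and whether it is shared
#' between channels.
#'
#' @param x_um,y_um,z_um centroid coordinates, um.
#' @param t frame index (1-based).
#' @param area_um2 rendered connected area, um^2 (> 0).
#' @param peak peak intensity added above background, a.u. (>= 0).
#' @param channel `"1"`, `"2"` or `"both"`.
#' @param co_label logical; `TRUE` when shared between channels.
#' @return A `data.frame` with one row per punctum.
#' @export
planted_puncta <- function(x_um, y_um, z_um, t = 1L, area_um2, peak,
                           channel = "1", co_label = channel == "both") {
  df <- data.frame(x_um = x_um, y_um = y_um, z_um = z_um, t = as.integer(t),
                   area_um2 = area_um2, peak = peak,
                   channel = as.character(channel), co_label = co_label,
                   stringsAsFactors = FALSE)
  if (nrow(df) && (any(df$area_um2 <= 0) || any(df$peak < 0))) {
    sq_stop("INVALID_PARAM", "puncta must have area > 0 and peak >= 0")
  }
  df
}

empty_puncta <- function() {
  planted_puncta(numeric(0), numeric(0), numeric(0), integer(0),
                 numeric(0), numeric(0), character(0), logical(0))
}

#' Scene description for the synthetic SOP field
#'
#' Describes the imaged geometry the generator renders: the two daughter-cell
#' nuclei flanking the new interface, the interface polyline, planted
#' puncta, a uniform cytoplasmic background and the apical (epidermal)
#' reference level used downstream as the apical mean fluorescence.
#'
#' @param nucleus_a,nucleus_b [ellipse_spec()] objects; must not overlap
#'   unless `allow_overlap = TRUE` (used to provoke QC failures).
#' @param interface_line `n x 2` matrix of `(x, y)` vertices in um.
#' @param puncta a [planted_puncta()] table.
#' @param background_level uniform background, a.u.
#' @param epidermal_interface_level apical reference level, a.u. (on the
#'   3-slice projection scale used by the cluster intensity threshold).
#' @param interface_level extra brightness of the interface band in the
#'   signal channel, a.u.
#' @param interface_width_um width of the rendered interface band, um.
#' @param allow_overlap permit overlapping nuclei (QC-failure scenario).
#' @return An object of class `SceneSpec`.
#' @export
scene_spec <- function(nucleus_a, nucleus_b, interface_line,
                       puncta = empty_puncta(), background_level = 100,
                       epidermal_interface_level = 500,
                       interface_level = 0, interface_width_um = 0.2,
                       allow_overlap = FALSE) {
  stopifnot(inherits(nucleus_a, "EllipseSpec"), inherits(nucleus_b, "EllipseSpec"))
  interface_line <- as.matrix(interface_line)
  if (background_level < 0 || epidermal_interface_level < 0) {
    sq_stop("INVALID_PARAM", "intensity levels must be >= 0")
  }
  if (!allow_overlap) {
    # conservative overlap screen on the bounding ellipses
    d <- sqrt(sum((nucleus_a$center_um - nucleus_b$center_um)^2))
    if (d < min(nucleus_a$semi_axes_um) + min(nucleus_b$semi_axes_um)) {
      sq_stop("INVALID_PARAM", "nuclei overlap; set allow_overlap = TRUE")
    }
  }
  structure(
    list(nucleus_a = nucleus_a, nucleus_b = nucleus_b,
         interface_line = interface_line, puncta = puncta,
         background_level = background_level,
         epidermal_interface_level = epidermal_interface_level,
         interface_level = interface_level,
         interface_width_um = interface_width_um,
         allow_overlap = allow_overlap),
    class = "SceneSpec")
}

#' Default SOP scene with randomly planted puncta
#'
#' Convenience builder for the study geometry: two nuclei flanking a
#' vertical interface at mid-field, with `n_puncta` puncta planted on a
#' spaced lattice inside the inter-nuclear corridor so that rendered spots
#' never merge. Areas and peaks are drawn uniformly from the given ranges.
#'
#' @param n_puncta number of planted puncta (0-10 fits the default lattice).
#' @param seed RNG seed for placement and punctum properties.
#' @param area_range area range, um^2.
#' @param peak_range peak intensity range, a.u.
#' @param t frame the puncta appear in.
#' @param channel channel of the planted puncta.
#' @param ... forwarded to [scene_spec()].
#' @return A [scene_spec()].
#' @export
sop_scene <- function(n_puncta = 5L, seed = 1L, area_range = c(0.05, 0.15),
                      peak_range = c(2000, 3000), t = 1L, channel = "1", ...) {
  slots <- expand.grid(x = c(6.1, 6.7), y = seq(5.2, 7.4, by = 0.55))
  if (n_puncta > nrow(slots)) {
    sq_stop("INVALID_PARAM", "at most %d puncta fit the default lattice",
            nrow(slots))
  }
  pnc <- with_seed(seed, {
    if (n_puncta == 0L) empty_puncta() else {
      pick <- slots[sample.int(nrow(slots), n_puncta), , drop = FALSE]
      planted_puncta(
        x_um = pick$x + stats::runif(n_puncta, -0.02, 0.02),
        y_um = pick$y + stats::runif(n_puncta, -0.02, 0.02),
        z_um = 2.25,
        t = t,
        area_um2 = stats::runif(n_puncta, area_range[1], area_range[2]),
        peak = stats::runif(n_puncta, peak_range[1], peak_range[2]),
        channel = channel)
    }
  })
  scene_spec(
    nucleus_a = ellipse_spec(c(4.2, 6.4), c(1.6, 1.3)),
    nucleus_b = ellipse_spec(c(8.6, 6.4), c(1.6, 1.3)),
    interface_line = rbind(c(6.4, 4.0), c(6.4, 8.8)),
    puncta = pnc, ...)
}

# --- rendering -------------------------------------------------------------

# render one noiseless frame -> array [z, c, y, x]
render_frame <- function(scene, acq, t) {
  ny <- acq$field_px[1]; nx <- acq$field_px[2]
  ps <- acq$pixel_size_xy
  xs <- (seq_len(nx) - 0.5) * ps # pixel-center physical coords
  ys <- (seq_len(ny) - 0.5) * ps
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  arr <- array(scene$background_level, c(acq$n_z, 2L, ny, nx))
  mid_z_um <- acq$n_z * acq$z_step / 2
  for (which_nuc in c("nucleus_a", "nucleus_b")) {
    nuc <- scene[[which_nuc]]
    inside <- ((X - nuc$center_um[1]) / nuc$semi_axes_um[1])^2 +
      ((Y - nuc$center_um[2]) / nuc$semi_axes_um[2])^2 <= 1
    for (z in seq_len(acq$n_z)) {
      z_um <- (z - 0.5) * acq$z_step
      if (abs(z_um - mid_z_um) <= nuc$z_extent_um / 2) {
        pl <- matrix(arr[z, 2L, , ], ny, nx)
        pl[inside] <- pl[inside] + nuc$mean_intensity
        arr[z, 2L, , ] <- pl
      }
    }
  }
  if (scene$interface_level > 0) {
    dmin <- matrix(Inf, ny, nx)
    v <- scene$interface_line
    for (i in seq_len(nrow(v) - 1L)) {
      dmin <- pmin(dmin, dist_to_segment(X, Y, v[i, ], v[i + 1L, ]))
    }
    band <- dmin <= scene$interface_width_um / 2
    for (z in seq_len(acq$n_z)) {
      pl <- matrix(arr[z, 1L, , ], ny, nx)
      pl[band] <- pl[band] + scene$interface_level
      arr[z, 1L, , ] <- pl
    }
  }
  pn <- scene$puncta
  pn <- pn[pn$t == t, , drop = FALSE]
  if (nrow(pn)) {
    for (i in seq_len(nrow(pn))) {
      zi <- max(1L, min(acq$n_z, as.integer(round(pn$z_um[i] / acq$z_step + 0.5))))
      chs <- switch(pn$channel[i], "1" = 1L, "2" = 2L, "both" = c(1L, 2L),
                    sq_stop("INVALID_PARAM", "unknown punctum channel"))
      sp <- punctum_pixels(pn$x_um[i], pn$y_um[i], pn$area_um2[i],
                           pn$peak[i], acq)
      if (is.null(sp)) {
        sq_stop("SCENE_OUT_OF_BOUNDS",
                "punctum %d extends outside the field of view", i)
      }
      for (ch in chs) {
        pl <- matrix(arr[zi, ch, , ], ny, nx)
        pl[sp$idx] <- pl[sp$idx] + sp$val
        arr[zi, ch, , ] <- pl
      }
    }
  }
  arr
}

dist_to_segment <- function(X, Y, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  l2 <- vx^2 + vy^2
  tt <- ((X - p1[1]) * vx + (Y - p1[2]) * vy) / l2
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((X - (p1[1] + tt * vx))^2 + (Y - (p1[2] + tt * vy))^2)
}

# Select the round(area/px^2) pixel centers nearest the punctum centroid and
# give them a Gaussian profile (sigma = equivalent radius), so the rendered
# connected area matches the requested area to within half a pixel.
punctum_pixels <- function(x_um, y_um, area_um2, peak, acq) {
  ps <- acq$pixel_size_xy
  n_px <- max(1L, as.integer(round(area_um2 / ps^2)))
  r_um <- sqrt(area_um2 / pi)
  half <- ceiling(r_um / ps) + 3L
  cx <- x_um / ps + 0.5 # 1-based fractional column of the centroid
  cy <- y_um / ps + 0.5
  cols <- (floor(cx) - half):(floor(cx) + half)
  rows <- (floor(cy) - half):(floor(cy) + half)
  if (min(cols) < 1L || max(cols) > acq$field_px[2] ||
      min(rows) < 1L || max(rows) > acq$field_px[1]) {
    return(NULL)
  }
  grid <- expand.grid(row = rows, col = cols)
  d_um <- sqrt(((grid$col - cx) * ps)^2 + ((grid$row - cy) * ps)^2)
  ord <- order(d_um, grid$row, grid$col)
  sel <- ord[seq_len(n_px)]
  list(idx = cbind(grid$row[sel], grid$col[sel]),
       val = peak * exp(-d_um[sel]^2 / (2 * r_um^2)))
}

check_scene_bounds <- function(scene, acq) {
  fx <- acq$field_px[2] * acq$pixel_size_xy
  fy <- acq$field_px[1] * acq$pixel_size_xy
  for (nuc in list(scene$nucleus_a, scene$nucleus_b)) {
    if (nuc$center_um[1] - nuc$semi_axes_um[1] < 0 ||
        nuc$center_um[1] + nuc$semi_axes_um[1] > fx ||
        nuc$center_um[2] - nuc$semi_axes_um[2] < 0 ||
        nuc$center_um[2] + nuc$semi_axes_um[2] > fy) {
      sq_stop("SCENE_OUT_OF_BOUNDS", "nucleus outside the field of view")
    }
  }
  if (nrow(scene$puncta)) {
    r <- sqrt(scene$puncta$area_um2 / pi)
    if (any(scene$puncta$x_um - r < 0) || any(scene$puncta$x_um + r > fx) ||
        any(scene$puncta$y_um - r < 0) || any(scene$puncta$y_um + r > fy)) {
      sq_stop("SCENE_OUT_OF_BOUNDS", "punctum outside the field of view")
    }
  }
  invisible(TRUE)
}

apply_noise <- function(arr, acq) {
  if (is.finite(acq$poisson_scale)) {
    arr[] <- stats::rpois(length(arr), arr * acq$poisson_scale) /
      acq$poisson_scale
  }
  if (acq$gaussian_sigma > 0) {
    arr[] <- arr + stats::rnorm(length(arr), 0, acq$gaussian_sigma)
  }
  arr
}

#' Generate a ground-truthed synthetic time-lapse
#'
#' Renders the scene frame by frame (channel 1 = signal, channel 2 =
#' nuclear), applies exponential photobleaching at the acquisition's
#' `bleach_rate` and then shot/read noise, and returns the calibrated stack
#' together with the planted-punctum ground-truth table (pixel coordinates
#' are 0-based pixel centers). The same scene and seed always reproduce the
#' identical stack.
#'
#' @param scene a [scene_spec()].
#' @param acq an [acquisition_model()].
#' @return A list with elements `stack` ([image_stack()]) and `truth`
#'   (`data.frame`: t, x_px, y_px, z, area_um2, peak, channel, co_label).
#' @export
generate_timelapse <- function(scene, acq) {
  stopifnot(inherits(scene, "SceneSpec"), inherits(acq, "AcquisitionModel"))
  check_scene_bounds(scene, acq)
  ny <- acq$field_px[1]; nx <- acq$field_px[2]
  data <- array(0, c(acq$n_frames, acq$n_z, 2L, ny, nx))
  with_seed(acq$seed, {
    for (t in seq_len(acq$n_frames)) {
      fr <- render_frame(scene, acq, t)
      fr <- fr * exp(-acq$bleach_rate * (t - 1L))
      fr <- apply_noise(fr, acq)
      data[t, , , , ] <- fr
    }
  })
  stack <- image_stack(data, acq$pixel_size_xy, acq$z_step,
                       acq$frame_interval,
                       channel_names = c("signal", "nuclear"))
  pn <- scene$puncta
  truth <- data.frame(
    t = pn$t,
    x_px = pn$x_um / acq$pixel_size_xy - 0.5,
    y_px = pn$y_um / acq$pixel_size_xy - 0.5,
    z = if (nrow(pn)) pmax(1L, pmin(acq$n_z, as.integer(
      round(pn$z_um / acq$z_step + 0.5)))) else integer(0),
    area_um2 = pn$area_um2, peak = pn$peak, channel = pn$channel,
    co_label = pn$co_label, stringsAsFactors = FALSE)
  list(stack = stack, truth = truth)
}

#' Apply exponential photobleaching to a stack
#'
#' Multiplies frame `t` (0-based) by `exp(-rate * t)`, the decay that the
#' reference-region bleaching correction later removes.
#'
#' @param stack an [image_stack()].
#' @param rate bleach rate per frame (>= 0).
#' @return The bleached [image_stack()].
#' @export
apply_bleaching <- function(stack, rate) {
  stopifnot(inherits(stack, "ImageStack"))
  if (rate < 0) sq_stop("INVALID_PARAM", "bleach rate must be >= 0")
  for (t in seq_len(dim(stack$data)[1])) {
    stack$data[t, , , , ] <- stack$data[t, , , , ] * exp(-rate * (t - 1L))
  }
  stack
}

#' Generate a co-moving two-channel kymograph pair
#'
#' Emulates cluster tracks on an interface kymograph: `n_tracks` Gaussian
#' tracks per channel on a spaced position lattice (so tracks never overlap),
#' a fraction `co_fraction` of which occupy identical positions in both
#' channels while the rest are placed independently. Tracks drift linearly;
#' intensities are quantised to integer a.u. after noise, as a photon
#' counting detector would.
#'
#' @param n_tracks tracks per channel.
#' @param co_fraction fraction of shared tracks, in `[0, 1]`.
#' @param drift drift in px/frame.
#' @param acq an [acquisition_model()]; its seed, noise model and
#'   `frame_interval` (2 s for the high-time-resolution mode) are used.
#' @param n_frames,n_positions kymograph dimensions.
#' @param track_sigma_px Gaussian track half-width, px.
#' @param track_intensity peak track intensity, a.u.
#' @param background background level, a.u.
#' @return A list with `kymo1`, `kymo2` ([kymograph()] objects) and `truth`
#'   (`data.frame`: track, co_label, p0_ch1, p0_ch2).
#' @export
generate_coloc_kymographs <- function(n_tracks, co_fraction, drift = 0,
                                      acq = acquisition_model(frame_interval = 2),
                                      n_frames = 64L, n_positions = 512L,
                                      track_sigma_px = 1.5,
                                      track_intensity = 500,
                                      background = 0) {
  if (co_fraction < 0 || co_fraction > 1) {
    sq_stop("INVALID_PARAM", "co_fraction must be in [0, 1]")
  }
  # lattice spacing exceeds the truncated track support (2 * 3 sigma), so
  # tracks never overlap; leave room for the full drift excursion
  lo <- 8 - min(0, drift * (n_frames - 1L))
  hi <- n_positions - 8 - max(0, drift * (n_frames - 1L))
  slots <- seq(ceiling(lo), floor(hi), by = ceiling(6 * track_sigma_px) + 3L)
  n_co <- round(co_fraction * n_tracks)
  need <- n_tracks + (n_tracks - n_co)
  if (need > length(slots)) {
    sq_stop("INVALID_PARAM", "too many tracks for the position lattice")
  }
  xs <- seq_len(n_positions)
  render <- function(pos0) {
    k <- matrix(background, n_frames, n_positions)
    for (p0 in pos0) {
      for (t in seq_len(n_frames)) {
        c0 <- p0 + drift * (t - 1L)
        w <- abs(xs - c0) <= 3 * track_sigma_px
        k[t, w] <- k[t, w] +
          track_intensity * exp(-(xs[w] - c0)^2 / (2 * track_sigma_px^2))
      }
    }
    k
  }
  res <- with_seed(acq$seed, {
    pos <- sample(slots, need)
    p1 <- pos[seq_len(n_tracks)]
    co_idx <- seq_len(n_co)
    p2 <- p1
    if (n_tracks > n_co) {
      p2[(n_co + 1L):n_tracks] <- pos[(n_tracks + 1L):need]
    }
    k1 <- apply_noise(render(p1), acq)
    k2 <- apply_noise(render(p2), acq)
    list(k1 = round(k1), k2 = round(k2), p1 = p1, p2 = p2,
         co = seq_len(n_tracks) %in% co_idx)
  })
  truth <- data.frame(track = seq_len(n_tracks), co_label = res$co,
                      p0_ch1 = res$p1, p0_ch2 = res$p2)
  list(kymo1 = kymograph(res$k1, acq$frame_interval, acq$pixel_size_xy),
       kymo2 = kymograph(res$k2, acq$frame_interval, acq$pixel_size_xy),
       truth = truth)
}

#' Generate a synthetic FRAP trace
#'
#' Produces a bleach-recovery time series following the single-exponential
#' model: constant `prebleach` signal, a bleach to
#' `I_post = prebleach * (1 - bleach_depth)`, then
#' `I(t) = I_post + mobile_fraction * (prebleach - I_post) *
#' (1 - exp(-(t - t_bleach) / tau))`, plus optional Gaussian noise. The
#' generating parameters are attached as ground truth.
#'
#' @param prebleach pre-bleach intensity, a.u.
#' @param bleach_depth fractional bleach, in `[0, 1]`.
#' @param tau recovery time constant, s (> 0).
#' @param mobile_fraction recoverable share, in `[0, 1]`.
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param acq an [acquisition_model()]; `frame_interval` and `seed` are used.
#' @param n_prebleach,n_postbleach frame counts before/after the bleach.
#' @return A [frap_trace()] with a `truth` element.
#' @export
generate_frap_trace <- function(prebleach = 1000, bleach_depth = 0.8,
                                tau = 20, mobile_fraction = 0.5,
                                noise_sd = 0,
                                acq = acquisition_model(frame_interval = 2),
                                n_prebleach = 5L, n_postbleach = 60L) {
  if (bleach_depth < 0 || bleach_depth > 1) {
    sq_stop("INVALID_PARAM", "bleach_depth must be in [0, 1]")
  }
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    sq_stop("INVALID_PARAM", "mobile_fraction must be in [0, 1]")
  }
  if (tau <= 0) sq_stop("INVALID_PARAM", "tau must be > 0")
  if (noise_sd < 0) sq_stop("INVALID_PARAM", "noise_sd must be >= 0")
  n <- n_prebleach + n_postbleach
  time <- (seq_len(n) - 1L) * acq$frame_interval
  bleach_index <- n_prebleach + 1L
  i_post <- prebleach * (1 - bleach_depth)
  intensity <- numeric(n)
  intensity[seq_len(n_prebleach)] <- prebleach
  post <- bleach_index:n
  dt <- time[post] - time[bleach_index]
  intensity[post] <- i_post +
    mobile_fraction * (prebleach - i_post) * (1 - exp(-dt / tau))
  if (noise_sd > 0) {
    intensity <- with_seed(acq$seed,
                           intensity + stats::rnorm(n, 0, noise_sd))
  }
  tr <- frap_trace(time, intensity, bleach_index = bleach_index,
                   prebleach_frames = n_prebleach)
  tr$truth <- list(prebleach = prebleach, I_post = i_post, tau = tau,
                   mobile_fraction = mobile_fraction)
  tr
}

#' Write a planted-punctum ground-truth table to CSV
#'
#' @param truth the `truth` element of [generate_timelapse()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
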