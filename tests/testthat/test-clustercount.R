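disk_mask <- function(ny, nx, cx, cy, r) {
  X <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
  Y <- matrix(seq_len(ny) - 1, ny, nx)
  (X - cx)^2 + (Y - cy)^2 <= r^2
}

test_that("nuclei segmentation recovers the planted nuclei", {
  acq <- acquisition_model(gaussian_sigma = 10, poisson_scale = 1, seed = 21)
  sc <- sop_scene(n_puncta = 0, seed = 1)
  tl <- generate_timelapse(sc, acq)
  nuc <- sum_project(tl$stack, 2, 1, 5)
  pair <- segment_nuclei(nuc, pixel_size_xy = 0.05)
  # ground-truth centroids in 0-based px
  expect_lt(max(abs(pair$centroid_a - c(4.2 / 0.05 - 0.5, 6.4 / 0.05 - 0.5))), 1)
  expect_lt(max(abs(pair$centroid_b - c(8.6 / 0.05 - 0.5, 6.4 / 0.05 - 0.5))), 1)
  # mirror-symmetric scene: equal areas within 2%
  aa <- sum(pair$roi_a$mask); ab <- sum(pair$roi_b$mask)
  expect_lt(abs(aa - ab) / aa, 0.02)

  img <- matrix(0, 64, 64); img[20:40, 20:40] <- 100
  expect_error(segment_nuclei(img), class = "SEGMENTATION_FAILED")
  expect_error(segment_nuclei(matrix(5, 32, 32)),
               class = "SEGMENTATION_FAILED")
})

test_that("QC flags touching and z-stacked nuclei", {
  # touching ROIs (gap 1 px)
  a <- roi_mask(disk_mask(60, 120, 30, 30, 12), pixel_size_xy = 0.05)
  b <- roi_mask(disk_mask(60, 120, 56, 30, 12), pixel_size_xy = 0.05)
  pair <- nuclei_pair(a, b, c(30, 30), c(56, 30))
  expect_equal(qc_check(pair), "TOO_CLOSE")

  # concentric ring/disk with 3 um axial offset
  ring <- disk_mask(60, 60, 30, 30, 20) & !disk_mask(60, 60, 30, 30, 12)
  inner <- disk_mask(60, 60, 30, 30, 8)
  pair_z <- nuclei_pair(roi_mask(inner, pixel_size_xy = 0.05),
                        roi_mask(ring, pixel_size_xy = 0.05),
                        c(30, 30), c(30, 30), z_offset_um = 3)
  expect_equal(qc_check(pair_z), "Z_STACKED")

  # well-separated coplanar nuclei
  c1 <- roi_mask(disk_mask(60, 120, 25, 30, 10), pixel_size_xy = 0.05)
  c2 <- roi_mask(disk_mask(60, 120, 80, 30, 10), pixel_size_xy = 0.05)
  ok <- nuclei_pair(c1, c2, c(25, 30), c(80, 30))
  expect_equal(qc_check(ok), "OK")
})

test_that("ovoid mask contains both nuclei and matches the geometric case", {
  m1 <- disk_mask(100, 140, 30, 40, 10)
  m2 <- disk_mask(100, 140, 70, 40, 10)
  pair <- nuclei_pair(roi_mask(m1, pixel_size_xy = 0.05),
                      roi_mask(m2, pixel_size_xy = 0.05),
                      c(30, 40), c(70, 40))
  ov <- ovoid_mask(pair, margin_px = 2)
  expect_true(all(ov$mask[m1 | m2])) # full containment
  # two 10-px circles 40 px apart, margin 2: semi-major within 1 px of 32
  ij <- which(ov$mask, arr.ind = TRUE)
  semi_major <- max(abs((ij[, 2] - 1) - 50))
  expect_lt(abs(semi_major - 32), 1 + 1e-9)
  # symmetry about the perpendicular bisector
  left <- sum(ov$mask[, 1:50]); right <- sum(ov$mask[, 52:140])
  expect_lt(abs(left - right) / left, 0.02)
})

test_that("inter-nuclear ROI excludes the nuclei and obeys set identities", {
  m1 <- disk_mask(80, 120, 30, 40, 12)
  m2 <- disk_mask(80, 120, 80, 40, 12)
  pair <- nuclei_pair(roi_mask(m1, pixel_size_xy = 0.05),
                      roi_mask(m2, pixel_size_xy = 0.05),
                      c(30, 40), c(80, 40))
  ov <- ovoid_mask(pair, 3)
  res <- internuclear_roi(ov, pair)
  expect_false(any(res$mask & (m1 | m2)))
  expect_equal(sum(res$mask), sum(ov$mask) - sum(ov$mask & (m1 | m2)))

  # nuclei covering the whole frame leave nothing to search
  left <- matrix(FALSE, 20, 20); left[, 1:10] <- TRUE
  pair2 <- nuclei_pair(roi_mask(left, pixel_size_xy = 0.05),
                       roi_mask(!left, pixel_size_xy = 0.05),
                       c(4.5, 9.5), c(14.5, 9.5))
  expect_error(internuclear_roi(ovoid_mask(pair2, 3), pair2),
               class = "EMPTY_SEARCH_REGION")
})

test_that("particle analysis uses 8-connectivity and original intensities", {
  img <- matrix(0, 20, 20)
  roi <- roi_mask(matrix(TRUE, 20, 20), pixel_size_xy = 0.1)
  expect_equal(nrow(analyse_particles(img, roi, 50)), 0)

  img[5, 5:9] <- 500 # 5-px blob
  p <- analyse_particles(img, roi, 50)
  expect_equal(nrow(p), 1)
  expect_equal(p$pixel_count, 5L)
  expect_equal(p$area_um2, 0.05)
  expect_equal(p$mean_intensity, 500)

  # diagonal-only contact merges under 8-connectivity
  img2 <- matrix(0, 10, 10)
  img2[3, 3] <- 100; img2[4, 4] <- 100
  p2 <- analyse_particles(img2, roi_mask(matrix(TRUE, 10, 10),
                                         pixel_size_xy = 0.1), 10)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$pixel_count, 2L)
})

test_that("intensity threshold is the printed linear formula", {
  expect_equal(intensity_threshold(0), 227.6)
  expect_equal(intensity_threshold(1000), 493.0)
  expect_equal(intensity_threshold(2000), 758.4)
  expect_error(intensity_threshold(-5), class = "INVALID_PARAM")
})

test_that("cluster filter applies inclusive area bounds and the intensity cut", {
  parts <- data.frame(
    pixel_count = c(12L, 100L, 40L, 40L),
    area_um2 = c(0.03, 0.25, 0.1, 0.1),
    mean_intensity = c(10000, 10000, 200, 500),
    x_px = 1:4, y_px = 1:4)
  kept <- filter_clusters(parts, apical_mean = 0)
  expect_equal(kept$area_um2, c(0.03, 0.1))
  expect_equal(kept$mean_intensity, c(10000, 500))
  # idempotent
  expect_equal(filter_clusters(kept, apical_mean = 0), kept)
})

test_that("tightening the filters never increases the retained count", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    parts <- data.frame(pixel_count = sample(4:120, n, TRUE))
    parts$area_um2 <- parts$pixel_count * 0.0025
    parts$mean_intensity <- runif(n, 100, 2000)
    parts$x_px <- seq_len(n); parts$y_px <- seq_len(n)
    am <- runif(1, 0, 2000)
    n0 <- nrow(filter_clusters(parts, filter_params(), am))
    n_min <- nrow(filter_clusters(parts, filter_params(min_area = 0.06), am))
    n_slope <- nrow(filter_clusters(parts, filter_params(slope = 0.5), am))
    expect_lte(n_min, n0)
    expect_lte(n_slope, n0)
  }
})

test_that("full macro recovers planted counts and flags bad frames", {
  acq <- acquisition_model(gaussian_sigma = 15, poisson_scale = 1, seed = 77)
  sc <- sop_scene(n_puncta = 5, seed = 13)
  tl <- generate_timelapse(sc, acq)
  res <- count_timecourse(tl$stack,
                          apical_mean = sc$epidermal_interface_level)
  expect_equal(res$frames$qc_status, "OK")
  expect_equal(res$frames$n_clusters, 5L)

  # all puncta below the minimal area are rejected
  sc_small <- sop_scene(n_puncta = 5, seed = 13, area_range = c(0.01, 0.01))
  tl_small <- generate_timelapse(sc_small, acq)
  res_small <- count_timecourse(tl_small$stack,
                                apical_mean = sc_small$epidermal_interface_level)
  expect_equal(res_small$frames$n_clusters, 0L)

  # nuclei too close: frame excluded with zero clusters
  sc_close <- scene_spec(ellipse_spec(c(4.2, 6.4), c(1.6, 1.3)),
                         ellipse_spec(c(7.45, 6.4), c(1.6, 1.3)),
                         interface_line = rbind(c(5.9, 4), c(5.9, 9)),
                         allow_overlap = TRUE)
  tl_close <- generate_timelapse(sc_close, acq)
  res_close <- count_timecourse(tl_close$stack, apical_mean = 500)
  expect_true(res_close$frames$qc_status %in% c("TOO_CLOSE", "FAILED"))
  expect_equal(res_close$frames$n_clusters, 0L)
})

test_that("recovered cluster intensities track the noiseless render", {
  for (seed in 1:3) {
    sc <- sop_scene(n_puncta = 4, seed = 100 + seed)
    noisy <- generate_timelapse(sc, acquisition_model(
      gaussian_sigma = 15, poisson_scale = 1, seed = seed))
    clean <- generate_timelapse(sc, acquisition_model(seed = seed))
    rn <- count_timecourse(noisy$stack, apical_mean = 500)
    rc <- count_timecourse(clean$stack, apical_mean = 500)
    expect_equal(nrow(rn$clusters), 4)
    expect_equal(nrow(rc$clusters), 4)
    # match clusters by centroid and compare mean intensities
    for (i in seq_len(4)) {
      j <- which.min((rc$clusters$x_px - rn$clusters$x_px[i])^2 +
                       (rc$clusters$y_px - rn$clusters$y_px[i])^2)
      expect_lt(abs(rn$clusters$mean_intensity[i] -
                      rc$clusters$mean_intensity[j]) /
                  rc$clusters$mean_intensity[j], 0.1)
    }
  }
})
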