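test_that("identical scene and seed reproduce the stack bit for bit", {
  acq <- acquisition_model(gaussian_sigma = 10, poisson_scale = 1, seed = 42)
  sc <- sop_scene(n_puncta = 3, seed = 5)
  a <- generate_timelapse(sc, acq)
  b <- generate_timelapse(sc, acq)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth, b$truth)
  # a different seed changes the noise realisation
  acq2 <- acquisition_model(gaussian_sigma = 10, poisson_scale = 1, seed = 43)
  expect_false(identical(generate_timelapse(sc, acq2)$stack$data,
                         a$stack$data))
})

test_that("noiseless empty scene never exceeds background between nuclei", {
  acq <- acquisition_model(seed = 1) # no noise by default
  sc <- sop_scene(n_puncta = 0)
  tl <- generate_timelapse(sc, acq)
  sig <- tl$stack$data[1, 5, 1, , ] # signal channel, mid z
  # inter-nuclear corridor (between the nuclei, away from both)
  corridor <- sig[80:176, 118:138]
  expect_true(all(corridor <= sc$background_level))
  expect_equal(nrow(tl$truth), 0)
})

test_that("rendered punctum areas match the requested areas within 15%", {
  areas <- seq(0.01, 0.3, by = 0.01)
  acq <- acquisition_model(seed = 1)
  pn <- planted_puncta(x_um = rep(seq(1.2, 11.6, length.out = 10), 3),
                       y_um = rep(seq(1.5, 11.3, length.out = 3), each = 10),
                       z_um = 2.25, t = 1L, area_um2 = areas, peak = 1000)
  sc <- scene_spec(ellipse_spec(c(4.2, 6.4), c(0.2, 0.2), mean_intensity = 0),
                   ellipse_spec(c(8.6, 6.4), c(0.2, 0.2), mean_intensity = 0),
                   interface_line = rbind(c(6.4, 4), c(6.4, 9)),
                   puncta = pn, background_level = 0)
  tl <- generate_timelapse(sc, acq)
  z <- tl$truth$z[1]
  sig <- tl$stack$data[1, z, 1, , ]
  lbl <- sopquant:::label8(sig > 0)
  cnt <- tabulate(lbl[lbl > 0])
  expect_equal(length(cnt), length(areas))
  rendered <- sort(cnt) * acq$pixel_size_xy^2
  expect_true(all(abs(rendered - sort(areas)) <= 0.15 * sort(areas)))
  expect_equal(nrow(tl$truth), length(areas))
})

test_that("scene geometry outside the field is rejected", {
  sc <- scene_spec(ellipse_spec(c(0.5, 6.4), c(1.6, 1.3)),
                   ellipse_spec(c(8.6, 6.4), c(1.6, 1.3)),
                   interface_line = rbind(c(6.4, 4), c(6.4, 9)))
  expect_error(generate_timelapse(sc, acquisition_model()),
               class = "SCENE_OUT_OF_BOUNDS")
})

test_that("apply_bleaching follows the closed-form exponential decay", {
  s <- image_stack(array(100, c(3, 1, 1, 4, 4)), 0.05)
  expect_identical(apply_bleaching(s, 0)$data, s$data)
  b <- apply_bleaching(s, log(2))
  expect_equal(b$data[2, 1, 1, , ], matrix(50, 4, 4))
  expect_equal(b$data[3, 1, 1, , ], matrix(25, 4, 4))
  expect_error(apply_bleaching(s, -0.1), class = "INVALID_PARAM")
})

test_that("bleached constant stack is recovered flat by the correction", {
  s <- image_stack(array(500, c(6, 1, 1, 40, 40)), 0.05)
  b <- apply_bleaching(s, 0.2)
  frames <- lapply(1:6, function(t) matrix(b$data[t, 1, 1, , ], 40, 40))
  arr <- array(0, c(6, 40, 40)); for (t in 1:6) arr[t, , ] <- frames[[t]]
  rois <- propose_background_rois(matrix(FALSE, 40, 40), size = 5,
                                  pixel_size_xy = 0.05)
  bg <- measure_background(arr, rois)
  raw <- vapply(frames, function(fr) mean(fr[20:25, 20:25]), numeric(1))
  s2 <- correct_and_normalize(raw, bg)
  expect_lt(max(abs(s2$corrected - 500)) / 500, 1e-6)
  expect_lt(max(abs(s2$normalized - 1)), 1e-6)
})

test_that("coloc kymograph truth matches the requested co-fraction", {
  g1 <- generate_coloc_kymographs(10, 1, acq = acquisition_model(seed = 3))
  expect_true(all(g1$truth$co_label))
  expect_identical(g1$truth$p0_ch1, g1$truth$p0_ch2)
  # proportional channels when noiseless and identical
  expect_equal(g1$kymo1$values, g1$kymo2$values)

  g0 <- generate_coloc_kymographs(10, 0, acq = acquisition_model(seed = 4))
  expect_false(any(g0$truth$co_label))
  expect_true(all(g0$truth$p0_ch1 != g0$truth$p0_ch2))
  # disjoint supports
  expect_equal(sum(g0$kymo1$values * g0$kymo2$values), 0)

  expect_error(generate_coloc_kymographs(10, 1.5),
               class = "INVALID_PARAM")
})

test_that("frap trace follows the single-exponential closed form", {
  acq <- acquisition_model(frame_interval = 10 * log(2))
  tr <- generate_frap_trace(prebleach = 1000, bleach_depth = 0.8, tau = 10,
                            mobile_fraction = 0.6, acq = acq)
  i_post <- 200
  plateau <- i_post + 0.6 * (1000 - i_post)
  # one frame after the bleach sits at t = 10*ln2: halfway up the recovery
  expect_equal(tr$intensity[tr$bleach_index + 1L],
               i_post + (plateau - i_post) / 2)
  expect_equal(tr$intensity[tr$bleach_index], i_post)

  flat <- generate_frap_trace(mobile_fraction = 0)
  post <- flat$bleach_index:length(flat$time)
  expect_true(all(flat$intensity[post] == flat$intensity[post[1]]))

  expect_error(generate_frap_trace(tau = -1), class = "INVALID_PARAM")
  expect_error(generate_frap_trace(mobile_fraction = 2),
               class = "INVALID_PARAM")
})
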