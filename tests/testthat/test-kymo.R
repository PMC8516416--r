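test_that("kymograph rows reflect per-frame intensity and shape contract", {
  # every pixel of frame t equals t -> row t is constant t
  frames <- lapply(1:4, function(t) matrix(t, 30, 70))
  ln <- line_roi(rbind(c(10, 15), c(59, 15)), width = 5)
  ky <- build_kymograph(frames, ln)
  expect_equal(dim(ky$values), c(4, 50))
  for (t in 1:4) expect_equal(unname(ky$values[t, ]), rep(t, 50))

  # 10-frame series over a 50-pixel line -> 10 x 50 matrix
  frames10 <- lapply(1:10, function(t) matrix(runif(30 * 70), 30, 70))
  expect_equal(dim(build_kymograph(frames10, ln)$values), c(10, 50))
})

test_that("width averaging takes the mean across the line's width", {
  img <- matrix(0, 30, 70)
  img[11, ] <- 0 # y = 10
  img[12, ] <- 2 # y = 11
  ln <- line_roi(rbind(c(10, 10.5), c(59, 10.5)), width = 2)
  ky <- build_kymograph(list(img), ln)
  expect_equal(unname(ky$values[1, ]), rep(1, 50))

  # width 1 reduces to the single-pixel profile
  img2 <- matrix(seq_len(30 * 70), 30, 70)
  ln1 <- line_roi(rbind(c(10, 12), c(59, 12)), width = 1)
  ky1 <- build_kymograph(list(img2), ln1)
  expect_equal(unname(ky1$values[1, ]), img2[13, 11:60])

  ln_out <- line_roi(rbind(c(10, 1), c(59, 1)), width = 30)
  expect_error(build_kymograph(list(img), ln_out),
               class = "ROI_OUT_OF_BOUNDS")
})

test_that("interface profile averages a band around the interface", {
  ky <- kymograph(matrix(1, 5, 40))
  expect_equal(as.numeric(interface_profile(ky, 20)), rep(1, 5))

  ky2 <- kymograph(matrix(rep(0:19, each = 3), 3, 20))
  expect_equal(as.numeric(interface_profile(ky2, 20)), rep(9.5, 3))

  expect_error(interface_profile(ky2, 30), class = "BAND_TOO_WIDE")

  # a bright moving interface is tracked by the default argmax center
  vals <- matrix(10, 6, 60)
  for (t in 1:6) vals[t, 25 + t] <- 500
  raw <- interface_profile(kymograph(vals), band_width = 5)
  expect_true(all(raw == (500 + 4 * 10) / 5))
})

test_that("bleach correction factor is t0 mean over frame mean", {
  bg <- background_set(matrix(c(300, 150, 100), 3, 3))
  expect_equal(bleach_correction_factor(bg), c(1, 2, 3))
  expect_equal(bleach_correction_factor(bg, 2), 2)
  bg0 <- background_set(matrix(c(300, 0), 2, 3))
  expect_error(bleach_correction_factor(bg0),
               class = "DEGENERATE_BACKGROUND")
  expect_error(background_set(matrix(1, 3, 2)), class = "FORMAT_ERROR")
})

test_that("correct_and_normalize applies the two printed formulas", {
  # signal equal to the background stays at 1
  bg <- background_set(matrix(c(500, 400, 320), 3, 3))
  s <- correct_and_normalize(c(500, 400, 320), bg)
  expect_equal(s$normalized, rep(1, 3))
  expect_equal(s$normalized[1], s$raw[1] / 500)

  # hand-computed two-frame case
  bg2 <- background_set(matrix(c(200, 100), 2, 3))
  s2 <- correct_and_normalize(c(400, 200), bg2)
  expect_equal(s2$corrected, c(400, 400))
  expect_equal(s2$normalized, c(2, 2))

  # shared exponential decay cancels exactly
  k <- 0.3
  decay <- 500 * exp(-k * (0:9))
  bg3 <- background_set(matrix(decay, 10, 3))
  s3 <- correct_and_normalize(decay, bg3)
  expect_lt(max(abs(s3$normalized - 1)), 1e-9)

  expect_error(correct_and_normalize(c(1, 2), bg3), class = "FORMAT_ERROR")
})

test_that("normalised series is invariant to shared per-frame rescaling", {
  set.seed(11)
  raw <- runif(8, 300, 600)
  regions <- matrix(runif(24, 200, 400), 8, 3)
  base <- correct_and_normalize(raw, background_set(regions))
  for (rep in 1:5) {
    g <- runif(8, 0.2, 3)
    scaled <- correct_and_normalize(raw * g, background_set(regions * g))
    expect_lt(max(abs(scaled$normalized - base$normalized) /
                    abs(base$normalized)), 1e-9)
  }
})
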