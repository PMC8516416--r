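test_that("pearson correlation matches the product-moment formula", {
  set.seed(2)
  x <- runif(50, 0, 100)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x + 100), -1)

  # hand evaluation of the covariance sums
  a <- c(1, 2, 3, 4); b <- c(2, 4, 5, 9)
  sxy <- sum((a - mean(a)) * (b - mean(b)))
  r_hand <- sxy / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), r_hand)
  expect_equal(r_hand, 11 / sqrt(130))

  expect_error(pearson_r(rep(1, 10), runif(10)),
               class = "UNDEFINED_CORRELATION")
  expect_error(pearson_r(1:4, 1:5), class = "SHAPE_ERROR")
})

test_that("costes regression recovers exact linear relations", {
  set.seed(3)
  x <- runif(200, 0, 100)
  th <- costes_autothreshold(x, 2 * x)
  expect_equal(th$slope, 2)
  expect_equal(th$intercept, 0, tolerance = 1e-8)
  expect_error(costes_autothreshold(rep(1, 20), runif(20)),
               class = "UNDEFINED_CORRELATION")
})

test_that("costes stopping rule leaves uncorrelated below-threshold pixels", {
  set.seed(4)
  x <- runif(500, 0, 50)
  y <- runif(500, 0, 50)
  th <- costes_autothreshold(x, y)
  sel <- x < th$T1 & y < th$T2
  if (sum(sel) >= 10 && stats::sd(x[sel]) > 0 && stats::sd(y[sel]) > 0) {
    expect_lte(stats::cor(x[sel], y[sel]), 0)
  }
})

test_that("costes threshold equals the exhaustive-scan oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    # uncorrelated dim background plus a correlated bright subset
    x <- runif(n, 0, 30)
    y <- runif(n, 0, 30)
    bright <- sample(n, 40)
    x[bright] <- runif(40, 40, 100)
    y[bright] <- x[bright] * 1.5 + rnorm(40, 0, 3)
    got <- costes_autothreshold(x, y)
    want <- oracle_costes(x, y)
    expect_equal(got$T1, want$T1, label = sprintf("seed %d", seed))
    expect_equal(got$T2, want$T2, tolerance = 1e-6)
  }
})

test_that("manders coefficients are the thresholded signal fractions", {
  x <- c(5, 8, 2, 9)
  expect_equal(unname(manders_above_threshold(x, x, 1, 1)), c(1, 1))

  d1 <- c(10, 20, 0, 0); d2 <- c(0, 0, 5, 9)
  expect_equal(unname(manders_above_threshold(d1, d2, 1, 1)), c(0, 0))

  ch1 <- c(10, 0, 5, 0); ch2 <- c(8, 0, 0, 7)
  tm <- manders_above_threshold(ch1, ch2, 1, 1)
  expect_equal(unname(tm), c(10 / 15, 8 / 15))

  expect_error(manders_above_threshold(c(0, 0), c(1, 2), 0, 0),
               class = "UNDEFINED_COEFFICIENT")
})

test_that("manders coefficients are stable under channel rescaling", {
  # orthogonal regression is not exactly equivariant under axis scaling, so
  # the thresholds shift slightly; the coefficients must stay put
  g <- generate_coloc_kymographs(15, 0.6, acq = acquisition_model(
    frame_interval = 2, poisson_scale = 1, seed = 8))
  base <- kymo_coloc(g$kymo1, g$kymo2)
  for (cc in c(0.5, 3)) {
    sc1 <- kymo_coloc(g$kymo1$values * cc, g$kymo2)
    expect_equal(sc1$tM1, base$tM1, tolerance = 0.02)
    expect_equal(sc1$tM2, base$tM2, tolerance = 0.02)
  }
})

test_that("channel swap exchanges the two coefficients", {
  g <- generate_coloc_kymographs(15, 0.4, acq = acquisition_model(
    frame_interval = 2, poisson_scale = 1, seed = 12))
  ab <- kymo_coloc(g$kymo1, g$kymo2)
  ba <- kymo_coloc(g$kymo2, g$kymo1)
  expect_equal(ba$tM1, ab$tM2, tolerance = 0.02)
  expect_equal(ba$tM2, ab$tM1, tolerance = 0.02)
  expect_true(all(c(ab$tM1, ab$tM2, ba$tM1, ba$tM2) >= 0))
  expect_true(all(c(ab$tM1, ab$tM2, ba$tM1, ba$tM2) <= 1))
})

test_that("kymograph colocalisation separates shared from disjoint tracks", {
  acq <- acquisition_model(frame_interval = 2, seed = 6)
  g1 <- generate_coloc_kymographs(20, 1, drift = 0.2, acq = acq)
  r1 <- kymo_coloc(g1$kymo1, g1$kymo2)
  expect_gt(r1$tM1, 0.98)
  expect_gt(r1$tM2, 0.98)

  g0 <- generate_coloc_kymographs(20, 0, acq = acquisition_model(
    frame_interval = 2, seed = 7))
  r0 <- kymo_coloc(g0$kymo1, g0$kymo2)
  expect_lte(r0$tM1, 0.05)
  expect_lte(r0$tM2, 0.05)

  expect_error(kymo_coloc(matrix(1:12, 3, 4), matrix(1:12, 4, 3)),
               class = "SHAPE_ERROR")
})

test_that("block randomisation declares shared tracks significant", {
  g <- generate_coloc_kymographs(20, 1, acq = acquisition_model(
    frame_interval = 2, poisson_scale = 1, seed = 9))
  r <- kymo_coloc(g$kymo1, g$kymo2, significance = TRUE, seed = 11)
  expect_lte(r$significance_p, 0.05)
  # deterministic given the seed
  r2 <- kymo_coloc(g$kymo1, g$kymo2, significance = TRUE, seed = 11)
  expect_identical(r$significance_p, r2$significance_p)
})
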