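#' Colocalisation settings
#'
#' @param psf_px point-spread-function size in px (default 4.0); used as the
#'   block size of the Costes block-randomisation significance test.
#' @param n_randomizations number of block shuffles for the significance
#'   test.
#' @return An object of class `ColocSettings`.
#' @export
coloc_settings <- function(psf_px = 4.0, n_randomizations = 100L) {
  if (psf_px <= 0) sq_stop("INVALID_PARAM", "psf_px must be > 0")
  structure(list(psf_px = psf_px, threshold_mode = "costes",
                 n_randomizations = as.integer(n_randomizations)),
            class = "ColocSettings")
}

#' Pearson correlation between two channels
#'
#' @param ch1,ch2 numeric arrays of identical shape, each non-constant.
#' @return Product-moment correlation over all pixels.
#' @export
pearson_r <- function(ch1, ch2) {
  x <- as.numeric(ch1); y <- as.numeric(ch2)
  if (length(x) != length(y)) {
    sq_stop("SHAPE_ERROR", "channels have different sizes")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    sq_stop("UNDEFINED_CORRELATION", "a channel is constant")
  }
  stats::cor(x, y)
}

#' Costes automatic threshold pair
#'
#' Fits the orthogonal (total-least-squares) regression
#' `ch2 = a * ch1 + b`, then scans `T1` downwards through the sorted
#' distinct values of channel 1 with `T2 = a * T1 + b`, stopping at the
#' largest `T1` for which the Pearson correlation of the pixels below both
#' thresholds (`ch1 < T1` and `ch2 < T2`) is `<= 0`, or for which the
#' below-threshold pixel set becomes smaller than `min_pixels`.
#'
#' @param ch1,ch2 numeric arrays of identical shape.
#' @param min_pixels smallest below-threshold set still scanned.
#' @return List with `T1`, `T2`, `slope`, `intercept`.
#' @export
costes_autothreshold <- function(ch1, ch2, min_pixels = 10L) {
  x <- as.numeric(ch1); y <- as.numeric(ch2)
  if (length(x) != length(y)) {
    sq_stop("SHAPE_ERROR", "channels have different sizes")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    sq_stop("UNDEFINED_CORRELATION", "a channel has zero variance")
  }
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  a <- if (sxy != 0) {
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  } else {
    sqrt(syy / sxx)
  }
  b <- mean(y) - a * mean(x)
  cand <- sort(unique(x), decreasing = TRUE)
  T1 <- cand[1L]; T2 <- a * T1 + b
  had_valid <- FALSE
  for (T1c in cand) {
    T2c <- a * T1c + b
    sel <- x < T1c & y < T2c
    if (sum(sel) < min_pixels) {
      if (had_valid) break # the below-threshold set became too small: stop
      T1 <- T1c; T2 <- T2c # not yet populated (e.g. negative slope): go on
      next
    }
    had_valid <- TRUE
    T1 <- T1c; T2 <- T2c
    xs <- x[sel]; ys <- y[sel]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) break
    if (stats::cor(xs, ys) <= 0) break
  }
  list(T1 = T1, T2 = T2, slope = a, intercept = b)
}

#' Thresholded Manders coefficients
#'
#' `tM1` is the fraction of channel 1's total signal located at pixels where
#' channel 2 exceeds its threshold, and `tM2` the reciprocal:
#' `tM1 = sum(ch1[ch2 > T2]) / sum(ch1)`,
#' `tM2 = sum(ch2[ch1 > T1]) / sum(ch2)`.
#'
#' @param ch1,ch2 numeric arrays of identical shape (non-negative signal).
#' @param T1,T2 channel thresholds, e.g. from [costes_autothreshold()].
#' @return Named numeric vector `c(tM1, tM2)`.
#' @export
manders_above_threshold <- function(ch1, ch2, T1, T2) {
  x <- as.numeric(ch1); y <- as.numeric(ch2)
  if (length(x) != length(y)) {
    sq_stop("SHAPE_ERROR", "channels have different sizes")
  }
  if (sum(x) <= 0 || sum(y) <= 0) {
    sq_stop("UNDEFINED_COEFFICIENT", "a channel has zero total signal")
  }
  c(tM1 = sum(x[y > T2]) / sum(x), tM2 = sum(y[x > T1]) / sum(y))
}

# permute complete psf x psf blocks of a matrix (edge remainders untouched)
block_shuffle <- function(m, psf) {
  psf <- max(1L, as.integer(round(psf)))
  nbr <- nrow(m) %/% psf; nbc <- ncol(m) %/% psf
  nb <- nbr * nbc
  if (nb < 2L) return(m)
  perm <- sample.int(nb)
  out <- m
  for (k in seq_len(nb)) {
    src <- perm[k] - 1L; dst <- k - 1L
    sr <- (src %% nbr) * psf; sc <- (src %/% nbr) * psf
    dr <- (dst %% nbr) * psf; dc <- (dst %/% nbr) * psf
    out[(dr + 1L):(dr + psf), (dc + 1L):(dc + psf)] <-
      m[(sr + 1L):(sr + psf), (sc + 1L):(sc + psf)]
  }
  out
}

#' Kymograph colocalisation (Costes thresholds + Manders coefficients)
#'
#' Runs [costes_autothreshold()] and [manders_above_threshold()] on two
#' kymographs of identical shape, and optionally estimates significance by
#' Costes block randomisation: `psf_px`-sized blocks of channel 1 are
#' shuffled `n_randomizations` times and the p-value is the fraction of
#' shuffles whose full-image Pearson correlation reaches the observed one.
#' The headline value is the mean of the two Manders coefficients.
#'
#' @param kymoA,kymoB [kymograph()] objects or plain matrices.
#' @param settings a [coloc_settings()].
#' @param significance run the block-randomisation test.
#' @param seed RNG seed for the randomisation.
#' @return An object of class `ColocResult`: list with `tM1`, `tM2`,
#'   `manders_mean`, `T1`, `T2`, `slope`, `intercept`, `pearson_full` and
#'   `significance_p` (`NA` unless requested).
#' @export
kymo_coloc <- function(kymoA, kymoB, settings = coloc_settings(),
                       significance = FALSE, seed = 1L) {
  m1 <- if (inherits(kymoA, "Kymograph")) kymoA$values else as.matrix(kymoA)
  m2 <- if (inherits(kymoB, "Kymograph")) kymoB$values else as.matrix(kymoB)
  if (!identical(dim(m1), dim(m2))) {
    sq_stop("SHAPE_ERROR", "kymographs have different shapes (%s vs %s)",
            paste(dim(m1), collapse = "x"), paste(dim(m2), collapse = "x"))
  }
  th <- costes_autothreshold(m1, m2)
  tm <- manders_above_threshold(m1, m2, th$T1, th$T2)
  r_obs <- pearson_r(m1, m2)
  p <- NA_real_
  if (significance) {
    p <- with_seed(seed, {
      r_sh <- vapply(seq_len(settings$n_randomizations), function(i) {
        stats::cor(as.numeric(block_shuffle(m1, settings$psf_px)),
                   as.numeric(m2))
      }, numeric(1))
      mean(r_sh >= r_obs)
    })
  }
  structure(list(tM1 = unname(tm["tM1"]), tM2 = unname(tm["tM2"]),
                 manders_mean = mean(tm), T1 = th$T1, T2 = th$T2,
                 slope = th$slope, intercept = th$intercept,
                 pearson_full = r_obs, significance_p = p),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("ColocResult: tM1 = %.3f, tM2 = %.3f (mean %.3f)\n",
              x$tM1, x$tM2, x$manders_mean))
  cat(sprintf("  Costes thresholds T1 = %.4g, T2 = %.4g; Pearson r = %.3f\n",
              x$T1, x$T2, x$pearson_full))
  if (!is.na(x$significance_p)) {
    cat(sprintf("  block-randomisation p = %.3f\n", x$significance_p))
  }
  invisible(x)
}
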