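#' Renyi-entropy automatic threshold
#'
#' Computes the Renyi-entropy threshold of a gray-level histogram following
#' the three-order combination of Sahoo, Wilkins and Yeager, the algorithm
#' behind the widely used "RenyiEntropy" autothreshold. For each Renyi order
#' alpha in {1, 1/2, 2} (order 1 being the Shannon/maximum-entropy limit), a
#' candidate threshold maximises the summed Renyi entropies of the
#' background (bins `<= t`) and foreground (bins `> t`) distributions; the
#' three sorted candidates `t1 <= t2 <= t3` are then blended with the
#' method's beta weights, which depend on whether consecutive candidates lie
#' within 5 gray levels of each other, and on the histogram mass between the
#' outer candidates:
#'
#' `t* = floor( t1 (P(t1) + omega b1 / 4) + t2 omega b2 / 4 +
#'              t3 (1 - P(t3) + omega b3 / 4) )`
#'
#' with `P` the cumulative histogram and `omega = P(t3) - P(t1)`. Pixels
#' strictly above the returned gray level are foreground.
#'
#' @param counts non-negative histogram counts; bin `i` holds gray level
#'   `i - 1` (a 256-bin histogram covers gray levels 0-255).
#' @return Integer threshold gray level (0-based bin).
#' @export
renyi_threshold <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || sum(counts) <= 0) {
    sq_stop("DEGENERATE_HISTOGRAM", "histogram must have non-negative mass")
  }
  nz <- which(counts > 0)
  if (length(nz) < 2L) {
    sq_stop("DEGENERATE_HISTOGRAM",
            "histogram needs mass in at least 2 distinct bins")
  }
  n <- length(counts)
  p <- counts / sum(counts)
  P1 <- cumsum(p)
  # tail mass; clamp tiny negative/positive round-off so "no foreground
  # mass" is recognised exactly (smallest true tail mass is 1/sum(counts))
  P2 <- pmax(1 - P1, 0)
  P2[P2 < 1e-12] <- 0
  first <- nz[1L]; last <- nz[length(nz)]
  its <- first:last

  # Candidate selection mirrors the reference: the best total entropy must
  # strictly exceed 0, otherwise the candidate stays at gray level 0.
  pick <- function(tot) {
    best <- 0; best_t <- 0L
    for (k in seq_along(its)) {
      if (is.finite(tot[k]) && tot[k] > best) {
        best <- tot[k]
        best_t <- its[k] - 1L
      }
    }
    best_t
  }

  # alpha -> 1 (Shannon / Kapur maximum entropy)
  plogp <- ifelse(p > 0, p * log(p), 0)
  Hc <- cumsum(-plogp)
  Htot <- Hc[n]
  eb <- Hc[its] / P1[its] + log(P1[its])
  eo <- ifelse(P2[its] > 0,
               (Htot - Hc[its]) / P2[its] + log(pmax(P2[its], 1e-300)),
               0)
  t_shannon <- pick(eb + eo)

  # alpha = 1/2
  Sc <- cumsum(sqrt(p))
  Stot <- Sc[n]
  eb <- Sc[its] / sqrt(P1[its])
  eo <- ifelse(P2[its] > 0, (Stot - Sc[its]) / sqrt(pmax(P2[its], 0)), NaN)
  prod_half <- eb * eo
  t_half <- pick(ifelse(is.finite(prod_half) & prod_half > 0,
                        2 * log(prod_half), 0))

  # alpha = 2
  Qc <- cumsum(p^2)
  Qtot <- Qc[n]
  eb <- Qc[its] / P1[its]^2
  eo <- ifelse(P2[its] > 0, (Qtot - Qc[its]) / P2[its]^2, NaN)
  prod_two <- eb * eo
  t_two <- pick(ifelse(is.finite(prod_two) & prod_two > 0,
                       -log(prod_two), 0))

  ts <- sort(c(t_half, t_shannon, t_two))
  if (abs(ts[1L] - ts[2L]) <= 5) {
    b <- if (abs(ts[2L] - ts[3L]) <= 5) c(1, 2, 1) else c(0, 1, 3)
  } else {
    b <- if (abs(ts[2L] - ts[3L]) <= 5) c(3, 1, 0) else c(1, 2, 1)
  }
  P1_at <- function(g) P1[g + 1L] # g is a 0-based gray level
  omega <- P1_at(ts[3L]) - P1_at(ts[1L])
  opt <- ts[1L] * (P1_at(ts[1L]) + 0.25 * omega * b[1L]) +
    0.25 * ts[2L] * omega * b[2L] +
    ts[3L] * (1 - P1_at(ts[3L]) + 0.25 * omega * b[3L])
  as.integer(floor(opt))
}

#' Histogram of intensities on a fixed number of bins
#'
#' Min-max rescales the values into `n_bins` equal-width bins (the histogram
#' the Renyi autothreshold operates on) and returns the counts together with
#' the mapping back to intensity units.
#'
#' @param values numeric intensities.
#' @param n_bins number of bins (default 256).
#' @return List with `counts` (length `n_bins`), `min`, `bin_width`, and
#'   `threshold_value(bin)`, a function mapping a threshold bin to the
#'   intensity above which a pixel is foreground.
#' @export
intensity_histogram <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  lo <- min(values); hi <- max(values)
  if (hi <= lo) {
    sq_stop("DEGENERATE_HISTOGRAM", "constant intensities give no histogram")
  }
  w <- (hi - lo) / n_bins
  bins <- pmin(floor((values - lo) / w), n_bins - 1L)
  counts <- tabulate(bins + 1L, nbins = n_bins)
  list(counts = counts, min = lo, bin_width = w,
       threshold_value = function(bin) lo + (bin + 1) * w)
}
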