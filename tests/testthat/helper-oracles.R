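# Independent brute-force oracles used to cross-check the package's own
# implementations. These deliberately use naive per-threshold summation and
# a different regression route (PCA) from the package code.

# Renyi-entropy threshold by exhaustive entropy maximisation per order,
# followed by the published three-candidate combination rule.
oracle_renyi <- function(counts) {
  counts <- as.numeric(counts)
  n <- length(counts)
  p <- counts / sum(counts)
  nz <- which(counts > 0)
  first <- nz[1L]
  last <- nz[length(nz)]
  best_for_alpha <- function(alpha) {
    best_ent <- 0
    best_t <- 0L
    for (it in first:last) {
      pb <- p[1:it]
      po <- if (it < n) p[(it + 1):n] else numeric(0)
      P1 <- sum(pb)
      P2 <- sum(po)
      if (alpha == 1) {
        q <- pb[pb > 0] / P1
        eb <- -sum(q * log(q))
        eo <- 0
        if (P2 > 0) {
          q <- po[po > 0] / P2
          eo <- -sum(q * log(q))
        }
        tot <- eb + eo
      } else if (alpha == 0.5) {
        tot <- 0
        if (P2 > 0) {
          prod <- sum(sqrt(pb / P1)) * sum(sqrt(po / P2))
          if (prod > 0) tot <- 2 * log(prod)
        }
      } else { # alpha == 2
        tot <- 0
        if (P2 > 0) {
          prod <- sum((pb / P1)^2) * sum((po / P2)^2)
          if (prod > 0) tot <- -log(prod)
        }
      }
      if (is.finite(tot) && tot > best_ent) {
        best_ent <- tot
        best_t <- it - 1L
      }
    }
    best_t
  }
  ts <- sort(c(best_for_alpha(0.5), best_for_alpha(1), best_for_alpha(2)))
  if (abs(ts[1] - ts[2]) <= 5) {
    bw <- if (abs(ts[2] - ts[3]) <= 5) c(1, 2, 1) else c(0, 1, 3)
  } else {
    bw <- if (abs(ts[2] - ts[3]) <= 5) c(3, 1, 0) else c(1, 2, 1)
  }
  Pc <- cumsum(p)
  omega <- Pc[ts[3] + 1L] - Pc[ts[1] + 1L]
  opt <- ts[1] * (Pc[ts[1] + 1L] + 0.25 * omega * bw[1]) +
    0.25 * ts[2] * omega * bw[2] +
    ts[3] * (1 - Pc[ts[3] + 1L] + 0.25 * omega * bw[3])
  as.integer(floor(opt))
}

# assorted random 256-bin histograms: bimodal mixtures, uniform, sparse
random_histogram <- function(seed) {
  set.seed(seed)
  kind <- seed %% 4L
  h <- if (kind == 0L) {
    bg <- round(5000 * stats::dnorm(0:255, mean = sample(40:90, 1), sd = stats::runif(1, 5, 25)))
    fg <- round(stats::runif(1, 100, 2000) *
                  stats::dnorm(0:255, mean = sample(140:230, 1), sd = stats::runif(1, 5, 30)))
    bg + fg
  } else if (kind == 1L) {
    stats::rpois(256, lambda = stats::runif(1, 1, 30))
  } else if (kind == 2L) {
    h0 <- numeric(256)
    idx <- sample(1:256, sample(3:12, 1))
    h0[idx] <- sample(1:500, length(idx), replace = TRUE)
    h0
  } else {
    round(stats::runif(256, 0, 100) * (stats::runif(256) < 0.7))
  }
  if (sum(h > 0) < 2) h[c(10, 200)] <- h[c(10, 200)] + 5
  h
}

# Costes threshold by exhaustive scan: orthogonal regression via PCA, then
# the largest T1 whose valid below-threshold set is uncorrelated (r <= 0).
oracle_costes <- function(x, y, min_pixels = 10L) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  pc <- stats::prcomp(cbind(x, y))
  a <- pc$rotation[2, 1] / pc$rotation[1, 1]
  b <- mean(y) - a * mean(x)
  cand <- sort(unique(x), decreasing = TRUE)
  for (T1 in cand) {
    T2 <- a * T1 + b
    sel <- x < T1 & y < T2
    if (sum(sel) < min_pixels) next
    if (stats::sd(x[sel]) == 0 || stats::sd(y[sel]) == 0) {
      return(list(T1 = T1, T2 = T2))
    }
    if (stats::cor(x[sel], y[sel]) <= 0) return(list(T1 = T1, T2 = T2))
  }
  list(T1 = cand[length(cand)], T2 = a * cand[length(cand)] + b)
}
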